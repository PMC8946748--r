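# Two-phase unsupervised click-type discovery. Phase 1 clusters the clicks
# of each 5-minute bin on spectral similarity (Chinese whispers with edge
# pruning p_e = 0.95) and summarizes each within-bin cluster; phase 2
# clusters up to 40,000 bin-level summaries per deployment on combined
# spectral + envelope similarity (p_e = 0.98) and prunes weak clusters.

#' Clustering configuration
#'
#' @param bin_minutes Time-bin length, minutes.
#' @param min_cluster_rl_db Only clicks at or above this peak-to-peak level
#'   (dB re 1 uPa) enter clustering.
#' @param pe_phase1,pe_phase2 Edge-pruning parameters (see
#'   [chinese_whispers()]): each node retains roughly its strongest
#'   `1 - p_e` fraction of edges (top 5% in phase 1, top 2% in phase 2).
#'   The pruning semantics controls cluster granularity.
#' @param max_bins_phase2 Maximum number of bin summaries admitted to the
#'   phase-2 graph; larger inputs are uniformly subsampled (seeded).
#' @param min_bins_per_cluster,min_clicks_per_cluster Phase-2 pruning:
#'   clusters with fewer contributing bin-level averages, or representing
#'   fewer individual detections, are discarded.
#' @param cw_iterations Chinese whispers iteration cap (early stop on label
#'   stability).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(bin_minutes = 5, min_cluster_rl_db = 120,
                           pe_phase1 = 0.95, pe_phase2 = 0.98,
                           max_bins_phase2 = 40000,
                           min_bins_per_cluster = 25,
                           min_clicks_per_cluster = 50,
                           cw_iterations = 20) {
  stopifnot(pe_phase1 > 0, pe_phase1 < 1, pe_phase2 > 0, pe_phase2 < 1,
            bin_minutes > 0, max_bins_phase2 > 0,
            min_bins_per_cluster > 0, min_clicks_per_cluster > 0)
  structure(as.list(environment()), class = "cluster_config")
}

# Rows centered and scaled to unit L2 norm, so tcrossprod gives Pearson
# correlations. Zero-variance rows are mapped to zero vectors (similarity 0
# with everything: a flat spectrum carries no shape information).
.std_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- Inf
  m / nrm
}

#' Pairwise spectral similarity
#'
#' Pearson correlation of dB spectra restricted to the analysis band
#' (default 5-100 kHz on the 500 Hz grid). Correlation is invariant to the
#' per-click min-max normalization, making the measure amplitude-invariant
#' and shape-sensitive.
#'
#' @param spectra_db Matrix, one spectrum per row on the 500 Hz grid.
#' @param lo_khz,hi_khz Band restriction, kHz.
#' @param bin_khz Grid spacing, kHz.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
spectral_similarity <- function(spectra_db, lo_khz = 5, hi_khz = 100,
                                bin_khz = 0.5) {
  freqs <- (seq_len(ncol(spectra_db)) - 1) * bin_khz
  keep <- freqs >= lo_khz & freqs <= hi_khz
  z <- .std_rows(spectra_db[, keep, drop = FALSE])
  s <- tcrossprod(z)
  diag(s) <- 1
  s
}

# k-th largest value of a vector (partial sort).
.kth_largest <- function(v, k) -sort(-v, partial = k)[k]

# Neighbors retained per node: the top (1 - p_e) fraction, floored at 10.
# A kNN graph percolates around k ~ log n, but label propagation needs a
# comfortable margin above that (~2 log2 n for typical bin/cluster sizes)
# or homogeneous groups fragment into arbitrary sub-labels.
.prune_k <- function(n, p_e) {
  min(n - 1L, max(10L, round((1 - p_e) * (n - 1))))
}

# Per-node pruning thresholds: node i's threshold is its k-th largest
# off-diagonal similarity, k = round((1 - p_e) * (n - 1)), at least 1. An
# edge survives pruning when it is positive and at least one endpoint ranks
# it among its top (1 - p_e) fraction of edges, so every node retains its
# strongest links and homogeneous groups are not shredded by a global
# cutoff.
.prune_row_thresholds <- function(s, p_e) {
  n <- nrow(s)
  k <- .prune_k(n, p_e)
  d <- s
  diag(d) <- -Inf
  apply(d, 1, .kth_largest, k = k)
}

#' Chinese whispers clustering of a similarity matrix
#'
#' Edge pruning with parameter `p_e`: each node ranks its off-diagonal
#' similarities, and an edge is retained only if it is positive and lies in
#' the top `1 - p_e` fraction of edges of at least one of its endpoints
#' (p_e = 0.95 keeps roughly each node's strongest 5%). Randomized label
#' propagation then runs on the pruned graph: each node adopts the label
#' with maximal summed edge weight among its neighbors, in a fresh random
#' node order each iteration, ties broken at random, until labels stabilize
#' or the iteration cap is reached. Isolated nodes keep their own singleton
#' label. Deterministic under `set.seed()`.
#'
#' @param s Symmetric similarity matrix, unit diagonal.
#' @param p_e Edge-pruning parameter in (0, 1).
#' @param iterations Iteration cap.
#' @return Integer cluster labels, one per node (values are arbitrary ids).
#' @export
chinese_whispers <- function(s, p_e, iterations = 20) {
  n <- nrow(s)
  if (is.null(n) || n == 0) return(integer(0))
  if (n == 1) return(1L)
  thr <- .prune_row_thresholds(s, p_e)
  keep <- upper.tri(s) & s > 0 &
    (s >= matrix(thr, n, n) | s >= matrix(thr, n, n, byrow = TRUE))
  ut <- which(keep, arr.ind = TRUE)
  if (nrow(ut) == 0) return(seq_len(n))
  .cw_propagate(n, ut[, 1], ut[, 2], s[ut], iterations)
}

#' Assign clicks to 5-minute bins for clustering
#'
#' Half-open bins `[t, t + bin_minutes)` anchored at `origin_s`; a click on
#' a bin boundary belongs to the later bin. Clicks below
#' `min_cluster_rl_db` are excluded before binning.
#'
#' @param cs A `click_set`.
#' @param cfg [cluster_config()].
#' @param origin_s Recording start time, seconds.
#' @return Named list of `click_set`s, names are bin start times (seconds).
#' @export
assign_bins <- function(cs, cfg = cluster_config(), origin_s = 0) {
  keep <- cs$clicks$pp_db >= cfg$min_cluster_rl_db
  cs <- subset_click_set(cs, keep)
  if (nrow(cs$clicks) == 0) return(list())
  width <- cfg$bin_minutes * 60
  bin <- floor((cs$clicks$peak_s - origin_s) / width)
  idx <- split(seq_len(nrow(cs$clicks)), bin)
  out <- lapply(idx, function(i) subset_click_set(cs, i))
  names(out) <- as.character(origin_s + as.numeric(names(idx)) * width)
  out
}

#' Bin summary container
#'
#' Matrix-backed store of per-(bin, within-bin-cluster) summaries: mean dB
#' spectrum, ICI histogram of intervals between consecutive click starts,
#' mean envelope, click count.
#'
#' @param df data.frame (bin_start, n_clicks, source_cluster).
#' @param spectra,ici,envelopes Matrices, one row per summary.
#' @return Object of class `bin_summary_set`.
#' @export
bin_summary_set <- function(df, spectra, ici, envelopes) {
  stopifnot(nrow(df) == nrow(spectra), nrow(df) == nrow(ici),
            nrow(df) == nrow(envelopes))
  structure(list(df = df, spectra = spectra, ici = ici,
                 envelopes = envelopes), class = "bin_summary_set")
}

#' @export
print.bin_summary_set <- function(x, ...) {
  cat("<bin_summary_set> ", nrow(x$df), " summaries\n", sep = "")
  invisible(x)
}

#' Combine bin summary sets
#' @param sets List of `bin_summary_set` objects.
#' @return Combined `bin_summary_set`.
#' @export
bind_bin_summaries <- function(sets) {
  sets <- sets[vapply(sets, function(s) nrow(s$df) > 0, logical(1))]
  if (length(sets) == 0) stop("no non-empty bin summary sets")
  bin_summary_set(do.call(rbind, lapply(sets, `[[`, "df")),
                  do.call(rbind, lapply(sets, `[[`, "spectra")),
                  do.call(rbind, lapply(sets, `[[`, "ici")),
                  do.call(rbind, lapply(sets, `[[`, "envelopes")))
}

#' Subset a bin summary set
#' @param bss A `bin_summary_set`.
#' @param idx Row indices or logical mask.
#' @export
subset_bin_summaries <- function(bss, idx) {
  bin_summary_set(bss$df[idx, , drop = FALSE],
                  bss$spectra[idx, , drop = FALSE],
                  bss$ici[idx, , drop = FALSE],
                  bss$envelopes[idx, , drop = FALSE])
}

#' Phase-1: cluster the clicks of one bin
#'
#' Chinese whispers on pairwise spectral similarity with `pe_phase1`
#' pruning. Each resulting cluster of two or more clicks yields one bin
#' summary (mean spectrum, ICI histogram of consecutive click starts, mean
#' envelope, click count). Nodes isolated by pruning, and single-member
#' labels, are excluded from the summaries: they represent clicks too
#' dissimilar to the bin's dominant type(s). Bins with a single click
#' produce one trivial summary.
#'
#' @param cs_bin `click_set` of one bin's clicks (post level cut).
#' @param cfg [cluster_config()].
#' @param bin_start Bin start time, seconds (carried to the summaries).
#' @param ici_cfg [ici_config()] controlling the ICI histogram grid.
#' @return List with `summaries` (a `bin_summary_set`), `labels` (one per
#'   input click), and `members` (per summary, the indices of its clicks).
#' @export
cluster_bin <- function(cs_bin, cfg = cluster_config(), bin_start = 0,
                        ici_cfg = ici_config()) {
  n <- nrow(cs_bin$clicks)
  if (n == 0) stop("empty bin")
  if (n == 1) {
    labels <- 1L
  } else {
    s <- spectral_similarity(cs_bin$spectra)
    labels <- chinese_whispers(s, cfg$pe_phase1, cfg$cw_iterations)
  }
  groups <- split(seq_len(n), labels)
  groups <- groups[vapply(groups, length, integer(1)) >= 2 |
                     length(groups) == 1]
  if (length(groups) == 0) {
    return(list(summaries = bin_summary_set(
      data.frame(bin_start = numeric(0), n_clicks = integer(0),
                 source_cluster = integer(0)),
      matrix(0, 0, ncol(cs_bin$spectra)),
      matrix(0, 0, round(ici_cfg$hist_max_s / ici_cfg$hist_bin_s)),
      matrix(0, 0, ncol(cs_bin$envelopes))), labels = labels,
      members = list()))
  }
  rows <- lapply(seq_along(groups), function(g) {
    i <- groups[[g]]
    times <- sort(cs_bin$clicks$peak_s[i])
    list(df = data.frame(bin_start = bin_start, n_clicks = length(i),
                         source_cluster = g),
         spec = colMeans(cs_bin$spectra[i, , drop = FALSE]),
         ici = ici_histogram(diff(times), ici_cfg),
         env = colMeans(cs_bin$envelopes[i, , drop = FALSE]))
  })
  summaries <- bin_summary_set(
    do.call(rbind, lapply(rows, `[[`, "df")),
    do.call(rbind, lapply(rows, `[[`, "spec")),
    do.call(rbind, lapply(rows, `[[`, "ici")),
    do.call(rbind, lapply(rows, `[[`, "env")))
  list(summaries = summaries, labels = labels, members = unname(groups))
}

# Blockwise per-row pruning thresholds for the phase-2 combined similarity
# (the 40,000-node matrix never exists in full).
.phase2_row_thresholds <- function(zs, ze, p_e, block = 1000L) {
  n <- nrow(zs)
  k <- .prune_k(n, p_e)
  thr <- numeric(n)
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(n, b0 + block - 1L)
    w <- (tcrossprod(zs[b0:b1, , drop = FALSE], zs) +
            tcrossprod(ze[b0:b1, , drop = FALSE], ze)) / 2
    w[cbind(seq_len(b1 - b0 + 1L), b0:b1)] <- -Inf  # exclude self
    thr[b0:b1] <- apply(w, 1, .kth_largest, k = k)
  }
  thr
}

#' Phase-2: cluster bin-level summaries into candidate click types
#'
#' If more than `max_bins_phase2` summaries are supplied, a seeded uniform
#' subsample of exactly that many is admitted to graph construction (the
#' step is memory-limited). Similarity is the arithmetic mean of the
#' spectral-shape correlation and the mean-envelope correlation; edges below
#' the `pe_phase2` quantile are pruned and Chinese whispers is run on the
#' remaining graph. Clusters with fewer than `min_bins_per_cluster`
#' bin-level averages or fewer than `min_clicks_per_cluster` total
#' detections are discarded. The similarity graph is built blockwise so the
#' full 40,000-node pass stays within memory.
#'
#' @param bss A `bin_summary_set` for one deployment.
#' @param cfg [cluster_config()].
#' @return List with `clusters` (list of type clusters: id, member_bins
#'   indices into the admitted set, summary_spectrum, ici_distribution,
#'   mean_envelope, n_bins, n_total_clicks), `labels` (per admitted
#'   summary; 0 = not in a kept cluster), `admitted` (indices into `bss`),
#'   and `log` (n_input, n_admitted, threshold, n_raw_clusters, n_kept).
#' @export
cluster_types <- function(bss, cfg = cluster_config()) {
  n_input <- nrow(bss$df)
  if (n_input == 0) stop("no bin summaries supplied")
  admitted <- seq_len(n_input)
  if (n_input > cfg$max_bins_phase2) {
    admitted <- sort(sample.int(n_input, cfg$max_bins_phase2))
  }
  sub <- subset_bin_summaries(bss, admitted)
  n <- nrow(sub$df)
  freqs <- (seq_len(ncol(sub$spectra)) - 1) * 0.5
  band <- freqs >= 5 & freqs <= 100
  zs <- .std_rows(sub$spectra[, band, drop = FALSE])
  ze <- .std_rows(sub$envelopes)
  thr <- .phase2_row_thresholds(zs, ze, cfg$pe_phase2)
  # blockwise edge construction: keep positive similarities ranked in the
  # top (1 - p_e) of either endpoint
  block <- 1000L
  ei <- list(); ej <- list(); ew <- list()
  nb <- 0L
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(n, b0 + block - 1L)
    rows <- b0:b1
    w <- (tcrossprod(zs[rows, , drop = FALSE], zs) +
            tcrossprod(ze[rows, , drop = FALSE], ze)) / 2
    keep <- w > 0 & (w >= thr[rows] | sweep(w, 2, thr, `>=`)) &
      outer(rows, seq_len(n), `<`)   # j > i only
    sel <- which(keep)
    if (length(sel)) {
      nb <- nb + 1L
      ei[[nb]] <- rows[(sel - 1L) %% length(rows) + 1L]
      ej[[nb]] <- (sel - 1L) %/% length(rows) + 1L
      ew[[nb]] <- w[sel]
    }
  }
  if (nb == 0) {
    labels <- seq_len(n)
  } else {
    labels <- .cw_propagate(n, unlist(ei), unlist(ej), unlist(ew),
                            cfg$cw_iterations)
  }
  groups <- split(seq_len(n), labels)
  n_raw <- length(groups)
  keep <- vapply(groups, function(i) {
    length(i) >= cfg$min_bins_per_cluster &&
      sum(sub$df$n_clicks[i]) >= cfg$min_clicks_per_cluster
  }, logical(1))
  groups <- groups[keep]
  clusters <- lapply(seq_along(groups), function(g) {
    i <- groups[[g]]
    list(id = g,
         member_bins = i,
         summary_spectrum = colMeans(sub$spectra[i, , drop = FALSE]),
         ici_distribution = colSums(sub$ici[i, , drop = FALSE]),
         mean_envelope = colMeans(sub$envelopes[i, , drop = FALSE]),
         n_bins = length(i),
         n_total_clicks = sum(sub$df$n_clicks[i]))
  })
  final <- integer(n)
  for (g in seq_along(groups)) final[groups[[g]]] <- g
  list(clusters = clusters, labels = final, admitted = admitted,
       summaries = sub,
       log = list(n_input = n_input, n_admitted = n, threshold = thr,
                  n_raw_clusters = n_raw, n_kept = length(clusters)))
}
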