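# Shared fixtures and independent brute-force oracles.

FS <- 200000
CAL <- calibration(140)

# A short single-component probe click (100 us, broad band) whose
# above-threshold region sits well inside the snippet.
probe_template <- function(peak_khz = 40, bw_khz = 17.7, duration_us = 100) {
  data.frame(name = "probe", peak_freq_khz = peak_khz, bw3db_khz = bw_khz,
             modal_ici_s = 0.1, duration_us = duration_us,
             ici_jitter_cv = 0)
}

probe_components <- function(tpl) {
  data.frame(name = tpl$name, freq_khz = tpl$peak_freq_khz, rel_amp = 1,
             bw_khz = tpl$bw3db_khz)
}

# Place click snippets (already scaled) at given onset samples in a quiet
# scene of n samples with optional Gaussian noise.
place_clicks <- function(n, snippet, onsets, noise_sd = 0) {
  x <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  for (i0 in onsets) {
    i1 <- i0 + length(snippet) - 1L
    x[i0:i1] <- x[i0:i1] + snippet
  }
  x
}

scale_to_db <- function(snippet, db, cal = CAL) {
  snippet * db_to_p2p(db, cal) / (max(snippet) - min(snippet))
}

# ---- brute-force segmentation oracle ---------------------------------------
# Literal re-implementation of the stage-2 rules by naive scanning, sharing
# only the energy/envelope vectors with the tested code.
segment_oracle <- function(p2p, energy, raw, fs, cal = CAL,
                           cfg = detector_config()) {
  thr <- db_to_p2p(cfg$pp_threshold_db - cfg$db_tol, cal)
  e_thr <- quantile(energy, cfg$energy_percentile / 100, names = FALSE)
  n <- length(p2p)
  high <- which(p2p >= thr)
  if (length(high) == 0) return(cbind(start = integer(0), end = integer(0)))
  # group high samples into runs by scanning
  runs <- list()
  s <- high[1]; prev <- high[1]
  for (i in high[-1]) {
    if (i == prev + 1) prev <- i
    else { runs[[length(runs) + 1]] <- c(s, prev); s <- i; prev <- i }
  }
  runs[[length(runs) + 1]] <- c(s, prev)
  bounds <- list()
  for (r in runs) {
    seg <- r[1]:r[2]
    peak <- seg[which.max(energy[seg])]
    a <- peak
    while (a > 1 && energy[a - 1] > e_thr) a <- a - 1
    b <- peak
    while (b < n && energy[b + 1] > e_thr) b <- b + 1
    bounds[[length(bounds) + 1]] <- c(a, b)
  }
  bounds <- unique(bounds)
  bounds <- bounds[order(vapply(bounds, `[`, 1, 1))]
  merged <- list(bounds[[1]])
  for (k in seq_along(bounds)[-1]) {
    last <- merged[[length(merged)]]
    gap_us <- (bounds[[k]][1] - last[2] - 1) / fs * 1e6
    if (gap_us < cfg$click_merge_us) {
      merged[[length(merged)]] <- c(last[1], max(last[2], bounds[[k]][2]))
    } else merged[[length(merged) + 1]] <- bounds[[k]]
  }
  m <- do.call(rbind, merged)
  colnames(m) <- c("start", "end")
  keep <- vapply(seq_len(nrow(m)), function(k)
    max(abs(raw[m[k, 1]:m[k, 2]])) < cfg$clip_level, logical(1))
  m[keep, , drop = FALSE]
}

# ---- brute-force Chinese whispers oracle -----------------------------------
# Naive R implementation of the same propagation semantics (random node
# order per sweep, adopt the neighbor label with maximal summed weight,
# random tie-break) on a pruned similarity matrix. Pruning re-implemented
# by naive per-node ranking: an edge survives if positive and within the
# top (1 - p_e) edges of either endpoint.
cw_oracle <- function(s, p_e, iterations = 20) {
  n <- nrow(s)
  if (n == 0) return(integer(0))
  k <- min(n - 1, max(10, round((1 - p_e) * (n - 1))))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    kth <- sort(s[i, others], decreasing = TRUE)[k]
    for (j in others) {
      if (s[i, j] > 0 && s[i, j] >= kth) {
        w[i, j] <- s[i, j]
        w[j, i] <- s[i, j]
      }
    }
  }
  labels <- seq_len(n)
  for (it in seq_len(iterations)) {
    changed <- FALSE
    for (v in sample.int(n)) {
      nb <- which(w[v, ] > 0)
      if (length(nb) == 0) next
      scores <- tapply(w[v, nb], labels[nb], sum)
      best <- names(scores)[scores == max(scores)]
      pick <- as.integer(if (length(best) > 1) sample(best, 1) else best)
      if (pick != labels[v]) { labels[v] <- pick; changed <- TRUE }
    }
    if (!changed) break
  }
  labels
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# ---- synthetic feature helpers ---------------------------------------------
# Gaussian-bump dB spectrum on the 200-bin grid.
bump_spectrum <- function(f0_khz, width_khz = 3, floor_db = -40,
                          height_db = 35) {
  f <- (0:199) * 0.5
  floor_db + height_db * exp(-(f - f0_khz)^2 / (2 * width_khz^2))
}

# Build a bin_summary_set of planted types.
planted_summaries <- function(centers_khz, n_each, n_clicks = 10,
                              jitter_db = 0.5, ici_bin = 15) {
  rows <- sum(n_each)
  spec <- matrix(0, rows, 200)
  env <- matrix(0, rows, 200)
  ici <- matrix(0, rows, 100)
  r <- 0
  for (k in seq_along(centers_khz)) {
    base <- bump_spectrum(centers_khz[k])
    ebase <- exp(-((1:200) - 40 - 10 * k)^2 / (2 * 15^2))
    for (j in seq_len(n_each[k])) {
      r <- r + 1
      spec[r, ] <- base + rnorm(200, sd = jitter_db)
      env[r, ] <- ebase + rnorm(200, sd = 0.01)
      ici[r, ici_bin + k] <- 20
    }
  }
  bin_summary_set(
    data.frame(bin_start = seq_len(rows) * 300,
               n_clicks = rep(n_clicks, rows),
               source_cluster = 1L),
    spec, ici, env)
}

# Fabricate a click_set from scalar vectors (for binning/threshold logic).
fab_click_set <- function(times_s, pp_db, peak_khz = 30) {
  n <- length(times_s)
  recs <- lapply(seq_len(n), function(i) {
    list(start_s = times_s[i] - 1e-4, end_s = times_s[i] + 1e-4,
         peak_s = times_s[i], peak_freq_khz = peak_khz,
         pp_db = pp_db[i], peak_spec_db = 100, bw3db_khz = 5,
         duration_us = 200,
         spectrum_db = bump_spectrum(peak_khz),
         envelope = exp(-((1:200) - 100)^2 / 200))
  })
  click_set(recs, FS, CAL)
}

# Detect one synthesized bout scene and return the retained click_set.
detect_scene <- function(scene, cfg = detector_config()) {
  detect_clicks(scene$wave, scene$fs_hz, CAL, cfg)$clicks
}
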