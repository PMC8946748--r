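# Bin-level classification: balanced-class training-set construction,
# feature assembly from bin summaries, label review support, per-class
# false-positive-rate estimation and threshold sweeps. The network itself
# lives in mlp.R.

#' Training-set configuration
#'
#' A balanced set of `examples_per_class` (default 5,500) per class is
#' assembled: well-represented classes are uniformly subsampled, minority
#' classes are augmented by adding Gaussian noise to existing examples.
#' Each class is split 5,000/500 train/test, and the training part is
#' further split 80/20 into fitting and validation subsets.
#'
#' @param examples_per_class Balanced per-class total.
#' @param train_per_class,test_per_class Train/test split sizes (must sum to
#'   `examples_per_class`).
#' @param val_fraction Fraction of the training partition held out for
#'   validation.
#' @param augment_noise_sigma Augmentation noise scale, as a fraction of the
#'   per-feature dynamic range (features are normalized to [0, 1]).
#' @return A list of class `training_config`.
#' @export
training_config <- function(examples_per_class = 5500,
                            train_per_class = 5000, test_per_class = 500,
                            val_fraction = 0.2, augment_noise_sigma = 0.05) {
  stopifnot(train_per_class + test_per_class == examples_per_class,
            val_fraction > 0, val_fraction < 1, augment_noise_sigma >= 0)
  structure(as.list(environment()), class = "training_config")
}

#' Assemble classifier features from bin summaries
#'
#' Concatenates, per summary: the min-max-normalized mean spectrum, the
#' ICI histogram normalized to unit maximum, and the min-max-normalized
#' mean envelope — spectral shape, click rate, and waveform envelope shape.
#' Every block lies in [0, 1] and the total length is fixed across
#' examples.
#'
#' @param bss A `bin_summary_set`.
#' @return Numeric matrix, one feature row per summary.
#' @export
bin_features <- function(bss) {
  norm01 <- function(m) {
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    (m - lo) / pmax(hi - lo, 1e-12)
  }
  ici <- bss$ici / pmax(apply(bss$ici, 1, max), 1)
  cbind(norm01(bss$spectra), ici, norm01(bss$envelopes))
}

#' Build a balanced, partitioned training set
#'
#' @param class_examples Named list mapping class name to a feature matrix
#'   (rows = examples). Every class must have at least one example.
#' @param cfg [training_config()].
#' @param seed Optional seed (subsampling, augmentation and splits).
#' @return A list with matrices/labels `train` (the fitting subset), `val`,
#'   `test`, plus `train_full` indices bookkeeping and a `counts`
#'   data.frame (class, n_raw, n_augmented, n_total, n_train_partition,
#'   n_test, n_fit, n_val).
#' @export
build_balanced_set <- function(class_examples, cfg = training_config(),
                               seed = NULL) {
  stopifnot(is.list(class_examples), length(class_examples) > 0,
            !is.null(names(class_examples)))
  if (!is.null(seed)) set.seed(seed)
  empty <- names(class_examples)[vapply(class_examples, nrow, 1L) == 0]
  if (length(empty)) stop("class with no examples: ",
                          paste(empty, collapse = ", "))
  p <- ncol(class_examples[[1]])
  parts <- list(train = list(), val = list(), test = list())
  counts <- list()
  for (cls in names(class_examples)) {
    x <- class_examples[[cls]]
    if (ncol(x) != p) stop("feature length mismatch in class ", cls)
    n_raw <- nrow(x)
    n_aug <- 0L
    if (n_raw >= cfg$examples_per_class) {
      x <- x[sample.int(n_raw, cfg$examples_per_class), , drop = FALSE]
    } else {
      n_aug <- cfg$examples_per_class - n_raw
      src <- x[sample.int(n_raw, n_aug, replace = TRUE), , drop = FALSE]
      aug <- src + matrix(rnorm(length(src), sd = cfg$augment_noise_sigma),
                          nrow(src))
      aug[aug < 0] <- 0   # re-clip to the valid feature range
      aug[aug > 1] <- 1
      x <- rbind(x, aug)
    }
    idx <- sample.int(cfg$examples_per_class)
    test_i <- idx[seq_len(cfg$test_per_class)]
    train_i <- idx[-seq_len(cfg$test_per_class)]
    n_val <- round(cfg$val_fraction * length(train_i))
    val_i <- train_i[seq_len(n_val)]
    fit_i <- train_i[-seq_len(n_val)]
    parts$train[[cls]] <- x[fit_i, , drop = FALSE]
    parts$val[[cls]] <- x[val_i, , drop = FALSE]
    parts$test[[cls]] <- x[test_i, , drop = FALSE]
    counts[[cls]] <- data.frame(
      class = cls, n_raw = n_raw, n_augmented = n_aug,
      n_total = cfg$examples_per_class,
      n_train_partition = length(train_i), n_test = length(test_i),
      n_fit = length(fit_i), n_val = length(val_i))
  }
  bind <- function(pp) {
    list(x = do.call(rbind, pp),
         y = factor(rep(names(pp), vapply(pp, nrow, 1L)),
                    levels = names(class_examples)))
  }
  out <- list(train = bind(parts$train), val = bind(parts$val),
              test = bind(parts$test),
              counts = do.call(rbind, c(counts, make.row.names = FALSE)))
  class(out) <- "balanced_set"
  out
}

#' Classify bin summaries
#'
#' Runs a trained network over bin summaries, yielding one label and an
#' associated softmax probability per 5-minute bin summary.
#'
#' @param model A model from [train_network()].
#' @param bss A `bin_summary_set`, or a precomputed feature matrix.
#' @return data.frame (bin_start if available, class, probability) with the
#'   full softmax matrix in attribute `probs` (rows sum to 1).
#' @export
predict_bins <- function(model, bss) {
  x <- if (inherits(bss, "bin_summary_set")) bin_features(bss) else bss
  if (nrow(x) == 0) {
    out <- data.frame(class = character(0), probability = numeric(0))
    attr(out, "probs") <- matrix(0, 0, length(model$classes))
    return(out)
  }
  if (ncol(x) != model$n_in)
    stop("feature length ", ncol(x), " does not match model (", model$n_in, ")")
  probs <- mlp_forward(model, x)
  k <- max.col(probs)
  out <- data.frame(class = model$classes[k],
                    probability = probs[cbind(seq_len(nrow(probs)), k)],
                    stringsAsFactors = FALSE)
  if (inherits(bss, "bin_summary_set")) out <- cbind(bss$df["bin_start"], out)
  attr(out, "probs") <- probs
  out
}

#' Label review artifact and removal mask
#'
#' Emits the analyst-review artifact for one class — the class's spectra
#' sorted by peak frequency and concatenated into an image — and applies an
#' externally supplied removal mask. The judgment of which labels are
#' blatantly inconsistent is a human step and out of scope; the mask makes
#' the review reproducible.
#'
#' @param labels data.frame of labels for one class (one row per bin).
#' @param spectra Matrix of the corresponding mean spectra.
#' @param path Output PNG path for the concatenated-spectra artifact.
#' @param removal_mask Logical vector (TRUE = remove); default none.
#' @return List with `labels` (a `review_flag` column added: "kept" or
#'   "removed"), `order` (row order used in the artifact, by peak
#'   frequency), `artifact` (path).
#' @export
review_labels <- function(labels, spectra, path = NULL, removal_mask = NULL) {
  stopifnot(nrow(labels) == nrow(spectra))
  if (is.null(removal_mask)) removal_mask <- rep(FALSE, nrow(labels))
  stopifnot(length(removal_mask) == nrow(labels))
  peak <- max.col(spectra, ties.method = "first")
  ord <- order(peak)
  if (!is.null(path) && nrow(spectra) > 0) {
    m <- spectra[ord, , drop = FALSE]
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    m <- (m - lo) / pmax(hi - lo, 1e-12)
    png::writePNG(m, path)
  }
  labels$review_flag <- ifelse(removal_mask, "removed", "kept")
  list(labels = labels, order = ord, artifact = path)
}

#' Stratified false-positive-rate estimation
#'
#' Estimates residual classifier error per class (and per site when given)
#' from a stratified random subset of the retained labels: within each
#' class-by-site stratum, `n_per_stratum` labels are sampled and compared
#' against truth; FPR is the fraction judged incorrect. Strata with no
#' retained labels are flagged undefined, never reported as zero.
#'
#' @param labels data.frame with columns `class` (predicted), `truth`,
#'   and optionally `site` and `deployment`.
#' @param n_per_stratum Number of labels reviewed per stratum.
#' @param seed Optional seed.
#' @param average_deployments If TRUE and a `deployment` column exists,
#'   estimates are computed per deployment and averaged within site.
#' @return data.frame (class, site, fpr, n_reviewed, defined).
#' @export
estimate_fpr <- function(labels, n_per_stratum = 50, seed = NULL,
                         average_deployments = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (!"site" %in% names(labels)) labels$site <- "all"
  strat_cols <- c("class", "site")
  if (average_deployments && "deployment" %in% names(labels))
    strat_cols <- c(strat_cols, "deployment")
  key <- interaction(labels[strat_cols], drop = TRUE)
  res <- lapply(split(seq_len(nrow(labels)), key), function(i) {
    take <- if (length(i) > n_per_stratum) sample(i, n_per_stratum) else i
    wrong <- labels$class[take] != labels$truth[take]
    data.frame(class = labels$class[i[1]], site = labels$site[i[1]],
               deployment = if ("deployment" %in% strat_cols)
                 labels$deployment[i[1]] else NA,
               fpr = mean(wrong), n_reviewed = length(take),
               defined = length(take) > 0)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  if (average_deployments && "deployment" %in% strat_cols) {
    out <- aggregate(cbind(fpr = out$fpr, n_reviewed = out$n_reviewed),
                     by = list(class = out$class, site = out$site),
                     FUN = mean)
    out$n_reviewed <- round(out$n_reviewed)
    out$defined <- TRUE
  }
  out
}

#' Received-level / clicks-per-bin threshold sweep
#'
#' Explores enforcing increasingly high received-level and
#' number-of-clicks-per-bin thresholds as approaches to minimize FPR by
#' excluding poor-quality bins. Retention is monotonically non-increasing
#' along both grid axes.
#'
#' @param labels data.frame with `class`, `truth`, `rl_db` (per-bin
#'   received level) and `n_clicks`.
#' @param rl_grid,clicks_grid Threshold grids.
#' @return data.frame (min_rl_db, min_clicks, fpr, retention, n_retained).
#' @export
threshold_sweep <- function(labels, rl_grid = c(0, 120, 125, 130),
                            clicks_grid = c(0, 10, 50, 100)) {
  grid <- expand.grid(min_rl_db = rl_grid, min_clicks = clicks_grid)
  n <- nrow(labels)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    keep <- labels$rl_db >= grid$min_rl_db[k] &
      labels$n_clicks >= grid$min_clicks[k]
    fpr <- if (any(keep)) mean(labels$class[keep] != labels$truth[keep])
      else NA_real_
    data.frame(min_rl_db = grid$min_rl_db[k], min_clicks = grid$min_clicks[k],
               fpr = fpr, retention = sum(keep) / n, n_retained = sum(keep))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
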