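# Per-type descriptive statistics: median peak frequency and -3 dB
# bandwidth with 10th/90th percentiles, and the modal inter-click interval
# summarized as the median of per-bin modes.

#' ICI histogram configuration
#'
#' Intervals are histogrammed on a fixed grid (default 0.01 s bins over
#' 0-1 s, so catalog modal values land on bin centers 0.005, 0.015, ...).
#' Modes below `suppress_below_s` are suppressed: high-density encounters
#' saturate the ICI distribution with near-zero intervals when click trains
#' from many simultaneously clicking animals interleave.
#'
#' @param suppress_below_s Histogram mass below this interval (s) is ignored
#'   by [modal_ici()].
#' @param hist_bin_s Histogram bin width, s.
#' @param hist_max_s Histogram upper limit, s.
#' @return A list of class `ici_config`.
#' @export
ici_config <- function(suppress_below_s = 0.02, hist_bin_s = 0.01,
                       hist_max_s = 1.0) {
  stopifnot(suppress_below_s > 0, suppress_below_s < hist_max_s,
            hist_bin_s > 0)
  structure(list(suppress_below_s = suppress_below_s,
                 hist_bin_s = hist_bin_s, hist_max_s = hist_max_s),
            class = "ici_config")
}

#' Histogram a set of inter-click intervals
#'
#' @param intervals Intervals, seconds; values outside `[0, hist_max_s]`
#'   are dropped.
#' @param cfg [ici_config()].
#' @return Integer counts, one per bin; bin centers in attribute `centers`.
#' @export
ici_histogram <- function(intervals, cfg = ici_config()) {
  nb <- round(cfg$hist_max_s / cfg$hist_bin_s)
  intervals <- intervals[is.finite(intervals) & intervals >= 0 &
                           intervals <= cfg$hist_max_s]
  idx <- pmin(nb - 1, floor(intervals / cfg$hist_bin_s))
  counts <- tabulate(idx + 1L, nbins = nb)
  structure(counts, centers = (seq_len(nb) - 0.5) * cfg$hist_bin_s)
}

#' Modal inter-click interval of one histogram
#'
#' Returns the center of the maximal histogram bin after zeroing all bins
#' whose center lies below the suppression limit; ties go to the lowest bin
#' center. If no mass remains above the limit, the mode is undefined and
#' `NA` is returned.
#'
#' @param hist Counts from [ici_histogram()] (or any vector on the same
#'   grid).
#' @param cfg [ici_config()].
#' @return Modal ICI in seconds, or `NA_real_` when undefined.
#' @export
modal_ici <- function(hist, cfg = ici_config()) {
  centers <- attr(hist, "centers")
  if (is.null(centers)) {
    centers <- (seq_along(hist) - 0.5) * cfg$hist_bin_s
  }
  counts <- as.numeric(hist)
  counts[centers < cfg$suppress_below_s] <- 0
  if (all(counts == 0)) return(NA_real_)
  centers[which.max(counts)]
}

#' Characterize a click type
#'
#' Descriptive statistics in catalog form: median and 10th/90th percentiles
#' of peak frequency and -3 dB bandwidth over a sample of representative
#' clicks (default 2,000), the modal-ICI distribution over a sample of
#' 5-minute bins (default 1,000) summarized as the median of per-bin modes,
#' and bin-wise median/percentile spectra. When more clicks or bins are
#' available than the sample sizes, a seeded uniform subsample of exactly
#' those sizes is used; when fewer, all are used and the counts recorded.
#'
#' @param clicks A `click_set` of the type's clicks.
#' @param bins A `bin_summary_set` of the type's bin summaries.
#' @param name Type name (a name is also suggested from the median peak
#'   frequency, UD convention).
#' @param cfg [ici_config()].
#' @param n_clicks_max,n_bins_max Subsample sizes.
#' @param seed Optional seed for the subsampling.
#' @return Object of class `type_profile`.
#' @export
characterize_type <- function(clicks, bins = NULL, name = NULL,
                              cfg = ici_config(), n_clicks_max = 2000,
                              n_bins_max = 1000, seed = NULL) {
  stopifnot(nrow(clicks$clicks) > 0)
  if (!is.null(seed)) set.seed(seed)
  nc <- nrow(clicks$clicks)
  if (nc > n_clicks_max) {
    clicks <- subset_click_set(clicks, sort(sample.int(nc, n_clicks_max)))
    nc <- n_clicks_max
  }
  q3 <- function(x) quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  pf <- q3(clicks$clicks$peak_freq_khz)
  bw <- q3(clicks$clicks$bw3db_khz)
  spec_q <- apply(clicks$spectra, 2, q3)
  modal <- c(NA_real_, NA_real_, NA_real_)
  nb <- 0L
  modes <- numeric(0)
  if (!is.null(bins) && nrow(bins$df) > 0) {
    nb <- nrow(bins$df)
    if (nb > n_bins_max) {
      bins <- subset_bin_summaries(bins, sort(sample.int(nb, n_bins_max)))
      nb <- n_bins_max
    }
    modes <- apply(bins$ici, 1, modal_ici, cfg = cfg)
    modes <- modes[!is.na(modes)]
    if (length(modes)) modal <- q3(modes)
  }
  med_pf <- pf[2]
  structure(list(
    name = if (is.null(name)) paste0("UD", round(med_pf)) else name,
    suggested_name = paste0("UD", round(med_pf)),
    peak_freq_khz = c(p10 = pf[1], median = pf[2], p90 = pf[3]),
    bw3db_khz = c(p10 = bw[1], median = bw[2], p90 = bw[3]),
    modal_ici_s = c(p10 = modal[1], median = modal[2], p90 = modal[3]),
    n_clicks_used = nc,
    n_bins_used = nb,
    modes = modes,
    median_spectrum = spec_q[2, ],
    p10_spectrum = spec_q[1, ],
    p90_spectrum = spec_q[3, ]
  ), class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  fmt <- function(v) sprintf("%.3g [%.3g, %.3g]", v["median"], v["p10"], v["p90"])
  cat("<type_profile> ", x$name, "\n",
      "  peak frequency (kHz): ", fmt(x$peak_freq_khz), "\n",
      "  -3 dB bandwidth (kHz): ", fmt(x$bw3db_khz), "\n",
      "  modal ICI (s): ", fmt(x$modal_ici_s), "\n",
      "  n clicks = ", x$n_clicks_used, ", n bins = ", x$n_bins_used, "\n",
      sep = "")
  invisible(x)
}

#' Serialize a type profile to JSON
#' @param profile A `type_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_type_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile[setdiff(names(profile), "modes")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render the four-panel catalog figure for a type
#'
#' Panels: median power spectrum with 10th/90th percentile envelopes;
#' distribution of per-bin modal ICI values; concatenation of normalized
#' click spectra sorted by received level; concatenation of normalized
#' waveform envelopes sorted by received level.
#'
#' @param profile A `type_profile` from [characterize_type()].
#' @param clicks The `click_set` used.
#' @param path Output PNG path.
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_type_panel <- function(profile, clicks, path, width = 10, height = 8) {
  freq <- (seq_along(profile$median_spectrum) - 1) * 0.5
  spec_df <- data.frame(freq = freq, med = profile$median_spectrum,
                        p10 = profile$p10_spectrum, p90 = profile$p90_spectrum)
  p1 <- ggplot2::ggplot(spec_df, ggplot2::aes(x = freq)) +
    ggplot2::geom_line(ggplot2::aes(y = med)) +
    ggplot2::geom_line(ggplot2::aes(y = p10), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = p90), linetype = "dashed") +
    ggplot2::labs(x = "Frequency (kHz)", y = "Spectral level (dB)",
                  title = paste(profile$name, "median spectrum"))
  ici_df <- data.frame(mode = profile$modes)
  p2 <- ggplot2::ggplot(ici_df, ggplot2::aes(x = mode)) +
    ggplot2::geom_histogram(binwidth = 0.01, boundary = 0) +
    ggplot2::labs(x = "Modal ICI (s)", y = "Bins", title = "Modal ICI")
  ord <- order(clicks$clicks$pp_db)
  norm_rows <- function(m) {
    rng <- apply(m, 1, range)
    (m - rng[1, ]) / pmax(rng[2, ] - rng[1, ], 1e-12)
  }
  long <- function(m, what) {
    data.frame(row = rep(seq_len(nrow(m)), ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m), what = what)
  }
  sp <- long(norm_rows(clicks$spectra[ord, , drop = FALSE]), "spectra")
  en <- long(norm_rows(clicks$envelopes[ord, , drop = FALSE]), "envelopes")
  p3 <- ggplot2::ggplot(sp, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "Frequency bin", y = "Click (by received level)",
                  title = "Concatenated spectra") +
    ggplot2::theme(legend.position = "none")
  p4 <- ggplot2::ggplot(en, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "Envelope sample", y = "Click (by received level)",
                  title = "Concatenated envelopes") +
    ggplot2::theme(legend.position = "none")
  fig <- patchwork::wrap_plots(p1, p2, p3, p4, ncol = 2)
  ggplot2::ggsave(path, fig, width = width, height = height, dpi = 100)
  invisible(path)
}
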