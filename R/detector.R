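# Two-stage echolocation click detector. Stage 1 finds high-amplitude
# events on the band-passed, calibrated waveform; stage 2 segments
# individual impulses within each event and extracts per-click features.

#' Detector configuration
#'
#' Defaults follow the published detector: 5-pole Butterworth passband
#' 5-100 kHz, 118 dB re 1 uPa peak-to-peak threshold, events padded to
#' include all samples within 2.5 ms of each high-amplitude peak and merged
#' when separated by under 2.5 ms, impulse boundaries at the 70th percentile
#' of event energy, sub-impulses under 100 us apart merged, clipped signals
#' discarded, and candidate clicks with peak frequency below 5 kHz
#' discarded. Duration/bandwidth/envelope retention thresholds are
#' user-configurable and default to values spanning the variability of known
#' odontocete click types (so they mainly reject long narrowband pings).
#'
#' @param band_low_khz,band_high_khz Passband edges, kHz.
#' @param filter_poles Butterworth order (poles).
#' @param pp_threshold_db Stage-1 peak-to-peak threshold, dB re 1 uPa.
#' @param pp_window_us Width of the sliding window over which the waveform
#'   max-minus-min excursion is measured against the peak-to-peak
#'   threshold, us. One period of the 5 kHz lower band edge (200 us) spans
#'   a full carrier cycle of any in-band component without smearing event
#'   boundaries.
#' @param event_pad_ms Padding added around each high-amplitude region, ms.
#' @param event_merge_ms Events with gaps below this are merged, ms.
#' @param energy_percentile Percentile of event energy defining impulse
#'   boundaries (0-100).
#' @param click_merge_us Impulses closer than this are merged, us.
#' @param min_peak_freq_khz Candidate clicks with lower peak frequency are
#'   discarded.
#' @param min_duration_us,max_duration_us Retained click duration bounds, us.
#' @param min_bw3db_khz Minimum -3 dB bandwidth, kHz (rejects narrowband
#'   tonals).
#' @param energy_smooth_us Width of the moving-average window applied to
#'   squared amplitude for the energy-percentile boundary rule, us. Bridges
#'   the zero-crossing dips of the carrier while staying local in time.
#' @param clip_level Fraction of full scale treated as clipping.
#' @param n_fft FFT length (400 points at 200 kHz gives 500 Hz resolution).
#' @param n_env Envelope resample length for cross-click comparability.
#' @param db_tol Numerical tolerance (dB) applied when comparing calibrated
#'   levels against thresholds, guarding floating-point round-off at exact
#'   threshold crossings.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(band_low_khz = 5, band_high_khz = 100,
                            filter_poles = 5, pp_threshold_db = 118,
                            pp_window_us = 200,
                            event_pad_ms = 2.5, event_merge_ms = 2.5,
                            energy_percentile = 70, click_merge_us = 100,
                            min_peak_freq_khz = 5,
                            min_duration_us = 10, max_duration_us = 1500,
                            min_bw3db_khz = 0.4, energy_smooth_us = 125,
                            clip_level = 0.999,
                            n_fft = 400, n_env = 200, db_tol = 0.01) {
  stopifnot(band_low_khz > 0, band_low_khz < band_high_khz,
            energy_percentile > 0, energy_percentile < 100,
            event_pad_ms > 0, event_merge_ms > 0, click_merge_us > 0)
  structure(as.list(environment()), class = "detector_config")
}

#' Band-pass filter a waveform
#'
#' 5-pole Butterworth applied forward-backward (zero-phase) so click times
#' are not skewed by filter group delay. When the upper band edge reaches
#' Nyquist (the default 100 kHz at fs = 200 kHz) the filter degenerates to a
#' high-pass at the lower edge, which has the identical passband.
#'
#' @param x Waveform.
#' @param fs Sample rate, Hz.
#' @param cfg [detector_config()].
#' @return Filtered waveform, same length.
#' @export
bandpass <- function(x, fs, cfg = detector_config()) {
  nyq <- fs / 2
  lo <- cfg$band_low_khz * 1000
  hi <- cfg$band_high_khz * 1000
  if (lo >= nyq) stop("lower band edge at or above Nyquist")
  if (hi > nyq) stop("upper band edge above Nyquist")
  if (hi >= nyq * 0.999) {
    bf <- signal::butter(cfg$filter_poles, lo / nyq, type = "high")
  } else {
    bf <- signal::butter(cfg$filter_poles, c(lo, hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic-signal magnitude envelope
#'
#' @param x Real waveform.
#' @return Envelope (|analytic signal|), same length.
#' @export
analytic_envelope <- function(x) {
  n0 <- length(x)
  if (n0 < 2) return(abs(x))
  # pad to a 2-3-5-smooth length: fft on awkward lengths is much slower
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Smoothed per-sample energy
#'
#' Squared amplitude averaged over a short centered moving window. Raw
#' squared samples dip to zero at every carrier zero-crossing, which would
#' cut the contiguous-region boundary rule to a fraction of a carrier
#' period; the analytic envelope, conversely, is non-local in time for
#' clicks whose spectrum is truncated at Nyquist. A short moving average is
#' both smooth across carrier cycles and strictly local.
#'
#' @param x Waveform samples.
#' @param fs Sample rate, Hz.
#' @param smooth_us Window width, us.
#' @return Energy vector, same length as `x`.
#' @export
smoothed_energy <- function(x, fs, smooth_us = 125) {
  w <- max(1L, round(smooth_us * 1e-6 * fs))
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  if (w >= n) return(rep(mean(x^2), n))
  cs <- cumsum(c(0, x^2))
  h <- (w - 1L) %/% 2L
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Sliding peak-to-peak excursion
#'
#' Max-minus-min of the waveform within a centered sliding window, the
#' quantity the stage-1 threshold is applied to.
#'
#' @param x Waveform.
#' @param fs Sample rate, Hz.
#' @param window_us Window width, us.
#' @return Per-sample peak-to-peak excursion (sample units).
#' @export
sliding_p2p <- function(x, fs, window_us = 200) {
  .rolling_p2p(x, max(1L, round(window_us * 1e-6 * fs)))
}

#' Stage-1 event detection
#'
#' A sample counts as high-amplitude when the sliding peak-to-peak
#' excursion around it ([sliding_p2p()]) meets the calibrated p2p
#' threshold. High regions separated by less than `event_merge_ms` are
#' merged; the merged events are then padded by `event_pad_ms` on each side
#' (padding is clipped at the midpoint between adjacent events so the list
#' stays sorted and non-overlapping).
#'
#' @param x_filt Band-passed waveform.
#' @param fs Sample rate, Hz.
#' @param cal [calibration()].
#' @param cfg [detector_config()].
#' @param p2p Optional precomputed [sliding_p2p()] of `x_filt`.
#' @return data.frame (start_s, end_s, start_idx, end_idx, core_start_idx,
#'   core_end_idx), possibly empty; `core_*` delimit the unpadded
#'   high-amplitude region.
#' @export
detect_events <- function(x_filt, fs, cal = calibration(),
                          cfg = detector_config(), p2p = NULL) {
  if (is.null(p2p)) p2p <- sliding_p2p(x_filt, fs, cfg$pp_window_us)
  thr <- db_to_p2p(cfg$pp_threshold_db - cfg$db_tol, cal)
  runs <- logical_runs(p2p >= thr)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      core_start_idx = integer(0), core_end_idx = integer(0))
  if (nrow(runs) == 0) return(empty)
  merge_smp <- cfg$event_merge_ms * 1e-3 * fs
  # merge runs whose gap is strictly below the merge window
  merged <- list(runs[1, ])
  for (k in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    gap <- (runs[k, "start"] - last["end"] - 1) / fs * 1e3
    if (gap < cfg$event_merge_ms) {
      last["end"] <- runs[k, "end"]
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- runs[k, ]
    }
  }
  m <- do.call(rbind, merged)
  pad <- round(cfg$event_pad_ms * 1e-3 * fs)
  n <- length(x_filt)
  s <- pmax(1L, m[, "start"] - pad)
  e <- pmin(n, m[, "end"] + pad)
  if (nrow(m) > 1) {
    for (k in seq_len(nrow(m) - 1)) {
      if (e[k] >= s[k + 1]) {           # padded ranges collide: split at midpoint
        mid <- (m[k, "end"] + m[k + 1, "start"]) %/% 2
        e[k] <- mid
        s[k + 1] <- mid + 1L
      }
    }
  }
  data.frame(start_s = (s - 1) / fs, end_s = (e - 1) / fs,
             start_idx = as.integer(s), end_idx = as.integer(e),
             core_start_idx = as.integer(m[, "start"]),
             core_end_idx = as.integer(m[, "end"]))
}

#' Stage-2 impulse segmentation within one event
#'
#' Candidate impulses are runs of samples whose sliding peak-to-peak
#' excursion meets the amplitude threshold; each impulse's start/end are
#' the first and last sample of the contiguous region around its main peak
#' whose energy (smoothed squared amplitude, see [smoothed_energy()])
#' exceeds the event-wide `energy_percentile` percentile. Impulses
#' separated by less than `click_merge_us` are merged, and impulses
#' containing clipped samples are discarded.
#'
#' @param event_x Band-passed samples of one event (from [detect_events()]).
#' @param fs Sample rate, Hz.
#' @param cal [calibration()].
#' @param cfg [detector_config()].
#' @param p2p Optional precomputed [sliding_p2p()] of `event_x`.
#' @param raw_x Optional unfiltered samples of the event, used for the
#'   clipping check (defaults to `event_x`).
#' @return Integer matrix (start, end) of snippet boundaries within the
#'   event, zero rows if none survive.
#' @export
segment_clicks <- function(event_x, fs, cal = calibration(),
                           cfg = detector_config(), p2p = NULL,
                           raw_x = NULL) {
  if (is.null(p2p)) p2p <- sliding_p2p(event_x, fs, cfg$pp_window_us)
  if (is.null(raw_x)) raw_x <- event_x
  if (length(unique(event_x)) <= 1) return(cbind(start = integer(0), end = integer(0)))
  thr <- db_to_p2p(cfg$pp_threshold_db - cfg$db_tol, cal)
  energy <- smoothed_energy(event_x, fs, cfg$energy_smooth_us)
  e_thr <- quantile(energy, cfg$energy_percentile / 100, names = FALSE)
  runs <- logical_runs(p2p >= thr)
  if (nrow(runs) == 0) return(cbind(start = integer(0), end = integer(0)))
  n <- length(event_x)
  bounds <- matrix(0L, nrow(runs), 2)
  for (k in seq_len(nrow(runs))) {
    peak <- runs[k, "start"] +
      which.max(energy[runs[k, "start"]:runs[k, "end"]]) - 1L
    s <- peak
    while (s > 1L && energy[s - 1L] > e_thr) s <- s - 1L
    e <- peak
    while (e < n && energy[e + 1L] > e_thr) e <- e + 1L
    bounds[k, ] <- c(s, e)
  }
  bounds <- unique(bounds)
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  merge_us <- cfg$click_merge_us
  out <- list(bounds[1, ])
  for (k in seq_len(nrow(bounds))[-1]) {
    last <- out[[length(out)]]
    gap_us <- (bounds[k, 1] - last[2] - 1) / fs * 1e6
    if (gap_us < merge_us) {
      last[2] <- max(last[2], bounds[k, 2])
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- bounds[k, ]
    }
  }
  b <- do.call(rbind, out)
  colnames(b) <- c("start", "end")
  clipped <- vapply(seq_len(nrow(b)), function(k) {
    max(abs(raw_x[b[k, 1]:b[k, 2]])) >= cfg$clip_level
  }, logical(1))
  b[!clipped, , drop = FALSE]
}

#' Per-click features
#'
#' Spectrum: average of Hann-windowed `n_fft`-point FFT power frames at 50%
#' overlap; snippets shorter than `n_fft` samples are centered in a single
#' zero-padded frame, and Welch averaging over multiple frames is used only
#' for snippets of at least 1.5 frames. At fs = 200 kHz and 400 points the
#' one-sided spectrum has 200 bins on a 500 Hz grid (0-99.5 kHz).
#'
#' @param snippet Band-passed click samples.
#' @param fs Sample rate, Hz.
#' @param cal [calibration()].
#' @param cfg [detector_config()].
#' @param t_offset_s Time of the snippet's first sample in the recording.
#' @return A list: scalar features (start_s, end_s, peak_s, peak_freq_khz,
#'   pp_db, peak_spec_db, bw3db_khz, duration_us), `spectrum_db` (length
#'   `n_fft/2`), `envelope` (length `n_env`).
#' @export
click_features <- function(snippet, fs, cal = calibration(),
                           cfg = detector_config(), t_offset_s = 0) {
  stopifnot(length(snippet) > 0)
  nf <- cfg$n_fft
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nf) - 1) / (nf - 1))
  frame_power <- function(fr) {
    X <- fft(fr * win)
    (Mod(X)[seq_len(nf / 2)])^2
  }
  n <- length(snippet)
  if (n < 1.5 * nf) {
    fr <- numeric(nf)
    if (n >= nf) {
      mid <- (n - nf) %/% 2
      fr <- snippet[(mid + 1):(mid + nf)]
    } else {
      off <- (nf - n) %/% 2
      fr[(off + 1):(off + n)] <- snippet
    }
    P <- frame_power(fr)
  } else {
    hops <- seq(1, n - nf + 1, by = nf / 2)
    P <- rowMeans(vapply(hops, function(i) frame_power(snippet[i:(i + nf - 1)]),
                         numeric(nf / 2)))
  }
  spec_db <- 10 * log10(pmax(P, 1e-30)) + cal$db_pp_at_fullscale
  kpeak <- which.max(spec_db)
  peak_db <- spec_db[kpeak]
  within3 <- spec_db >= peak_db - 3
  lo <- kpeak
  while (lo > 1 && within3[lo - 1]) lo <- lo - 1
  hi <- kpeak
  while (hi < length(spec_db) && within3[hi + 1]) hi <- hi + 1
  bin_khz <- fs / nf / 1000
  env <- analytic_envelope(snippet)
  env200 <- approx(seq_along(env), env, n = cfg$n_env)$y
  peak_idx <- which.max(env)
  list(
    start_s = t_offset_s,
    end_s = t_offset_s + (n - 1) / fs,
    peak_s = t_offset_s + (peak_idx - 1) / fs,
    peak_freq_khz = (kpeak - 1) * bin_khz,
    pp_db = p2p_to_db(max(snippet) - min(snippet), cal),
    peak_spec_db = peak_db,
    bw3db_khz = (hi - lo + 1) * bin_khz,
    duration_us = n / fs * 1e6,
    spectrum_db = spec_db,
    envelope = env200
  )
}

#' Bundle click records into a click set
#'
#' A `click_set` holds the scalar feature table plus aligned spectrum and
#' envelope matrices (one row per click).
#'
#' @param records List of [click_features()] results.
#' @param fs Sample rate, Hz.
#' @param cal [calibration()].
#' @return Object of class `click_set` with elements `clicks` (data.frame),
#'   `spectra`, `envelopes`, `fs`, `cal`.
#' @export
click_set <- function(records, fs, cal) {
  scalars <- c("start_s", "end_s", "peak_s", "peak_freq_khz", "pp_db",
               "peak_spec_db", "bw3db_khz", "duration_us")
  if (length(records) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(scalars)),
                                 scalars))
    return(structure(list(clicks = df,
                          spectra = matrix(0, 0, 200),
                          envelopes = matrix(0, 0, 200),
                          fs = fs, cal = cal), class = "click_set"))
  }
  df <- do.call(rbind, lapply(records, function(r)
    as.data.frame(r[scalars])))
  rownames(df) <- NULL
  structure(list(
    clicks = df,
    spectra = do.call(rbind, lapply(records, `[[`, "spectrum_db")),
    envelopes = do.call(rbind, lapply(records, `[[`, "envelope")),
    fs = fs, cal = cal), class = "click_set")
}

#' @export
print.click_set <- function(x, ...) {
  cat("<click_set> ", nrow(x$clicks), " clicks, fs = ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Subset a click set
#' @param cs A `click_set`.
#' @param idx Row indices or logical mask.
#' @return A `click_set` with the selected clicks.
#' @export
subset_click_set <- function(cs, idx) {
  structure(list(clicks = cs$clicks[idx, , drop = FALSE],
                 spectra = cs$spectra[idx, , drop = FALSE],
                 envelopes = cs$envelopes[idx, , drop = FALSE],
                 fs = cs$fs, cal = cs$cal), class = "click_set")
}

#' Combine click sets
#' @param ... `click_set` objects with identical fs/cal.
#' @return Combined `click_set`.
#' @export
bind_click_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "click_set"))
    sets <- sets[[1]]
  structure(list(clicks = do.call(rbind, lapply(sets, `[[`, "clicks")),
                 spectra = do.call(rbind, lapply(sets, `[[`, "spectra")),
                 envelopes = do.call(rbind, lapply(sets, `[[`, "envelopes")),
                 fs = sets[[1]]$fs, cal = sets[[1]]$cal),
            class = "click_set")
}

#' Candidate retention rules
#'
#' Applies the user-defined retention thresholds to each candidate click:
#' peak frequency below `min_peak_freq_khz` (reason `low_peak_freq`),
#' duration outside bounds (reason `duration`), bandwidth below the minimum
#' (reason `bandwidth`). Retained records get reason `"keep"`.
#'
#' @param cs A `click_set` of candidates.
#' @param cfg [detector_config()].
#' @return List with `kept` (filtered `click_set`), `reason` (character per
#'   input click), `discarded` (data.frame of discarded scalars + reason).
#' @export
filter_candidates <- function(cs, cfg = detector_config()) {
  d <- cs$clicks
  reason <- rep("keep", nrow(d))
  reason[d$bw3db_khz < cfg$min_bw3db_khz] <- "bandwidth"
  reason[d$duration_us < cfg$min_duration_us |
           d$duration_us > cfg$max_duration_us] <- "duration"
  reason[d$peak_freq_khz < cfg$min_peak_freq_khz] <- "low_peak_freq"
  keep <- reason == "keep"
  disc <- d[!keep, , drop = FALSE]
  if (nrow(disc)) disc$reason <- reason[!keep]
  list(kept = subset_click_set(cs, keep), reason = reason, discarded = disc)
}

#' Full detection pipeline on one waveform
#'
#' Band-pass filter, stage-1 event detection, stage-2 segmentation, feature
#' extraction and candidate filtering.
#'
#' @param x Waveform in sample units, or a WAV path.
#' @param fs Sample rate, Hz (ignored when `x` is a path).
#' @param cal [calibration()].
#' @param cfg [detector_config()].
#' @param t_offset_s Recording time of the first sample (for chunked
#'   processing).
#' @return List with `clicks` (retained `click_set`), `events` (stage-1
#'   table), `discarded` (with reasons).
#' @export
detect_clicks <- function(x, fs = NULL, cal = calibration(),
                          cfg = detector_config(), t_offset_s = 0) {
  if (is.character(x)) {
    w <- read_wav(x)
    x <- w$x
    fs <- w$fs_hz
  }
  stopifnot(!is.null(fs))
  xf <- bandpass(x, fs, cfg)
  pp <- sliding_p2p(xf, fs, cfg$pp_window_us)
  ev <- detect_events(xf, fs, cal, cfg, p2p = pp)
  recs <- list()
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$start_idx[k]
    i1 <- ev$end_idx[k]
    b <- segment_clicks(xf[i0:i1], fs, cal, cfg,
                        p2p = pp[i0:i1], raw_x = x[i0:i1])
    for (j in seq_len(nrow(b))) {
      snip <- xf[(i0 + b[j, 1] - 1):(i0 + b[j, 2] - 1)]
      recs[[length(recs) + 1L]] <-
        click_features(snip, fs, cal, cfg,
                       t_offset_s = t_offset_s + (i0 + b[j, 1] - 2) / fs)
    }
  }
  cs <- click_set(recs, fs, cal)
  fc <- filter_candidates(cs, cfg)
  list(clicks = fc$kept, events = ev, discarded = fc$discarded,
       reason = fc$reason)
}
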