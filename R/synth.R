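# Synthetic soundscape generation: calibrated click trains from type
# templates, broadband noise, and confounders (sonar pings, snapping-shrimp
# impulses), with a ground-truth table for every synthesized click.

#' Draw inter-click intervals
#'
#' Lognormal ICI model parameterized so that the distribution MODE equals
#' the template's modal ICI (the statistic the type catalog reports) and the
#' coefficient of variation equals `cv`. `cv = 0` gives exactly constant
#' intervals.
#'
#' @param n Number of intervals.
#' @param modal_ici_s Modal inter-click interval, seconds.
#' @param cv Coefficient of variation (dimensionless).
#' @return Numeric vector of `n` intervals, seconds.
#' @export
draw_icis <- function(n, modal_ici_s, cv) {
  stopifnot(modal_ici_s > 0, cv >= 0)
  if (n <= 0) return(numeric(0))
  if (cv == 0) return(rep(modal_ici_s, n))
  sdlog2 <- log(1 + cv^2)
  # mode of lognormal = exp(meanlog - sdlog^2) => meanlog below
  rlnorm(n, meanlog = log(modal_ici_s) + sdlog2, sdlog = sqrt(sdlog2))
}

#' Synthesize a click train
#'
#' Places `n_clicks` copies of the template click with lognormal-jittered
#' inter-click intervals, each scaled so its peak-to-peak sample excursion
#' maps to `rl_db_pp` dB re 1 uPa through the calibration.
#'
#' @param template Template row or type name (see [click_type_templates()]).
#' @param n_clicks Number of clicks (>= 1).
#' @param rl_db_pp Peak-to-peak received level per click, dB re 1 uPa.
#'   Either a scalar or a vector of length `n_clicks`.
#' @param start_s Time of the first click onset, seconds (used in the truth
#'   table and for `bout_id` bookkeeping).
#' @param cal [calibration()] object.
#' @param fs_hz Sample rate, Hz.
#' @param seed Optional integer; when given, interval draws are seeded.
#' @param ici_jitter_cv Overrides the template's ICI jitter CV.
#' @param allow_clipping If `FALSE` (default), a requested level whose
#'   waveform would exceed full scale raises an error; set `TRUE` to
#'   synthesize deliberately clipped clicks (the detector discards them).
#' @param bout_id Identifier copied to the truth rows.
#' @return A list with `wave` (segment starting at `start_s`), `fs_hz`, and
#'   `truth`, a data.frame (click_time_s, template, rl_db_pp, bout_id) with
#'   click times at each click's envelope peak.
#' @export
synth_click_train <- function(template, n_clicks, rl_db_pp, start_s = 0,
                              cal = calibration(), fs_hz = 200000,
                              seed = NULL, ici_jitter_cv = NULL,
                              allow_clipping = FALSE, bout_id = 1L) {
  if (is.character(template)) template <- get_template(template)
  stopifnot(n_clicks >= 1)
  if (!is.null(seed)) set.seed(seed)
  cv <- if (is.null(ici_jitter_cv)) template$ici_jitter_cv else ici_jitter_cv
  snippet <- make_click_template(template, fs_hz)
  n_snip <- length(snippet)
  icis <- draw_icis(n_clicks - 1, template$modal_ici_s, cv)
  onsets_s <- cumsum(c(0, icis))
  onset_idx <- round(onsets_s * fs_hz) + 1L
  rl <- rep_len(rl_db_pp, n_clicks)
  if (any(!is.finite(rl))) stop("rl_db_pp must be finite")
  total <- onset_idx[n_clicks] + n_snip - 1L
  wave <- numeric(total)
  p2p_snip <- max(snippet) - min(snippet)
  for (k in seq_len(n_clicks)) {
    scale <- db_to_p2p(rl[k], cal) / p2p_snip
    scaled <- snippet * scale
    if (max(abs(scaled)) > 1 && !allow_clipping) {
      stop("requested level ", rl[k], " dB p2p exceeds full scale (",
           round(p2p_to_db(p2p_snip / max(abs(snippet)), cal), 1),
           " dB max); set allow_clipping = TRUE to synthesize clipped clicks")
    }
    i <- onset_idx[k]
    wave[i:(i + n_snip - 1L)] <- wave[i:(i + n_snip - 1L)] + scaled
  }
  peak_offset_s <- ((n_snip + 1) / 2 - 1) / fs_hz
  truth <- data.frame(
    click_time_s = start_s + onsets_s + peak_offset_s,
    template = template$name,
    rl_db_pp = rl,
    bout_id = bout_id,
    stringsAsFactors = FALSE
  )
  list(wave = wave, fs_hz = fs_hz, start_s = start_s, truth = truth)
}

#' Scene specification for the synthetic soundscape generator
#'
#' @param fs_hz Sample rate, Hz (nominal recorder rate 200 kHz).
#' @param duration_s Scene length, seconds.
#' @param noise_floor_db Ambient noise level expressed as the peak-to-peak
#'   dB re 1 uPa of typical background excursions; Gaussian noise is scaled
#'   so ~7 standard deviations span that excursion.
#' @param bouts List of bouts, each a list with `template` (name or row),
#'   `start_s`, `n_clicks`, `rl_db_pp`, and optionally `ici_jitter_cv`,
#'   `allow_clipping`.
#' @param confounders List of confounder specs: `list(kind = "sonar",
#'   start_s, freq_khz, duration_ms, rl_db_pp, n_pings, ping_interval_s)` for
#'   long-duration narrowband pings, or `list(kind = "shrimp", rate_per_s,
#'   rl_db_pp)` for broadband impulses at Poisson random times (cavitation
#'   bubbles snap at random, unlike the regular timing of click trains).
#' @param seed Integer seed; the whole scene is deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fs_hz = 200000, duration_s = 10, noise_floor_db = 75,
                       bouts = list(), confounders = list(), seed = 1L) {
  for (b in bouts) {
    if (b$start_s < 0 || b$start_s >= duration_s)
      stop("bout start time ", b$start_s, " outside [0, duration)")
    if (!is.finite(b$rl_db_pp)) stop("bout rl_db_pp must be finite")
  }
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 noise_floor_db = noise_floor_db, bouts = bouts,
                 confounders = confounders, seed = as.integer(seed)),
            class = "scene_spec")
}

# One sonar ping: Hann-enveloped narrowband tone.
sonar_ping <- function(freq_khz, duration_ms, fs_hz) {
  n <- max(3L, round(duration_ms * 1e-3 * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  env * cos(2 * pi * freq_khz * 1000 * t)
}

# One shrimp-like impulse: very short broadband Gabor at a random high
# frequency (snapping shrimp are broadband transients).
shrimp_snap <- function(fs_hz) {
  f <- runif(1, 40, 90)
  tpl <- data.frame(name = "shrimp", peak_freq_khz = f, bw3db_khz = 25,
                    modal_ici_s = 1, duration_us = 80, ici_jitter_cv = 0)
  comp <- data.frame(name = "shrimp", freq_khz = f, rel_amp = 1, bw_khz = 25)
  make_click_template(tpl, fs_hz, components = comp)
}

#' Synthesize a full scene
#'
#' Deterministic given the spec's seed: background Gaussian noise, all
#' click-train bouts, and confounders are generated from a single seeded RNG
#' stream. Overlapping bouts are summed with a warning (not fatal).
#'
#' @param spec A [scene_spec()].
#' @param cal A [calibration()].
#' @return A list with `wave`, `fs_hz`, `truth` (rows sorted by time; one
#'   per synthesized click, none for confounders), and `spec`.
#' @seealso [write_scene()] to write the WAV + truth CSV pair.
#' @export
synth_scene <- function(spec, cal = calibration()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs_hz)
  sd_noise <- db_to_p2p(spec$noise_floor_db, cal) / 7
  wave <- rnorm(n, sd = sd_noise)
  truth <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  for (bi in seq_along(spec$bouts)) {
    b <- spec$bouts[[bi]]
    tr <- synth_click_train(
      b$template, b$n_clicks, b$rl_db_pp, start_s = b$start_s, cal = cal,
      fs_hz = spec$fs_hz,
      ici_jitter_cv = if (is.null(b$ici_jitter_cv)) NULL else b$ici_jitter_cv,
      allow_clipping = isTRUE(b$allow_clipping), bout_id = bi
    )
    i0 <- round(b$start_s * spec$fs_hz) + 1L
    i1 <- i0 + length(tr$wave) - 1L
    if (i1 > n) {
      tr$wave <- tr$wave[seq_len(n - i0 + 1L)]
      keep <- tr$truth$click_time_s < spec$duration_s
      tr$truth <- tr$truth[keep, , drop = FALSE]
      i1 <- n
      warning("bout ", bi, " truncated at scene end")
    }
    if (nrow(occupied) > 0 &&
        any(i0 <= occupied[, 2] & i1 >= occupied[, 1])) {
      warning("bout ", bi, " overlaps an earlier bout; waveforms summed")
    }
    occupied <- rbind(occupied, c(i0, i1))
    wave[i0:i1] <- wave[i0:i1] + tr$wave
    truth[[length(truth) + 1L]] <- tr$truth
  }
  for (cf in spec$confounders) {
    if (identical(cf$kind, "sonar")) {
      ping <- sonar_ping(cf$freq_khz, cf$duration_ms, spec$fs_hz)
      ping <- ping * db_to_p2p(cf$rl_db_pp, cal) / (max(ping) - min(ping))
      n_pings <- if (is.null(cf$n_pings)) 1L else cf$n_pings
      gap <- if (is.null(cf$ping_interval_s)) 1 else cf$ping_interval_s
      for (k in seq_len(n_pings)) {
        i0 <- round((cf$start_s + (k - 1) * gap) * spec$fs_hz) + 1L
        i1 <- min(n, i0 + length(ping) - 1L)
        if (i0 > n) break
        wave[i0:i1] <- wave[i0:i1] + ping[seq_len(i1 - i0 + 1L)]
      }
    } else if (identical(cf$kind, "shrimp")) {
      n_snaps <- rpois(1, cf$rate_per_s * spec$duration_s)
      times <- sort(runif(n_snaps, 0, spec$duration_s))
      for (tt in times) {
        snap <- shrimp_snap(spec$fs_hz)
        snap <- snap * db_to_p2p(cf$rl_db_pp, cal) / (max(snap) - min(snap))
        i0 <- round(tt * spec$fs_hz) + 1L
        i1 <- min(n, i0 + length(snap) - 1L)
        if (i0 > n) next
        wave[i0:i1] <- wave[i0:i1] + snap[seq_len(i1 - i0 + 1L)]
      }
    } else {
      stop("unknown confounder kind: ", cf$kind)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(click_time_s = numeric(0), template = character(0),
               rl_db_pp = numeric(0), bout_id = integer(0))
  truth <- truth[order(truth$click_time_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(wave = wave, fs_hz = spec$fs_hz, truth = truth, spec = spec)
}

#' Write a scene to disk (16-bit PCM WAV + truth CSV)
#'
#' @param scene Result of [synth_scene()].
#' @param wav_path,truth_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_scene <- function(scene, wav_path, truth_path) {
  write_wav(scene$wave, wav_path, scene$fs_hz)
  write.csv(scene$truth, truth_path, row.names = FALSE)
  invisible(list(wav = wav_path, truth = truth_path))
}
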