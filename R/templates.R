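# Click-type templates. Parameter values (peak frequency, -3 dB bandwidth,
# modal ICI) follow the published catalog of fourteen western North Atlantic
# click types; durations, ICI jitter and multi-peak component structure are
# package defaults chosen to emulate the described spectra.

#' Catalog of click-type templates
#'
#' Fourteen odontocete click types: eight attributable to known species or
#' genera (Gg Risso's dolphin, Mb Sowerby's, Md Blainville's, Me Gervais',
#' Mm True's, Zc Cuvier's beaked whales, Kogia, Pm sperm whale) and six
#' unidentified delphinid ("UD") types named by median peak frequency in
#' kHz. `peak_freq_khz`, `bw3db_khz` and `modal_ici_s` are the published
#' median signal parameters; `duration_us` (click duration) and
#' `ici_jitter_cv` (coefficient of variation of the lognormal inter-click
#' interval) are synthesis defaults, since amplitude/duration distributions
#' per type are not published.
#'
#' The Kogia type is a near-Nyquist case at the nominal 200 kHz sample rate:
#' its narrow-band high-frequency spectrum is only partially captured below
#' the 100 kHz Nyquist limit.
#'
#' @return A data.frame with one row per type.
#' @seealso [click_type_components()] for multi-peak structure,
#'   [make_click_template()] to synthesize a waveform.
#' @export
click_type_templates <- function() {
  df <- data.frame(
    name          = c("Gg", "Mb", "Md", "Me", "Mm", "Zc", "Kogia", "Pm",
                      "UD36", "UD26", "UD28", "UD19", "UD47", "UD38"),
    peak_freq_khz = c(32.5, 67.0, 31.5, 46.5, 47.5, 38.5, 99.5, 8.5,
                      36.5, 26.5, 28.5, 19.0, 47.0, 38.5),
    bw3db_khz     = c(4.5, 13.5, 7.5, 11.5, 11.3, 7.0, 7.0, 3.0,
                      5.5, 4.0, 9.0, 9.0, 6.5, 8.0),
    modal_ici_s   = c(0.145, 0.135, 0.325, 0.285, 0.185, 0.465, 0.085, 0.475,
                      0.155, 0.165, 0.075, 0.135, 0.065, 0.065),
    duration_us   = c(360, 500, 500, 500, 500, 500, 300, 600,
                      300, 400, 200, 200, 250, 200),
    ici_jitter_cv = 0.15,
    stringsAsFactors = FALSE
  )
  df
}

#' Spectral components of multi-peaked click types
#'
#' Several types have multi-peaked spectra (e.g. Risso's dolphin with
#' auxiliary peaks at 23.5 and 27 kHz below its 32.5 kHz main peak, Cuvier's
#' beaked whale with auxiliary peaks near 23.5, 19 and 72 kHz, UD26 with a
#' deep notch between its ~19 kHz and ~29 kHz lobes). Templates are
#' synthesized as sums of Gaussian-windowed sinusoid (Gabor) components;
#' this table gives, per type, each component's center frequency, relative
#' amplitude and -3 dB bandwidth. Types absent from the table are
#' single-component.
#'
#' @return A data.frame (name, freq_khz, rel_amp, bw_khz). The main
#'   component (rel_amp = 1) carries the type's nominal peak frequency and
#'   bandwidth.
#' @export
click_type_components <- function() {
  tpl <- click_type_templates()
  main <- data.frame(name = tpl$name, freq_khz = tpl$peak_freq_khz,
                     rel_amp = 1, bw_khz = tpl$bw3db_khz,
                     stringsAsFactors = FALSE)
  aux <- data.frame(
    name     = c("Gg", "Gg", "Zc", "Zc", "Zc", "Me", "Mm",
                 "UD36", "UD36", "UD26", "UD47", "UD47", "UD38", "UD38"),
    freq_khz = c(23.5, 27.0, 23.5, 19.0, 72.0, 23.5, 24.5,
                 26.0, 23.0, 19.0, 20.0, 28.0, 16.0, 19.0),
    rel_amp  = c(0.40, 0.40, 0.55, 0.40, 0.30, 0.30, 0.30,
                 0.50, 0.40, 0.80, 0.40, 0.45, 0.35, 0.35),
    bw_khz   = c(2.5, 2, 3, 3, 5, 3, 3,
                 3, 3, 2.5, 2, 2, 2, 2),
    stringsAsFactors = FALSE
  )
  rbind(main, aux)
}

#' Look up one template row by name
#' @param name Type name, e.g. `"Gg"` or `"UD28"`.
#' @return One-row data.frame.
#' @export
get_template <- function(name) {
  tpl <- click_type_templates()
  row <- tpl[tpl$name == name, ]
  if (nrow(row) != 1) stop("unknown click type template: ", name)
  row
}

# Gaussian time-sigma (seconds) giving a -3 dB (half-power) spectral width
# bw_hz for a Gabor click: BW3dB = sqrt(ln 2) / (pi * sigma_t).
gabor_sigma_t <- function(bw_hz) sqrt(log(2)) / (pi * bw_hz)

#' Synthesize a unit-peak click waveform from a template
#'
#' The click model is a sum of Gaussian-enveloped sinusoids (Gabor
#' components): independently controllable peak frequency, -3 dB bandwidth
#' and duration. Returned snippet is normalized to unit peak amplitude and
#' truncated to the template duration.
#'
#' @param template A one-row template data.frame (see
#'   [click_type_templates()]) or a type name.
#' @param fs_hz Sample rate, Hz.
#' @param components Optional component table ([click_type_components()]
#'   layout); defaults to the package table, or a single component at the
#'   template's peak/bandwidth if the type is not listed.
#' @return Numeric waveform snippet, unit peak amplitude, cosine phase at
#'   the envelope center.
#' @details The main component frequency must lie at or below the Nyquist
#'   frequency; near-Nyquist types (Kogia at 99.5 kHz for fs = 200 kHz) are
#'   allowed and their spectrum is truncated at Nyquist. Auxiliary
#'   components above Nyquist are dropped.
#' @export
make_click_template <- function(template, fs_hz, components = NULL) {
  if (is.character(template)) template <- get_template(template)
  stopifnot(nrow(template) == 1)
  if (template$duration_us <= 0) stop("click duration must be positive")
  nyq <- fs_hz / 2
  if (template$peak_freq_khz * 1000 > nyq) {
    stop("peak frequency ", template$peak_freq_khz,
         " kHz exceeds Nyquist (", nyq / 1000, " kHz)")
  }
  if (is.null(components)) {
    comp <- click_type_components()
    comp <- comp[comp$name == template$name, ]
    if (nrow(comp) == 0) {
      comp <- data.frame(name = template$name,
                         freq_khz = template$peak_freq_khz,
                         rel_amp = 1, bw_khz = template$bw3db_khz)
    }
  } else {
    comp <- components
  }
  comp <- comp[comp$freq_khz * 1000 <= nyq, , drop = FALSE]
  dur_s <- template$duration_us * 1e-6
  n <- max(3L, round(dur_s * fs_hz))
  if (n %% 2 == 0) n <- n + 1L  # odd so the envelope peak is a sample
  t <- (seq_len(n) - (n + 1) / 2) / fs_hz
  x <- numeric(n)
  # rel_amp is the relative SPECTRAL peak height; a Gabor's spectral peak
  # scales with its time sigma, so time-domain amplitudes are compensated.
  sig <- gabor_sigma_t(comp$bw_khz * 1000)
  sig_ref <- sig[which.max(comp$rel_amp)]
  for (k in seq_len(nrow(comp))) {
    x <- x + comp$rel_amp[k] * (sig_ref / sig[k]) *
      exp(-t^2 / (2 * sig[k]^2)) *
      cos(2 * pi * comp$freq_khz[k] * 1000 * t)
  }
  x / max(abs(x))
}
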