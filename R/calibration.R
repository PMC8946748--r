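#' Scalar recorder calibration
#'
#' Maps dimensionless sample units (full scale = +-1) to sound pressure in
#' micro-Pascal. A single scalar is used: `db_pp_at_fullscale` is the
#' peak-to-peak sound pressure level, in dB re 1 uPa, that a full-scale
#' waveform excursion (from -1 to +1) represents. Frequency-dependent
#' hydrophone sensitivity is intentionally out of scope.
#'
#' @param db_pp_at_fullscale Peak-to-peak level (dB re 1 uPa) of a
#'   full-scale excursion. Default 140, comfortably above the 118 dB
#'   detection threshold so typical click levels (110-130 dB p2p) are
#'   representable without clipping.
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration(140)
#' p2p_to_db(db_to_p2p(125, cal), cal) # 125
#' @export
calibration <- function(db_pp_at_fullscale = 140) {
  stopifnot(is.numeric(db_pp_at_fullscale), length(db_pp_at_fullscale) == 1,
            is.finite(db_pp_at_fullscale))
  structure(list(db_pp_at_fullscale = db_pp_at_fullscale),
            class = "calibration")
}

#' @rdname calibration
#' @param db Peak-to-peak level(s), dB re 1 uPa.
#' @param cal A [calibration()] object.
#' @return `db_to_p2p()`: peak-to-peak excursion in sample units (full scale
#'   p2p = 2).
#' @export
db_to_p2p <- function(db, cal) {
  2 * 10^((db - cal$db_pp_at_fullscale) / 20)
}

#' @rdname calibration
#' @param p2p Peak-to-peak excursion(s) in sample units.
#' @export
p2p_to_db <- function(p2p, cal) {
  cal$db_pp_at_fullscale + 20 * log10(p2p / 2)
}
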