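# Transit-time physics: how long an object takes to cross the illumination
# slit, and the widths/thresholds that follow from it.

#' Transit width of an object crossing the illumination slit
#'
#' An object of physical length \eqn{L} moving at the flow speed \eqn{v}
#' occupies the detector for \eqn{(L + s)/v} seconds, where \eqn{s} is the
#' slit width: the signal rises when the leading edge enters the slit and
#' falls when the trailing edge leaves it. At sampling rate \eqn{f} the pulse
#' base width is \eqn{(L + s)/v \cdot f} samples, returned unrounded.
#'
#' A large single cell (15 um) at the instrument defaults (5 um slit,
#' 55.6 mm/s, 60 kHz) spans about 21.6 samples; a two-cell cluster
#' (26 um) about 33.5.
#'
#' @param object_length_um Object length in micrometres (>= 0; 0 gives the
#'   slit-only transit).
#' @param slit_width_um Illumination slit width in micrometres (default 5).
#' @param flow_speed_mm_s Flow speed in mm/s (default 55.6).
#' @param sample_rate Sampling rate in samples/s (default 60000).
#' @return Transit width in samples (real-valued).
#' @examples
#' transit_width_points(15) # ~21.6 samples
#' @export
transit_width_points <- function(object_length_um, slit_width_um = 5,
                                 flow_speed_mm_s = 55.6, sample_rate = 60000) {
  if (any(object_length_um < 0)) {
    stop_invalid("`object_length_um` must be >= 0")
  }
  if (slit_width_um <= 0 || flow_speed_mm_s <= 0 || sample_rate <= 0) {
    stop_invalid("slit width, flow speed and sample rate must all be positive")
  }
  # um -> mm: 1e-3; seconds * sample_rate -> samples
  (object_length_um + slit_width_um) * 1e-3 / flow_speed_mm_s * sample_rate
}

#' FWHM gate derived from a maximum single-cell transit width
#'
#' Multicellular events are separated from single cells by a full-width-at-
#' half-maximum threshold: the maximum single-cell transit width is scaled by
#' a conservative FWHM/base-width fraction (0.75) and rounded half-up to an
#' integer number of samples.
#'
#' @param max_transit Maximum single-cell transit width in samples (> 0).
#' @param fwhm_fraction Ratio of FWHM to full peak width, in (0, 1]
#'   (default 0.75).
#' @return Integer threshold in samples.
#' @examples
#' fwhm_gate_from_transit(22) # 17
#' @seealso [width_gate_threshold()] for the full derivation from cell size.
#' @export
fwhm_gate_from_transit <- function(max_transit, fwhm_fraction = 0.75) {
  if (max_transit <= 0) stop_invalid("`max_transit` must be positive")
  if (fwhm_fraction <= 0 || fwhm_fraction > 1) {
    stop_invalid("`fwhm_fraction` must be in (0, 1]")
  }
  as.integer(round_half_up(fwhm_fraction * max_transit))
}

#' Multicellular width-gate threshold from first principles
#'
#' Derives the FWHM gate from the largest single event expected in blood: the
#' transit width of a `max_cell_um` cell is computed, rounded up to whole
#' samples (a 15 um cell spans 21-22 points, and the conservative bound is
#' the upper one), and scaled by `fwhm_fraction`. At the instrument defaults
#' this yields the 17-sample gate.
#'
#' @inheritParams transit_width_points
#' @inheritParams fwhm_gate_from_transit
#' @param max_cell_um Largest single-cell (large CTC or white blood cell)
#'   length in micrometres (default 15).
#' @return Integer gate in samples.
#' @examples
#' width_gate_threshold() # 17
#' @export
width_gate_threshold <- function(max_cell_um = 15, slit_width_um = 5,
                                 flow_speed_mm_s = 55.6, sample_rate = 60000,
                                 fwhm_fraction = 0.75) {
  transit <- transit_width_points(max_cell_um, slit_width_um,
                                  flow_speed_mm_s, sample_rate)
  fwhm_gate_from_transit(ceiling(transit), fwhm_fraction)
}

#' Volumetric throughput of a rectangular microfluidic channel
#'
#' Cross-sectional area times mean flow speed, converted to microlitres per
#' minute. The 30 x 30 um^2 channel at 55.6 mm/s processes about 3 uL/min.
#'
#' @param channel_width_um,channel_height_um Channel cross-section in
#'   micrometres (> 0).
#' @param flow_speed_mm_s Flow speed in mm/s (> 0).
#' @return Throughput in uL/min (real-valued).
#' @examples
#' volumetric_throughput(30, 30, 55.6) # ~3 uL/min
#' @export
volumetric_throughput <- function(channel_width_um, channel_height_um,
                                  flow_speed_mm_s) {
  if (channel_width_um <= 0 || channel_height_um <= 0 || flow_speed_mm_s <= 0) {
    stop_invalid("channel dimensions and flow speed must be positive")
  }
  # um^2 * mm/s = 1e-12 m^2 * 1e-3 m/s = 1e-15 m^3/s = 1e-6 uL/s
  channel_width_um * channel_height_um * flow_speed_mm_s * 1e-6 * 60
}
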