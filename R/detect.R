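# Region-of-interest detection: blood-clot baseline correction, zero-phase
# band-pass filtering, per-segment normalization, principal-component
# Hotelling T^2 anomaly scoring, peak extraction with shoulder-equalized
# FWHM, and the multicellular width gate.

#' Detection parameters
#'
#' Thresholds and settings of the ROI detection chain. Defaults are the
#' operating values: clots are declared when the cumulative-scatter standard
#' deviation exceeds 1.75 V (variance 3.06 V^2, three standard deviations
#' above the expected 1.132 V^2 baseline), corrected with a 500-sample
#' moving average for at most three iterations; scatter channels are
#' band-pass filtered 50-10000 Hz with a second-order Butterworth applied
#' zero-phase; anomaly scores above 10 seed event ranges; events narrower
#' than 17 samples equalized FWHM are removed as single cells.
#'
#' @param clot_std_threshold Clot detection threshold on the cumulative
#'   scatter standard deviation, volts (strict `>`).
#' @param clot_variance_threshold Variance threshold (V^2) that triggers
#'   baseline correction (strict `>`).
#' @param moving_average_window Moving-average window, samples.
#' @param max_clot_iterations Maximum correction iterations.
#' @param butterworth_order Filter order (applied forward and backward).
#' @param band Pass band in Hz, `c(low, high)`; `high` must be below the
#'   Nyquist frequency.
#' @param t2_threshold Hotelling T^2 threshold (dimensionless, strict `>`).
#' @param min_fwhm Width gate in samples (inclusive: events with FWHM `>=`
#'   this survive).
#' @param n_principal_components Principal components retained in the T^2
#'   sum (`NULL` or `3` keeps all, making T^2 the squared Mahalanobis
#'   distance).
#' @param gfp_threshold_sd Amplitude threshold for the green ground-truth
#'   channel, in multiples of its baseline standard deviation.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(clot_std_threshold = 1.75,
                             clot_variance_threshold = 3.06,
                             moving_average_window = 500L,
                             max_clot_iterations = 3L,
                             butterworth_order = 2L,
                             band = c(50, 10000),
                             t2_threshold = 10,
                             min_fwhm = 17L,
                             n_principal_components = 2L,
                             gfp_threshold_sd = 5) {
  if (band[1] <= 0 || band[2] <= band[1]) {
    stop_invalid("`band` must satisfy 0 < low < high")
  }
  if (clot_std_threshold <= 0 || clot_variance_threshold <= 0 ||
      t2_threshold <= 0 || min_fwhm <= 0) {
    stop_invalid("thresholds must be positive")
  }
  structure(list(clot_std_threshold = clot_std_threshold,
                 clot_variance_threshold = clot_variance_threshold,
                 moving_average_window = as.integer(moving_average_window),
                 max_clot_iterations = as.integer(max_clot_iterations),
                 butterworth_order = as.integer(butterworth_order),
                 band = band, t2_threshold = t2_threshold,
                 min_fwhm = as.integer(min_fwhm),
                 n_principal_components = n_principal_components,
                 gfp_threshold_sd = gfp_threshold_sd),
            class = "detection_params")
}

#' Cumulative scatter signal
#'
#' Element-wise sum of the three independent scatter channels. With
#' uncorrelated baselines the cumulative variance is the sum of the channel
#' variances (about 1.132 V^2 at the nominal baselines).
#'
#' @param segment A `trace_segment`.
#' @return Numeric vector, volts.
#' @export
cumulative_scatter <- function(segment) {
  rowSums(segment$data[, scatter_channels(), drop = FALSE])
}

#' Detect a blood clot in a segment
#'
#' A clot is declared when the sample standard deviation of the cumulative
#' scatter signal strictly exceeds the clot threshold (default 1.75 V).
#'
#' @param cumulative Cumulative scatter signal (length >= 2).
#' @param params [detection_params()].
#' @return Logical flag.
#' @export
detect_clot <- function(cumulative, params = detection_params()) {
  if (length(cumulative) < 2L) stop_invalid("need at least 2 samples")
  stats::sd(cumulative) > params$clot_std_threshold
}

#' Correct blood-clot baseline drift
#'
#' When the cumulative-scatter variance exceeds the variance threshold
#' (3.06 V^2), each scatter channel has its centered moving-average baseline
#' subtracted and the channel's pre-subtraction global mean added back
#' (zero-mean residual plus original mean), repeating until the cumulative
#' standard deviation falls below 1.75 V or three iterations have run.
#' Clean segments are returned unchanged with `iterations = 0`.
#'
#' @param segment A `trace_segment`.
#' @param params [detection_params()].
#' @return List with `segment` (corrected) and `report` (class
#'   `clot_report`: `detected`, `initial_std`, `final_std`, `iterations`).
#' @export
correct_clot <- function(segment, params = detection_params()) {
  cum <- cumulative_scatter(segment)
  initial_std <- stats::sd(cum)
  w <- params$moving_average_window
  if (w > n_samples(segment)) {
    warning("moving-average window longer than segment; shrunk to segment length")
    w <- n_samples(segment)
  }
  detected <- stats::var(cum) > params$clot_variance_threshold
  iterations <- 0L
  if (detected) {
    while (iterations < params$max_clot_iterations &&
           stats::sd(cum) > params$clot_std_threshold) {
      for (ch in scatter_channels()) {
        x <- segment$data[, ch]
        m <- mean(x)
        resid <- x - moving_average(x, w)
        segment$data[, ch] <- resid - mean(resid) + m
      }
      cum <- cumulative_scatter(segment)
      iterations <- iterations + 1L
    }
  }
  report <- structure(list(detected = detected, initial_std = initial_std,
                           final_std = stats::sd(cum),
                           iterations = iterations),
                      class = "clot_report")
  list(segment = segment, report = report)
}

#' @export
print.clot_report <- function(x, ...) {
  cat(sprintf("clot_report: detected=%s initial_std=%.3f V final_std=%.3f V iterations=%d\n",
              x$detected, x$initial_std, x$final_std, x$iterations))
  invisible(x)
}

butter_filter <- function(params, sample_rate) {
  nyq <- sample_rate / 2
  if (params$band[2] >= nyq) {
    stop_invalid("band upper edge (", params$band[2],
                 " Hz) must be below the Nyquist frequency (", nyq, " Hz)")
  }
  signal::butter(params$butterworth_order, params$band / nyq, type = "pass")
}

#' Band-pass filter the scatter channels
#'
#' Second-order Butterworth band-pass (default 50-10000 Hz) applied
#' zero-phase (forward-backward), so peak locations are not shifted; output
#' length equals input length.
#'
#' @param segment A `trace_segment`.
#' @param params [detection_params()].
#' @param channels Channels to filter (default the three scatter channels).
#' @return The filtered segment.
#' @export
bandpass_filter <- function(segment, params = detection_params(),
                            channels = scatter_channels()) {
  bf <- butter_filter(params, segment$sample_rate)
  for (ch in intersect(channels, colnames(segment$data))) {
    segment$data[, ch] <- signal::filtfilt(bf, segment$data[, ch])
  }
  segment
}

#' Normalize scatter channels to [0, 1]
#'
#' Each scatter channel is affinely mapped so its segment minimum becomes 0
#' and maximum becomes 1, after dividing out an optional per-day laser power
#' factor. A constant channel is set to 0 with a warning.
#'
#' @param segment A `trace_segment`.
#' @param day_power_reference Multiplicative power factor to divide out
#'   (default 1).
#' @return The normalized segment.
#' @export
normalize_segment <- function(segment, day_power_reference = 1) {
  for (ch in scatter_channels()) {
    x <- segment$data[, ch] / day_power_reference
    rng <- range(x)
    if (rng[2] == rng[1]) {
      warning("channel ", ch, " is constant; set to 0")
      segment$data[, ch] <- 0
    } else {
      segment$data[, ch] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  segment
}

#' Hotelling T^2 anomaly trace
#'
#' Treats each time sample as a 3-feature observation (the normalized
#' scatter channels), computes principal components on the segment's own
#' observations, and scores every sample as the sum over the retained
#' components of score^2 / component variance. With all three components
#' retained this equals the squared Mahalanobis distance from the segment
#' centroid; with the default two components it measures distance within the
#' dominant-variance plane. Large values flag samples unlike the
#' blood-background baseline.
#'
#' @param segment A normalized `trace_segment`.
#' @param params [detection_params()]; `n_principal_components` selects the
#'   retained components.
#' @return Numeric vector of T^2 scores (dimensionless, >= 0).
#' @export
hotelling_t2_trace <- function(segment, params = detection_params()) {
  x <- segment$data[, scatter_channels(), drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  s <- crossprod(xc) / (nrow(xc) - 1)
  e <- eigen(s, symmetric = TRUE)
  k <- params$n_principal_components
  if (is.null(k)) k <- 3L
  k <- min(k, 3L)
  tol <- max(e$values) * 1e-12
  keep <- which(e$values[seq_len(k)] > tol)
  if (length(keep) < k) {
    warning("zero-variance principal component(s) excluded from the T^2 sum")
  }
  if (length(keep) == 0L) return(numeric(nrow(xc)))
  scores <- xc %*% e$vectors[, keep, drop = FALSE]
  drop(scores^2 %*% (1 / e$values[keep]))
}

#' Extract event ranges from an anomaly trace
#'
#' Contiguous runs where the T^2 trace strictly exceeds the threshold become
#' event ranges; within each range only the tallest local maximum is kept as
#' the event peak, so a range containing several local peaks is labelled as
#' a single (cluster) event.
#'
#' @param t2 Anomaly trace (>= 0 everywhere).
#' @param params [detection_params()].
#' @return Data frame with `start_index`, `peak_index`, `end_index`
#'   (1-based, inclusive) and `peak_t2`; zero rows for a flat trace.
#' @export
find_rois <- function(t2, params = detection_params()) {
  if (any(t2 < 0)) stop_invalid("T^2 trace must be non-negative")
  above <- t2 > params$t2_threshold
  if (!any(above)) {
    return(data.frame(start_index = integer(0), peak_index = integer(0),
                      end_index = integer(0), peak_t2 = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  start_index <- starts[runs]
  end_index <- ends[runs]
  peak_index <- integer(length(runs))
  peak_t2 <- numeric(length(runs))
  for (i in seq_along(runs)) {
    seg <- t2[start_index[i]:end_index[i]]
    j <- which.max(seg)
    peak_index[i] <- start_index[i] + j - 1L
    peak_t2[i] <- seg[j]
  }
  data.frame(start_index = start_index, peak_index = peak_index,
             end_index = end_index, peak_t2 = peak_t2)
}

#' Geometric height equalization of a peak waveform
#'
#' Rescales every local maximum of the region to exactly 1 and divides the
#' samples between consecutive maxima by the straight line joining their
#' original heights, so a lower-amplitude shoulder no longer narrows the
#' measured FWHM. A single-maximum region is simply divided by its peak
#' height; an all-zero region is returned unchanged with a warning.
#'
#' @param w Numeric waveform over one region of interest.
#' @return Equalized waveform of the same length.
#' @export
equalize_heights <- function(w) {
  if (all(w == 0)) {
    warning("all-zero region; equalization skipped")
    return(w)
  }
  peaks <- local_maxima(w)
  n <- length(w)
  if (length(peaks) == 1L) return(w / w[peaks])
  divisor <- numeric(n)
  divisor[seq_len(peaks[1])] <- w[peaks[1]]
  for (i in seq_len(length(peaks) - 1L)) {
    a <- peaks[i]; b <- peaks[i + 1L]
    divisor[a:b] <- w[a] + (w[b] - w[a]) * (0:(b - a)) / (b - a)
  }
  divisor[peaks[length(peaks)]:n] <- w[peaks[length(peaks)]]
  w / divisor
}

#' Measure FWHM on an equalized waveform
#'
#' Width of the half-maximum (>= 0.5 of the peak value) run containing the
#' peak, with sub-sample linear interpolation at the two crossings, rounded
#' half-up to an integer number of samples. If no half-maximum crossing
#' exists inside the region on either side, the region length is returned
#' with attribute `flagged = TRUE`.
#'
#' @param w Equalized waveform (peak value 1 at `peak_index`).
#' @param peak_index Index of the event peak within `w`.
#' @param round Round to the nearest integer (default `TRUE`); `FALSE`
#'   returns the interpolated sub-sample width.
#' @return FWHM in samples (>= 1), possibly with attribute `flagged`.
#' @export
measure_fwhm <- function(w, peak_index, round = TRUE) {
  n <- length(w)
  half <- w[peak_index] / 2
  left <- NA_real_
  for (i in seq(peak_index, 1L)) {
    if (w[i] < half) {
      left <- i + (half - w[i]) / (w[i + 1L] - w[i])
      break
    }
  }
  right <- NA_real_
  if (peak_index < n) {
    for (i in seq(peak_index + 1L, n)) {
      if (w[i] < half) {
        right <- i - 1L + (half - w[i - 1L]) / (w[i] - w[i - 1L])
        break
      }
    }
  }
  if (is.na(left) && is.na(right)) {
    out <- n
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (is.na(left)) left <- 1
  if (is.na(right)) right <- n
  if (!round) return(right - left)
  max(1L, as.integer(round_half_up(right - left)))
}

#' Remove events narrower than the multicellular gate
#'
#' Pure filter: retains exactly the events whose equalized FWHM is greater
#' than or equal to `min_fwhm` (default 17 samples); events narrower than
#' the gate are single cells and are removed.
#'
#' @param events Data frame carrying `fwhm_samples`.
#' @param params [detection_params()].
#' @return The surviving subset, same columns.
#' @export
width_gate <- function(events, params = detection_params()) {
  events[events$fwhm_samples >= params$min_fwhm, , drop = FALSE]
}

characterize_events <- function(trace, events, intensity = trace) {
  nvec <- nrow(events)
  fwhm <- integer(nvec)
  for (i in seq_len(nvec)) {
    rows <- events$start_index[i]:events$end_index[i]
    w <- trace[rows]
    eq <- suppressWarnings(equalize_heights(w))
    fwhm[i] <- as.integer(measure_fwhm(eq, events$peak_index[i] - events$start_index[i] + 1L))
  }
  events$fwhm_samples <- fwhm
  events$peak_intensity <- intensity[events$peak_index]
  events
}

#' Detect scatter regions of interest in one segment
#'
#' The full stage-one chain: clot detection/correction, zero-phase band-pass
#' filtering, per-segment normalization, Hotelling T^2 scoring, event-range
#' extraction, shoulder-equalized FWHM measurement, and (optionally) the
#' multicellular width gate.
#'
#' @param segment A `trace_segment` of raw voltages.
#' @param params [detection_params()].
#' @param day_power_reference Per-day power factor divided out before
#'   normalization.
#' @param apply_gate Apply the width gate (default `TRUE`).
#' @return List with `events` (peak-table rows: `segment_id`,
#'   `channel_group = "scatter_cumulative"`, `peak_index`, `start_index`,
#'   `end_index`, `fwhm_samples`, `peak_intensity`, `t2_score`),
#'   `clot_report`, and `t2` (the anomaly trace).
#' @export
detect_rois <- function(segment, params = detection_params(),
                        day_power_reference = 1, apply_gate = TRUE) {
  corrected <- correct_clot(segment, params)
  seg <- bandpass_filter(corrected$segment, params)
  seg <- normalize_segment(seg, day_power_reference)
  t2 <- hotelling_t2_trace(seg, params)
  events <- find_rois(t2, params)
  events <- characterize_events(t2, events)
  if (apply_gate) events <- width_gate(events, params)
  events <- data.frame(segment_id = rep(segment$segment_id, nrow(events)),
                       channel_group = rep("scatter_cumulative", nrow(events)),
                       peak_index = events$peak_index,
                       start_index = events$start_index,
                       end_index = events$end_index,
                       fwhm_samples = events$fwhm_samples,
                       peak_intensity = events$peak_intensity,
                       t2_score = events$peak_t2,
                       stringsAsFactors = FALSE)
  list(events = events, clot_report = corrected$report, t2 = t2)
}

#' Detect ground-truth regions in the green-fluorescence channel
#'
#' Applies the same filter / threshold / peak-extraction / equalized-FWHM
#' chain to the green exogenous-fluorescence channel, with an amplitude
#' threshold (multiples of the filtered channel's standard deviation) in
#' place of the T^2 score. The resulting regions serve as ground-truth
#' labels for spiked clusters and are never used as classifier input.
#'
#' @param segment A `trace_segment` containing a `gfp525` channel.
#' @param params [detection_params()].
#' @return Data frame of peak-table rows with `channel_group = "gfp"` and
#'   `t2_score = NA`.
#' @export
detect_gfp_rois <- function(segment, params = detection_params()) {
  if (!"gfp525" %in% colnames(segment$data)) {
    stop_invalid("segment has no gfp525 channel")
  }
  bf <- butter_filter(params, segment$sample_rate)
  g <- signal::filtfilt(bf, channel(segment, "gfp525"))
  thr <- params$gfp_threshold_sd * stats::sd(g)
  above <- g > thr
  if (!any(above)) {
    events <- data.frame(start_index = integer(0), peak_index = integer(0),
                         end_index = integer(0), peak_t2 = numeric(0))
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    events <- data.frame(start_index = starts[runs], peak_index = NA_integer_,
                         end_index = ends[runs], peak_t2 = NA_real_)
    for (i in seq_len(nrow(events))) {
      seg_vals <- g[events$start_index[i]:events$end_index[i]]
      events$peak_index[i] <- events$start_index[i] + which.max(seg_vals) - 1L
    }
  }
  events <- characterize_events(g, events)
  data.frame(segment_id = rep(segment$segment_id, nrow(events)),
             channel_group = rep("gfp", nrow(events)),
             peak_index = events$peak_index,
             start_index = events$start_index,
             end_index = events$end_index,
             fwhm_samples = events$fwhm_samples,
             peak_intensity = events$peak_intensity,
             t2_score = rep(NA_real_, nrow(events)),
             stringsAsFactors = FALSE)
}
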