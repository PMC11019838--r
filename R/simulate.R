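# Synthetic backscatter flow cytometry trace generator. Emulates the
# acquisition statistically: per-channel baseline variances, blood-clot
# baseline drift, single-cell and cluster peaks with transit-time widths,
# co-located green-fluorescence peaks for spiked clusters, optional
# autofluorescent confounders, and day-to-day laser power variation.

#' Simulation configuration
#'
#' Holds every tunable of the synthetic trace generator. Defaults reproduce
#' the acquisition conditions: 60 kHz sampling, 90 s segments, 55.6 mm/s
#' flow through a 5 um slit, and baseline variances of 0.169, 0.452 and
#' 0.511 V^2 on the 405/488/633 nm scatter channels.
#'
#' Event rates are Poisson intensities. Cluster sizes are drawn from a
#' three-class distribution (2 cells, 3-6 cells, 6+ cells) mapped to physical
#' length in micrometres. Peak amplitudes are per-channel means in volts with
#' a common log-normal event-to-event factor (`amplitude_sdlog`); the 405 nm
#' channel carries the highest signal-to-background ratio. Confounder events
#' (wide, cluster-like scatter peaks with weak green signal and some red
#' autofluorescence, mimicking white-blood-cell aggregates) and day-to-day
#' power variation default to off.
#'
#' @param sample_rate Samples per second (default 60000).
#' @param segment_duration Segment length in seconds (default 90).
#' @param flow_speed Flow speed in mm/s (default 55.6).
#' @param slit_width Illumination slit width in um (default 5).
#' @param channel_baseline_variance Named baseline variances (V^2) for the
#'   three scatter channels.
#' @param single_cell_rate Single-cell events per minute.
#' @param ctcc_rate Cluster (CTCC) events per minute.
#' @param ctcc_size_distribution List with `prob` (probabilities of the
#'   "2", "3-6" and "6+" cell classes, summing to 1) and `length_um`
#'   (min/max physical length per class).
#' @param peak_amplitude_model List of per-channel mean amplitudes (V) for
#'   `single_cell`, `ctcc` and `confounder` events, plus `gfp_ctcc`,
#'   `gfp_confounder` and `red_confounder` fluorescence amplitudes.
#' @param amplitude_sdlog Log-normal sd of the per-event amplitude factor.
#' @param clot_rate Blood-clot events per hour.
#' @param clot_drift_amplitude Standard deviation (V) of the clot drift on
#'   the cumulative scatter signal.
#' @param power_scale_by_day List with `meanlog`/`sdlog` of the per-day
#'   multiplicative power factor applied to all scatter channels
#'   (default degenerate at 1).
#' @param autofluor_confounder_rate Confounder events per minute (default 0).
#' @param shoulder_prob Probability that a cluster peak carries a
#'   lower-amplitude shoulder sub-peak.
#' @param single_cell_length_um Min/max single-cell length (um).
#' @param confounder_length_um Min/max confounder length (um).
#' @param gfp_baseline_sd,red_baseline_sd Baseline noise sd (V) of the
#'   fluorescence channels.
#' @param rng_seed Default seed used by [simulate_day()] when none is given.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 60000,
                       segment_duration = 90,
                       flow_speed = 55.6,
                       slit_width = 5,
                       channel_baseline_variance = c(scatter405 = 0.169,
                                                     scatter488 = 0.452,
                                                     scatter633 = 0.511),
                       single_cell_rate = 30,
                       ctcc_rate = 2,
                       ctcc_size_distribution = list(
                         prob = c("2" = 0.5, "3-6" = 0.4, "6+" = 0.1),
                         length_um = list("2" = c(24, 28),
                                          "3-6" = c(30, 55),
                                          "6+" = c(55, 80))),
                       peak_amplitude_model = list(
                         single_cell = c(scatter405 = 2.5, scatter488 = 2.2,
                                         scatter633 = 2.0),
                         ctcc = c(scatter405 = 5.0, scatter488 = 4.5,
                                  scatter633 = 4.0),
                         confounder = c(scatter405 = 1.5, scatter488 = 3.0,
                                        scatter633 = 5.0),
                         gfp_ctcc = 3.0,
                         gfp_confounder = 0.02,
                         red_confounder = 0.5),
                       amplitude_sdlog = 0.15,
                       clot_rate = 2,
                       clot_drift_amplitude = 2.5,
                       power_scale_by_day = list(meanlog = 0, sdlog = 0),
                       autofluor_confounder_rate = 0,
                       shoulder_prob = 0.2,
                       single_cell_length_um = c(8, 15),
                       confounder_length_um = c(24, 40),
                       gfp_baseline_sd = 0.05,
                       red_baseline_sd = 0.05,
                       rng_seed = 1L) {
  cfg <- list(sample_rate = sample_rate, segment_duration = segment_duration,
              flow_speed = flow_speed, slit_width = slit_width,
              channel_baseline_variance = channel_baseline_variance,
              single_cell_rate = single_cell_rate, ctcc_rate = ctcc_rate,
              ctcc_size_distribution = ctcc_size_distribution,
              peak_amplitude_model = peak_amplitude_model,
              amplitude_sdlog = amplitude_sdlog,
              clot_rate = clot_rate,
              clot_drift_amplitude = clot_drift_amplitude,
              power_scale_by_day = power_scale_by_day,
              autofluor_confounder_rate = autofluor_confounder_rate,
              shoulder_prob = shoulder_prob,
              single_cell_length_um = single_cell_length_um,
              confounder_length_um = confounder_length_um,
              gfp_baseline_sd = gfp_baseline_sd,
              red_baseline_sd = red_baseline_sd,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$single_cell_rate, cfg$ctcc_rate, cfg$clot_rate,
             cfg$autofluor_confounder_rate)
  if (any(rates < 0)) stop_invalid("all event rates must be >= 0")
  if (cfg$sample_rate <= 0) stop_invalid("`sample_rate` must be positive")
  if (cfg$segment_duration <= 0) stop_invalid("`segment_duration` must be positive")
  if (any(cfg$channel_baseline_variance <= 0)) {
    stop_invalid("baseline variances must be positive")
  }
  p <- cfg$ctcc_size_distribution$prob
  if (abs(sum(p) - 1) > 1e-8) {
    stop_invalid("`ctcc_size_distribution$prob` must sum to 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic BSFC simulation configuration\n")
  cat(sprintf("  sampling: %g Hz, %g s segments\n",
              x$sample_rate, x$segment_duration))
  cat(sprintf("  flow: %g mm/s through a %g um slit\n",
              x$flow_speed, x$slit_width))
  cat(sprintf("  baseline variances (V^2): %s\n",
              paste(sprintf("%s=%.3f", names(x$channel_baseline_variance),
                            x$channel_baseline_variance), collapse = ", ")))
  cat(sprintf("  rates: %g single cells/min, %g clusters/min, %g clots/h, %g confounders/min\n",
              x$single_cell_rate, x$ctcc_rate, x$clot_rate,
              x$autofluor_confounder_rate))
  invisible(x)
}

# Raised-cosine pulse with exponent 0.65, truncated at the transit base
# width. The exponent sets FWHM/base = 0.78 for the voltage pulse and 0.60
# for its square, which is the shape the anomaly (T^2) trace inherits: a
# 26 um two-cell cluster then measures ~20 samples FWHM on the anomaly trace
# (above the 17-sample gate) while a 15 um single cell measures ~13 (below).
pulse_shape <- function(n_offset, base_width, exponent = 0.65) {
  u <- n_offset / base_width                # -0.5..0.5 inside the pulse
  y <- numeric(length(u))
  inside <- abs(u) < 0.5
  y[inside] <- cos(pi * u[inside])^exponent
  y
}

#' Render a synthetic detector pulse
#'
#' Produces the multi-channel waveform of a single event: a smooth unimodal
#' raised-cosine pulse whose base width equals the transit width of an object
#' of length `length_um`, scaled per channel by `amplitudes`. An optional
#' shoulder attaches a lower-amplitude local maximum adjacent to the main
#' lobe, reproducing the shouldered peaks that motivate height equalization.
#'
#' @param kind Event kind label (recorded, not interpreted).
#' @param length_um Physical object length in um (> 0).
#' @param amplitudes Named non-negative peak amplitudes in volts, one per
#'   output channel.
#' @param shoulder Optional list with `amplitude` (fraction of the main
#'   amplitude), `offset` (centre offset as a fraction of the main base
#'   width) and `length` (shoulder object length as a fraction of
#'   `length_um`).
#' @param flow_speed,slit_width,sample_rate Transit-physics parameters; see
#'   [transit_width_points()].
#' @return A matrix (samples x channels) holding the pulse, with attributes
#'   `base_width` (samples) and `center` (row index of the pulse centre).
#' @export
render_peak <- function(kind, length_um, amplitudes, shoulder = NULL,
                        flow_speed = 55.6, slit_width = 5,
                        sample_rate = 60000) {
  if (length_um <= 0) stop_invalid("`length_um` must be positive")
  if (any(amplitudes < 0)) stop_invalid("amplitudes must be >= 0")
  base <- transit_width_points(length_um, slit_width, flow_speed, sample_rate)
  half_span <- ceiling(base / 2)
  extra <- 0
  if (!is.null(shoulder)) {
    extra <- ceiling(abs(shoulder$offset) * base +
                     transit_width_points(shoulder$length * length_um,
                                          slit_width, flow_speed,
                                          sample_rate) / 2)
  }
  offsets <- seq(-half_span - extra, half_span + extra)
  shape <- pulse_shape(offsets, base)
  if (!is.null(shoulder)) {
    sh_base <- transit_width_points(shoulder$length * length_um, slit_width,
                                    flow_speed, sample_rate)
    sh_center <- shoulder$offset * base
    shape <- shape + shoulder$amplitude * pulse_shape(offsets - sh_center, sh_base)
  }
  out <- outer(shape, as.numeric(amplitudes))
  colnames(out) <- names(amplitudes)
  attr(out, "base_width") <- base
  attr(out, "center") <- half_span + extra + 1L
  attr(out, "kind") <- kind
  out
}

# Draw a cluster physical length from the size-class distribution.
draw_ctcc_length <- function(dist) {
  cls <- sample(names(dist$prob), 1L, prob = dist$prob)
  rng <- dist$length_um[[cls]]
  stats::runif(1L, rng[1], rng[2])
}

# Place an event of the given footprint uniformly in [1, n], rejecting
# overlaps with already-occupied intervals (with a guard gap); errors when
# the segment cannot host the event at all.
place_event <- function(n, width, occupied, gap = 100L, tries = 200L,
                        what = "event") {
  if (width + 2L > n) {
    stop_invalid(sprintf("segment too short (%d samples) to host a %s of width %d",
                         n, what, width))
  }
  half <- ceiling(width / 2)
  for (i in seq_len(tries)) {
    center <- sample.int(n - 2L * half - 2L, 1L) + half + 1L
    lo <- center - half - gap
    hi <- center + half + gap
    clash <- any(occupied$lo <= hi & occupied$hi >= lo)
    if (!clash) return(center)
  }
  stop_invalid(sprintf("could not place a %s of width %d without overlap", what, width))
}

# Generate one segment's worth of events and return the channel matrix plus
# truth rows.
simulate_segment <- function(cfg, day_id, segment_id, power_scale) {
  n <- as.integer(round(cfg$sample_rate * cfg$segment_duration))
  sds <- sqrt(cfg$channel_baseline_variance)
  data <- cbind(scatter405 = stats::rnorm(n, 0, sds["scatter405"]),
                scatter488 = stats::rnorm(n, 0, sds["scatter488"]),
                scatter633 = stats::rnorm(n, 0, sds["scatter633"]),
                gfp525 = stats::rnorm(n, 0, cfg$gfp_baseline_sd),
                red670 = stats::rnorm(n, 0, cfg$red_baseline_sd))
  minutes <- cfg$segment_duration / 60
  counts <- c(single_cell = stats::rpois(1L, cfg$single_cell_rate * minutes),
              ctcc = stats::rpois(1L, cfg$ctcc_rate * minutes),
              confounder = stats::rpois(1L, cfg$autofluor_confounder_rate * minutes))
  occupied <- list(lo = integer(0), hi = integer(0))
  truth <- list()
  amp_model <- cfg$peak_amplitude_model
  ev <- 0L
  for (kind in names(counts)) {
    for (i in seq_len(counts[[kind]])) {
      ev <- ev + 1L
      length_um <- switch(kind,
        single_cell = stats::runif(1L, cfg$single_cell_length_um[1],
                                   cfg$single_cell_length_um[2]),
        ctcc = draw_ctcc_length(cfg$ctcc_size_distribution),
        confounder = stats::runif(1L, cfg$confounder_length_um[1],
                                  cfg$confounder_length_um[2]))
      factor <- exp(stats::rnorm(1L, 0, cfg$amplitude_sdlog))
      amps <- amp_model[[kind]] * factor *
        exp(stats::rnorm(3L, 0, cfg$amplitude_sdlog / 3))
      amps <- c(amps,
                gfp525 = switch(kind,
                                ctcc = amp_model$gfp_ctcc * factor,
                                confounder = amp_model$gfp_confounder * factor,
                                single_cell = 0),
                red670 = switch(kind,
                                confounder = amp_model$red_confounder * factor,
                                0))
      names(amps)[1:3] <- scatter_channels()
      shoulder <- NULL
      if (kind == "ctcc" && stats::runif(1L) < cfg$shoulder_prob) {
        shoulder <- list(amplitude = stats::runif(1L, 0.3, 0.5),
                         offset = 0.75, length = 0.5)
      }
      pk <- render_peak(kind, length_um, amps, shoulder,
                        flow_speed = cfg$flow_speed,
                        slit_width = cfg$slit_width,
                        sample_rate = cfg$sample_rate)
      center <- place_event(n, nrow(pk), occupied, what = kind)
      lo <- center - attr(pk, "center") + 1L
      hi <- lo + nrow(pk) - 1L
      rows <- seq(max(lo, 1L), min(hi, n))
      data[rows, colnames(pk)] <- data[rows, colnames(pk)] +
        pk[rows - lo + 1L, , drop = FALSE]
      occupied$lo <- c(occupied$lo, lo)
      occupied$hi <- c(occupied$hi, hi)
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = sprintf("d%ds%de%d", day_id, segment_id, ev),
        kind = kind, segment_id = segment_id,
        start_index = max(lo, 1L), end_index = min(hi, n),
        physical_length_um = length_um,
        has_gfp = kind == "ctcc", stringsAsFactors = FALSE)
    }
  }
  # Blood clots: low-frequency random-walk drift over the whole segment,
  # scaled so the cumulative-scatter sd rises above the clot threshold.
  n_clots <- stats::rpois(1L, cfg$clot_rate * cfg$segment_duration / 3600)
  if (n_clots > 0L) {
    rw <- cumsum(stats::rnorm(n))
    rw <- (rw - mean(rw)) / stats::sd(rw) * cfg$clot_drift_amplitude
    for (ch in scatter_channels()) data[, ch] <- data[, ch] + rw / 3
    ev <- ev + 1L
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("d%ds%de%d", day_id, segment_id, ev),
      kind = "clot", segment_id = segment_id,
      start_index = 1L, end_index = n,
      physical_length_um = NA_real_, has_gfp = FALSE,
      stringsAsFactors = FALSE)
  }
  for (ch in scatter_channels()) data[, ch] <- data[, ch] * power_scale
  list(data = data,
       truth = if (length(truth)) do.call(rbind, truth) else empty_truth_table())
}

empty_truth_table <- function() {
  data.frame(event_id = character(0), kind = character(0),
             segment_id = integer(0), start_index = integer(0),
             end_index = integer(0), physical_length_um = numeric(0),
             has_gfp = logical(0), stringsAsFactors = FALSE)
}

#' Simulate one acquisition day
#'
#' Generates `n_segments` fixed-length five-channel segments with a common
#' per-day laser power factor, plus a ground-truth table of every injected
#' event. Event counts per kind are Poisson at the configured rates; every
#' cluster places correlated scatter peaks on all three scatter channels and
#' a co-located green-fluorescence peak of matching transit width. Identical
#' `(config, seed)` reproduces identical output bit for bit.
#'
#' @param config A [sim_config()].
#' @param n_segments Number of segments (>= 1).
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @param day_id Integer day identifier recorded in segments and truth rows.
#' @return List with `segments` (list of `trace_segment`), `truth` (the
#'   truth table data frame) and `power_scale`.
#' @export
simulate_day <- function(config, n_segments = 1L, seed = config$rng_seed,
                         day_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_segments < 1L) stop_invalid("`n_segments` must be >= 1")
  with_seed(seed, {
    power_scale <- exp(stats::rnorm(1L, config$power_scale_by_day$meanlog,
                                    config$power_scale_by_day$sdlog))
    segments <- vector("list", n_segments)
    truth <- vector("list", n_segments)
    for (s in seq_len(n_segments)) {
      seg <- simulate_segment(config, day_id, s, power_scale)
      segments[[s]] <- trace_segment(seg$data, config$sample_rate,
                                     segment_id = s, day_id = day_id,
                                     start_time = (s - 1L) * config$segment_duration)
      truth[[s]] <- seg$truth
    }
    list(segments = segments, truth = do.call(rbind, truth),
         power_scale = power_scale)
  })
}

#' Write / read a simulation configuration as YAML
#'
#' The YAML file mirrors the `sim_config` fields one for one.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  # named vectors become YAML maps so channel names survive the round trip
  out$channel_baseline_variance <- as.list(out$channel_baseline_variance)
  out$peak_amplitude_model <- lapply(out$peak_amplitude_model, as.list)
  out$ctcc_size_distribution$prob <- as.list(out$ctcc_size_distribution$prob)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  raw$channel_baseline_variance <- unlist(raw$channel_baseline_variance)
  raw$peak_amplitude_model <- lapply(raw$peak_amplitude_model, unlist)
  raw$ctcc_size_distribution$prob <- unlist(raw$ctcc_size_distribution$prob)
  do.call(sim_config, raw)
}
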