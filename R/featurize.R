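# Classifier inputs: 297-point z-scored scatter windows around each detected
# peak, ground-truth labels from the green-fluorescence channel, and
# day-level train/validation/test splits.

FEATURE_WINDOW <- 49L   # +-49 samples around the peak -> 99 per channel
N_FEATURES <- 297L

#' Build the 297-point feature vector for one peak
#'
#' Each raw scatter channel is z-scored over the whole segment (mean
#' subtracted, divided by the standard deviation), then the samples within
#' +-49 points of the peak location are extracted (99 values per channel)
#' and concatenated in 405/488/633 order: features 1-99 from 405 nm,
#' 100-198 from 488 nm, 199-297 from 633 nm. Windows crossing a segment
#' boundary are edge-padded with the boundary value. Raw (unfiltered)
#' channels are used; the filtered trace serves only for ROI finding.
#'
#' @param segment A raw `trace_segment`.
#' @param peak_index Peak location within the segment.
#' @return Numeric vector of length 297.
#' @export
build_feature_vector <- function(segment, peak_index) {
  n <- n_samples(segment)
  if (peak_index < 1L || peak_index > n) {
    stop_invalid("`peak_index` outside the segment")
  }
  idx <- pmin(pmax(seq(peak_index - FEATURE_WINDOW,
                       peak_index + FEATURE_WINDOW), 1L), n)
  out <- numeric(0)
  for (ch in scatter_channels()) {
    x <- channel(segment, ch)
    s <- stats::sd(x)
    if (s == 0) {
      warning("channel ", ch, " has zero standard deviation; features set to 0")
      z <- rep(0, length(idx))
    } else {
      z <- (x[idx] - mean(x)) / s
    }
    out <- c(out, z)
  }
  out
}

#' Label scatter events against green-fluorescence ground truth
#'
#' A scatter event is a CTCC when a green-fluorescence region overlaps its
#' index range and either its own equalized FWHM strictly exceeds the gate
#' (default 17 samples) or the matching fluorescence region's FWHM does;
#' otherwise it is a non-CTCC (NC) event. Matching means any index-range
#' overlap. The rule depends only on (FWHM, overlap) pairs, so it is
#' symmetric in the order of either event list. Note the deliberate
#' asymmetry with detection: the width gate retains events with FWHM
#' exactly 17, but the label rule's strict `> 17` can still call such an
#' event NC when its fluorescence partner is also at or below 17.
#'
#' @param scatter_events Peak-table rows from [detect_rois()].
#' @param gfp_events Peak-table rows from [detect_gfp_rois()] for the same
#'   segment.
#' @param min_fwhm Gate in samples (default 17).
#' @return `scatter_events` with added columns `label` (factor
#'   `CTCC`/`NC`) and `gfp_match` (logical).
#' @export
label_events <- function(scatter_events, gfp_events, min_fwhm = 17L) {
  nvec <- nrow(scatter_events)
  label <- character(nvec)
  match <- logical(nvec)
  for (i in seq_len(nvec)) {
    ov <- which(gfp_events$start_index <= scatter_events$end_index[i] &
                gfp_events$end_index >= scatter_events$start_index[i])
    match[i] <- length(ov) > 0L
    gfp_fwhm <- if (match[i]) max(gfp_events$fwhm_samples[ov]) else -Inf
    is_ctcc <- match[i] && (scatter_events$fwhm_samples[i] > min_fwhm ||
                            gfp_fwhm > min_fwhm)
    label[i] <- if (is_ctcc) "CTCC" else "NC"
  }
  scatter_events$label <- factor(label, levels = c("NC", "CTCC"))
  scatter_events$gfp_match <- match
  scatter_events
}

#' Day-level train/validation/test splits
#'
#' Sets aside a fixed test set of about `test_fraction` of the days, then
#' builds `n_folds` train/validation partitions of the remaining days, each
#' fold sampling about `val_fraction` of the train+validation days for
#' validation. Splitting is always by day, never by event, so no recording
#' session leaks across sets. Deterministic given `seed`. At the reference
#' scale (34 days, test fraction 11/34, validation fraction 5/23) this gives
#' an 11-day test set and five folds of 18 training / 5 validation days.
#'
#' @param day_ids Vector of day identifiers (>= 3 days).
#' @param test_fraction Fraction of days held out for test.
#' @param n_folds Number of train/validation folds.
#' @param val_fraction Fraction of the non-test days used for validation in
#'   each fold.
#' @param seed Integer seed.
#' @return Object of class `dataset_splits`: list with `test_days` and
#'   `folds` (each a list with `train_days`, `val_days`).
#' @export
make_splits <- function(day_ids, test_fraction = 11 / 34, n_folds = 5L,
                        val_fraction = 5 / 23, seed = 1L) {
  day_ids <- unique(day_ids)
  n <- length(day_ids)
  if (n < 3L) stop_invalid("need at least 3 days to split")
  n_test <- max(1L, round_half_up(test_fraction * n))
  if (n - n_test < 2L) stop_invalid("too few days for the requested folds")
  with_seed(seed, {
    test_days <- sort(sample(day_ids, n_test))
    trainval <- setdiff(day_ids, test_days)
    n_val <- max(1L, round_half_up(val_fraction * length(trainval)))
    if (n_val >= length(trainval)) {
      stop_invalid("too few days for the requested folds")
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      val <- sort(sample(trainval, n_val))
      list(train_days = sort(setdiff(trainval, val)), val_days = val)
    })
    structure(list(test_days = test_days, folds = folds),
              class = "dataset_splits")
  })
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat(sprintf("dataset_splits: %d test day(s), %d fold(s)\n",
              length(x$test_days), length(x$folds)))
  cat("  test:", paste(x$test_days, collapse = ", "), "\n")
  for (i in seq_along(x$folds)) {
    cat(sprintf("  fold %d: %d train / %d val\n", i,
                length(x$folds[[i]]$train_days),
                length(x$folds[[i]]$val_days)))
  }
  invisible(x)
}

#' Build labeled examples for one segment
#'
#' Runs ground-truth labeling over the detected scatter events and extracts
#' the 297-point feature vector for each.
#'
#' @param segment Raw `trace_segment` (features use raw channels).
#' @param scatter_events Gated events from [detect_rois()].
#' @param gfp_events Events from [detect_gfp_rois()].
#' @param min_fwhm Label gate in samples.
#' @return List with `features` (matrix n x 297), `events` (labeled event
#'   table including `day_id`).
#' @export
build_examples <- function(segment, scatter_events, gfp_events,
                           min_fwhm = 17L) {
  labeled <- label_events(scatter_events, gfp_events, min_fwhm)
  labeled$day_id <- segment$day_id
  feats <- matrix(0, nrow(labeled), N_FEATURES)
  for (i in seq_len(nrow(labeled))) {
    feats[i, ] <- build_feature_vector(segment, labeled$peak_index[i])
  }
  list(features = feats, events = labeled)
}
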