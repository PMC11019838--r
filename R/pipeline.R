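# End-to-end orchestration: simulate -> detect -> featurize -> train ->
# predict -> evaluate, driven by a single validated YAML configuration with
# a global seed, writing all artifacts plus a manifest into a run directory.

pipeline_schema <- function() {
  list(
    seed = NULL,
    write_traces = NULL,
    simulate = c("n_days", "segments_per_day", "ctcc_rates",
                 names(formals(sim_config))),
    detect = names(formals(detection_params)),
    train = names(formals(train_config)),
    cascade = "n_models",
    split = c("test_fraction", "val_fraction"))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list or YAML file against the pipeline schema:
#' every unknown key is rejected by name, missing required keys are named,
#' and cross-field constraints (the detection band against the simulated
#' Nyquist frequency) are enforced.
#'
#' @param config A list or a YAML file path.
#' @return The validated configuration list, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  schema <- pipeline_schema()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top)) {
    stop_invalid("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  }
  if (is.null(config$seed)) stop_invalid("missing required config key: seed")
  for (section in c("simulate", "detect", "train", "cascade", "split")) {
    keys <- names(config[[section]])
    unknown <- setdiff(keys, schema[[section]])
    if (length(unknown)) {
      stop_invalid("unknown key(s) in `", section, "`: ",
                   paste(unknown, collapse = ", "))
    }
  }
  sample_rate <- config$simulate$sample_rate %||% 60000
  band_high <- if (!is.null(config$detect$band)) {
    max(unlist(config$detect$band))
  } else 10000
  if (band_high >= sample_rate / 2) {
    stop_invalid("cross-field error: `detect$band` upper edge (", band_high,
                 " Hz) must be below half of `simulate$sample_rate` (",
                 sample_rate / 2, " Hz)")
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_section <- function(constructor, overrides, drop = character(0)) {
  overrides <- overrides[setdiff(names(overrides), drop)]
  do.call(constructor, overrides %||% list())
}

#' Run the full detection pipeline on simulated data
#'
#' Simulates the configured acquisition days, runs ROI detection and
#' ground-truth labeling on every segment, trains a cascade on the training
#' days, predicts on everything, and writes peak tables, labeled examples,
#' predictions, an evaluation report and a manifest (with file checksums,
#' seeds and per-stage counts) into `out_dir`. Identical configuration and
#' seed reproduce an identical report.
#'
#' @param config Configuration list or YAML path; see [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return The evaluation report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  simc <- config$simulate
  n_days <- simc$n_days %||% 4L
  segs_per_day <- simc$segments_per_day %||% 1L
  ctcc_rates <- rep(unlist(simc$ctcc_rates %||% 2), length.out = n_days)
  sim_overrides <- simc[setdiff(names(simc),
                                c("n_days", "segments_per_day", "ctcc_rates"))]
  params <- build_section(detection_params, config$detect)
  tcfg <- build_section(train_config, config$train)
  tcfg$seed <- seed
  n_models <- config$cascade$n_models %||% 2L

  features <- list(); events <- list(); truths <- list(); clots <- 0L
  for (d in seq_len(n_days)) {
    cfg_d <- do.call(sim_config, c(sim_overrides,
                                   list(ctcc_rate = ctcc_rates[d])))
    day <- simulate_day(cfg_d, segs_per_day, seed = seed + 7919L * d,
                        day_id = d)
    truths[[d]] <- cbind(day_id = d, day$truth)
    for (seg in day$segments) {
      det <- detect_rois(seg, params)
      if (det$clot_report$detected) clots <- clots + 1L
      gfp <- detect_gfp_rois(seg, params)
      ex <- build_examples(seg, det$events, gfp, params$min_fwhm)
      if (nrow(ex$events)) {
        features[[length(features) + 1L]] <- ex$features
        events[[length(events) + 1L]] <- ex$events
      }
      if (isTRUE(config$write_traces)) {
        write_trace_csv(seg, file.path(out_dir,
                                       sprintf("trace_d%02d_s%02d.csv",
                                               d, seg$segment_id)))
      }
    }
  }
  features <- do.call(rbind, features)
  events <- do.call(rbind, events)
  truth <- do.call(rbind, truths)
  y <- as.integer(events$label == "CTCC")

  split_cfg <- config$split
  splits <- make_splits(seq_len(n_days),
                        test_fraction = split_cfg$test_fraction %||% 0.3,
                        n_folds = 1L,
                        val_fraction = split_cfg$val_fraction %||% 0.25,
                        seed = seed)
  fold <- splits$folds[[1L]]
  in_train <- events$day_id %in% fold$train_days
  in_val <- events$day_id %in% fold$val_days
  in_test <- events$day_id %in% splits$test_days

  cascade <- cascade_train(features[in_train, , drop = FALSE], y[in_train],
                           features[in_val, , drop = FALSE], y[in_val],
                           config = tcfg, n_models = n_models)
  audit <- predict(cascade, features, type = "audit")
  events$predicted <- ifelse(audit$class == 1L, "CTCC", "NC")

  cm <- confusion(events$label[in_test], events$predicted[in_test])
  metrics <- core_metrics(cm)
  true_per_day <- vapply(seq_len(n_days), function(d) {
    sum(truth$kind == "ctcc" & truth$day_id == d)
  }, numeric(1))
  detected_per_day <- vapply(seq_len(n_days), function(d) {
    sum(events$predicted == "CTCC" & events$day_id == d)
  }, numeric(1))
  pcc <- pearson_correlation(detected_per_day, true_per_day)
  n_stages <- length(cascade$stages)
  stage_fp <- vapply(seq_len(n_stages), function(k) {
    alive <- is.na(audit$drop_stage) | audit$drop_stage > k
    sum(alive & in_test & events$label == "NC")
  }, numeric(1))

  report <- list(
    seed = seed,
    n_days = n_days,
    days = list(train = fold$train_days, val = fold$val_days,
                test = splits$test_days),
    counts = list(events = nrow(events), positives = sum(y),
                  clot_segments = clots,
                  true_ctcc_per_day = as.numeric(true_per_day),
                  detected_ctcc_per_day = as.numeric(detected_per_day)),
    cascade = list(n_stages = n_stages,
                   stage_sizes = cascade$stage_sizes,
                   test_fp_after_stage = as.numeric(stage_fp)),
    test_confusion = unclass(cm)[c("tp", "fp", "tn", "fn")],
    test_metrics = unclass(metrics),
    detected_vs_true_pcc = pcc)

  write_peak_table(events[PEAK_TABLE_COLUMNS], file.path(out_dir, "peaks.csv"))
  data.table::fwrite(cbind(as.data.frame(features),
                           label = events$label,
                           predicted = events$predicted,
                           day_id = events$day_id),
                     file.path(out_dir, "examples.csv"))
  write_truth_table(truth, file.path(out_dir, "truth.csv"))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  artifact_files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = seed,
    files = lapply(artifact_files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
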