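# Reading/writing delimited voltage traces, splitting streams into
# fixed-length analysis segments, and persisting peak-characteristic tables.
# All indices in exported tables are 1-based with inclusive ranges (noted in
# a header comment of every CSV written here).

PEAK_TABLE_COLUMNS <- c("segment_id", "channel_group", "peak_index",
                        "start_index", "end_index", "fwhm_samples",
                        "peak_intensity", "t2_score")

#' Construct a trace segment
#'
#' A fixed-rate block of synchronized voltage channels with acquisition
#' metadata; the object all signal processing acts on.
#'
#' @param data Numeric matrix (samples x channels) with named columns; the
#'   three scatter channels (`scatter405`, `scatter488`, `scatter633`) are
#'   mandatory, `gfp525` and `red670` optional.
#' @param sample_rate Samples per second (> 0).
#' @param segment_id,day_id Integer identifiers.
#' @param start_time Segment start within its stream, seconds.
#' @param partial Whether this is a shortened final segment of a stream.
#' @return An object of class `trace_segment`.
#' @export
trace_segment <- function(data, sample_rate, segment_id = 1L, day_id = 1L,
                          start_time = 0, partial = FALSE) {
  data <- as.matrix(data)
  if (sample_rate <= 0) stop_invalid("`sample_rate` must be positive")
  missing_scatter <- setdiff(scatter_channels(), colnames(data))
  if (length(missing_scatter)) {
    stop_invalid("missing mandatory scatter channel(s): ",
                 paste(missing_scatter, collapse = ", "))
  }
  structure(list(data = data, sample_rate = sample_rate,
                 segment_id = as.integer(segment_id),
                 day_id = as.integer(day_id),
                 start_time = start_time, partial = isTRUE(partial),
                 missing_channels = setdiff(all_channels(), colnames(data))),
            class = "trace_segment")
}

#' @export
print.trace_segment <- function(x, ...) {
  cat(sprintf("trace_segment: day %d, segment %d, %d samples x %d channels @ %g Hz (%.2f s)%s\n",
              x$day_id, x$segment_id, nrow(x$data), ncol(x$data),
              x$sample_rate, nrow(x$data) / x$sample_rate,
              if (x$partial) " [partial]" else ""))
  if (length(x$missing_channels)) {
    cat("  absent channels:", paste(x$missing_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

n_samples <- function(segment) nrow(segment$data)

channel <- function(segment, name) {
  if (!name %in% colnames(segment$data)) {
    stop_invalid("channel `", name, "` is absent from this segment")
  }
  segment$data[, name]
}

#' Read a multi-channel trace CSV
#'
#' Loads a comma-separated trace (one column per channel, one row per
#' sample, header naming the channels). Channels are matched by header name,
#' never by position. Missing optional channels are flagged in the returned
#' object, not fabricated; missing mandatory scatter channels are an error.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @param sample_rate Acquisition rate in samples/s (default 60000).
#' @return A `trace_record`: list with `data` (matrix), `sample_rate` and
#'   `missing_channels`.
#' @export
read_trace_csv <- function(path, sample_rate = 60000) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  missing_scatter <- setdiff(scatter_channels(), names(dt))
  if (length(missing_scatter)) {
    stop_invalid("trace file is missing mandatory scatter channel(s): ",
                 paste(missing_scatter, collapse = ", "))
  }
  keep <- intersect(all_channels(), names(dt))
  m <- as.matrix(dt[keep])
  if (!is.numeric(m)) {
    bad <- which(!stats::complete.cases(suppressWarnings(
      apply(dt[keep], 2, as.numeric))))[1]
    stop_invalid(sprintf("malformed trace row at data line %d of %s",
                         bad, path))
  }
  if (anyNA(m)) {
    stop_invalid(sprintf("malformed trace row at data line %d of %s",
                         which(!stats::complete.cases(m))[1], path))
  }
  structure(list(data = m, sample_rate = sample_rate,
                 missing_channels = setdiff(all_channels(), keep)),
            class = "trace_record")
}

#' Write a segment (or record) to CSV
#'
#' One column per channel, one row per sample; full double precision (well
#' beyond the 16-bit acquisition resolution), so a write/read round trip is
#' lossless at text precision.
#'
#' @param x A `trace_segment` or `trace_record`.
#' @param path Output path.
#' @export
write_trace_csv <- function(x, path) {
  data.table::fwrite(as.data.frame(x$data), path)
  invisible(path)
}

#' Split a continuous record into fixed-length segments
#'
#' Partitions the record into consecutive non-overlapping segments of
#' `segment_duration` seconds; the final shorter remainder (if any) is
#' retained and flagged `partial`. Concatenating the segments restores the
#' record exactly.
#'
#' @param record A `trace_record` from [read_trace_csv()], or a
#'   `trace_segment`.
#' @param segment_duration Segment length in seconds (default 90, i.e. the
#'   1.5-minute analysis blocks).
#' @param day_id Day identifier stamped on each segment.
#' @return List of `trace_segment` objects.
#' @export
segment_stream <- function(record, segment_duration = 90, day_id = 1L) {
  n <- nrow(record$data)
  if (n == 0L) stop_invalid("record is empty")
  len <- as.integer(round(record$sample_rate * segment_duration))
  starts <- seq.int(1L, n, by = len)
  lapply(seq_along(starts), function(i) {
    rows <- starts[i]:min(starts[i] + len - 1L, n)
    trace_segment(record$data[rows, , drop = FALSE], record$sample_rate,
                  segment_id = i, day_id = day_id,
                  start_time = (starts[i] - 1L) / record$sample_rate,
                  partial = length(rows) < len)
  })
}

#' Write / read a peak-characteristics table
#'
#' Persists detected-peak characteristics (location, range, equalized FWHM,
#' intensity, anomaly score) as CSV with a stable column order and a header
#' comment documenting the index convention. The round trip is lossless;
#' missing anomaly scores (fluorescence rows) stay missing.
#'
#' @param table Data frame with columns `segment_id`, `channel_group`,
#'   `peak_index`, `start_index`, `end_index`, `fwhm_samples`,
#'   `peak_intensity`, `t2_score`.
#' @param path CSV path.
#' @return `read_peak_table()` returns the table as a data frame.
#' @export
write_peak_table <- function(table, path) {
  missing <- setdiff(PEAK_TABLE_COLUMNS, names(table))
  if (length(missing)) {
    stop_invalid("peak table is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  con <- file(path, "w")
  writeLines("# peak table: indices are 1-based, ranges inclusive", con)
  close(con)
  data.table::fwrite(table[PEAK_TABLE_COLUMNS], path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          skip = "segment_id")
  if (!identical(names(df), PEAK_TABLE_COLUMNS)) {
    stop_invalid("peak table schema mismatch: expected columns ",
                 paste(PEAK_TABLE_COLUMNS, collapse = ", "))
  }
  df$channel_group <- as.character(df$channel_group)
  df
}

#' Write / read an event truth table
#'
#' @param truth Truth table from [simulate_day()].
#' @param path CSV path.
#' @export
write_truth_table <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
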