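#' Read a spike table
#'
#' Reads the canonical delimited spike-timestamp format: a CSV with header
#' columns `electrode_id,time_s`, one row per spike. Rows may arrive in any
#' order; timestamps are sorted per electrode. Electrodes present in the
#' layout but absent from the file yield empty trains.
#'
#' @param source path or connection to the CSV.
#' @param layout an [mea_layout()]; rows referencing electrodes outside it are
#'   rejected.
#' @param epoch_duration epoch length in seconds; timestamps beyond it are
#'   rejected.
#' @param div,condition,culture_id optional metadata attached to the result.
#' @return An [mea_recording()].
#' @export
read_spike_table <- function(source, layout = default_mea_layout(),
                             epoch_duration = 900, div = NA_integer_,
                             condition = NA_character_,
                             culture_id = NA_character_) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (!all(c("electrode_id", "time_s") %in% names(df)))
    stop_bad_arg("spike table must have header columns electrode_id,time_s")
  times <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(times) | !is.finite(times) | times < 0)
  if (length(bad))
    stop_bad_arg("malformed spike-table row(s) at line(s) ",
                 paste(bad + 1L, collapse = ", "),
                 " (non-numeric or negative time)")
  unknown <- setdiff(unique(df$electrode_id), layout$electrode_ids)
  if (length(unknown))
    stop_bad_arg("unknown electrode id(s) in spike table: ",
                 paste(unknown, collapse = ", "))
  late <- which(times > epoch_duration)
  if (length(late))
    stop_bad_arg("timestamp exceeds epoch_duration at line(s) ",
                 paste(late + 1L, collapse = ", "))
  trains <- lapply(split(times, factor(df$electrode_id,
                                       levels = layout$electrode_ids)),
                   sort)
  trains <- Map(function(id, ts) {
    if (length(ts) > 1L && any(diff(ts) <= 0))
      stop_bad_arg("duplicate timestamps on electrode ", id)
    new_spike_train(id, ts, epoch_duration)
  }, names(trains), trains)
  mea_recording(unname(trains), layout = layout, div = div,
                condition = condition, culture_id = culture_id,
                epoch_duration = epoch_duration)
}

#' Write a spike table
#'
#' Writes the canonical `electrode_id,time_s` CSV. Rows are ordered by layout
#' electrode order, then ascending time; times are printed at microsecond
#' precision, so a read/write round trip is lossless to 1 us.
#'
#' @param recording an [mea_recording()].
#' @param sink path or connection to write to.
#' @return `sink`, invisibly.
#' @export
write_spike_table <- function(recording, sink) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  ids <- rep(names(recording$trains),
             vapply(recording$trains, function(tr) length(tr$timestamps),
                    integer(1)))
  ts <- unlist(lapply(recording$trains, `[[`, "timestamps"),
               use.names = FALSE)
  lines <- c("electrode_id,time_s",
             if (length(ids)) paste0(ids, ",", sprintf("%.6f", ts)))
  writeLines(lines, sink)
  invisible(sink)
}

#' Export bursts as a delimited table
#'
#' Flattens per-electrode burst tables into one data frame with columns
#' `electrode_id, start_s, end_s, n_spikes` (plus any metadata columns given),
#' optionally writing it as CSV.
#'
#' @param bursts named list of burst data frames, as returned by
#'   [detect_recording_bursts()].
#' @param sink optional path or connection; when given the table is written
#'   as CSV.
#' @return The combined data frame (invisibly when `sink` is given).
#' @export
burst_table <- function(bursts, sink = NULL) {
  rows <- lapply(names(bursts), function(id) {
    b <- bursts[[id]]
    if (!nrow(b)) return(NULL)
    data.frame(electrode_id = id, start_s = b$start, end_s = b$end,
               n_spikes = b$n_spikes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(electrode_id = character(), start_s = numeric(),
                      end_s = numeric(), n_spikes = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(sink)) {
    utils::write.csv(out, sink, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a raw voltage trace
#'
#' Reads a single-column numeric text file of voltage samples (microvolts).
#'
#' @param source path or connection.
#' @param sampling_rate samples per second (default 25 kHz).
#' @param electrode_id label for the trace.
#' @return A [raw_trace()].
#' @export
read_raw_trace <- function(source, sampling_rate = 25000,
                           electrode_id = "E1") {
  samples <- utils::read.table(source)[[1L]]
  raw_trace(electrode_id, samples, sampling_rate)
}
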