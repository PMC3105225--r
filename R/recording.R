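#' Spike train for one electrode
#'
#' Ordered spike timestamps recorded at one electrode during one epoch. Times
#' are seconds from epoch start and must lie in `[0, epoch_duration]` and be
#' strictly increasing.
#'
#' @param electrode_id electrode label.
#' @param timestamps numeric vector of spike times in seconds.
#' @param epoch_duration epoch length in seconds (default 900 s, a 15-minute
#'   recording).
#'
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(electrode_id, timestamps = numeric(),
                        epoch_duration = 900) {
  timestamps <- as.numeric(timestamps)
  if (!is_number(epoch_duration) || epoch_duration <= 0)
    stop_bad_arg("`epoch_duration` must be a positive number of seconds")
  if (length(timestamps)) {
    if (anyNA(timestamps) || any(!is.finite(timestamps)))
      stop_bad_arg("timestamps must be finite")
    if (any(timestamps < 0) || any(timestamps > epoch_duration))
      stop_bad_arg("timestamps must lie within [0, epoch_duration]")
    if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
      stop_bad_arg("timestamps must be strictly increasing")
  }
  structure(
    list(electrode_id = as.character(electrode_id)[1L],
         timestamps = timestamps,
         epoch_duration = epoch_duration),
    class = "spike_train")
}

new_spike_train <- function(electrode_id, timestamps, epoch_duration) {
  # fast path used by the simulator and readers after their own validation
  structure(
    list(electrode_id = electrode_id, timestamps = timestamps,
         epoch_duration = epoch_duration),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train [%s]: %d spikes over %g s\n",
              x$electrode_id, length(x$timestamps), x$epoch_duration))
  invisible(x)
}

#' MEA recording
#'
#' One recording epoch: one [spike_train()] per layout electrode plus culture
#' metadata. Electrodes without a supplied train get an empty train.
#'
#' @param trains list of `spike_train` objects; their `electrode_id`s must
#'   exist in `layout` and all trains must share `epoch_duration`.
#' @param layout an [mea_layout()].
#' @param div integer day in vitro, or `NA`.
#' @param condition condition label (e.g. `"untransfected"`), or `NA`.
#' @param culture_id culture identifier, or `NA`.
#' @param epoch_duration epoch length in seconds.
#'
#' @return An object of class `mea_recording` whose `$trains` is a named list
#'   (one entry per layout electrode, in layout order).
#' @export
mea_recording <- function(trains = list(), layout = default_mea_layout(),
                          div = NA_integer_, condition = NA_character_,
                          culture_id = NA_character_, epoch_duration = 900) {
  if (!inherits(layout, "mea_layout")) stop_bad_arg("`layout` must be an mea_layout")
  if (!is_number(epoch_duration) || epoch_duration <= 0)
    stop_bad_arg("`epoch_duration` must be a positive number of seconds")
  ids <- layout$electrode_ids
  full <- stats::setNames(vector("list", length(ids)), ids)
  for (tr in trains) {
    if (!inherits(tr, "spike_train"))
      stop_bad_arg("all elements of `trains` must be spike_train objects")
    if (!tr$electrode_id %in% ids)
      stop_bad_arg("train electrode id '", tr$electrode_id,
                   "' is not in the layout")
    if (abs(tr$epoch_duration - epoch_duration) > 1e-9)
      stop_bad_arg("all trains must share the recording epoch_duration")
    full[[tr$electrode_id]] <- tr
  }
  for (id in ids)
    if (is.null(full[[id]]))
      full[[id]] <- new_spike_train(id, numeric(), epoch_duration)
  structure(
    list(trains = full, layout = layout, div = as.integer(div),
         condition = as.character(condition),
         culture_id = as.character(culture_id),
         epoch_duration = epoch_duration),
    class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  n <- vapply(x$trains, function(tr) length(tr$timestamps), integer(1))
  cat(sprintf("MEA recording: %d electrodes, %d spikes, %g s epoch\n",
              length(x$trains), sum(n), x$epoch_duration))
  meta <- c(if (!is.na(x$condition)) paste0("condition=", x$condition),
            if (!is.na(x$culture_id)) paste0("culture=", x$culture_id),
            if (!is.na(x$div)) paste0("DIV=", x$div))
  if (length(meta)) cat(" ", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a recording to a sub-epoch
#'
#' Keeps spikes with `t0 <= t < t1` (half-open interval), re-zeroes times to
#' `t0` and sets the new epoch duration to `t1 - t0`. When `t1` is the epoch
#' end the window is closed there, so a spike at exactly `t = T` is kept and
#' a partition of `[0, T)` conserves the total spike count.
#'
#' @param recording an [mea_recording()].
#' @param t0,t1 window bounds in seconds, `0 <= t0 < t1 <= epoch_duration`.
#' @return A new `mea_recording` over the window.
#' @export
restrict_epoch <- function(recording, t0, t1) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  if (!is_number(t0) || !is_number(t1) || t0 >= t1)
    stop_bad_arg("need 0 <= t0 < t1")
  if (t0 < 0 || t1 > recording$epoch_duration + 1e-12)
    stop_bad_arg("window must lie within [0, epoch_duration]")
  dur <- t1 - t0
  at_end <- abs(t1 - recording$epoch_duration) <= 1e-12
  out <- recording
  out$epoch_duration <- dur
  out$trains <- lapply(recording$trains, function(tr) {
    ts <- tr$timestamps
    ts <- ts[ts >= t0 & (ts < t1 | (at_end & ts <= t1))] - t0
    new_spike_train(tr$electrode_id, ts, dur)
  })
  out
}

#' Total spike count of a recording
#'
#' The sum of all spikes detected across all electrodes in the epoch; the
#' first of the seven network-activity parameters.
#'
#' @param recording an [mea_recording()].
#' @return Integer spike count.
#' @export
total_spikes <- function(recording) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  sum(vapply(recording$trains, function(tr) length(tr$timestamps), integer(1)))
}
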