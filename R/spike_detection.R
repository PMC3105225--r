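#' Raw voltage trace
#'
#' A regularly sampled extracellular voltage signal from one electrode.
#'
#' @param electrode_id electrode label.
#' @param samples numeric vector of voltages in microvolts.
#' @param sampling_rate samples per second; the MEA amplifier digitizes at
#'   25 kHz by default.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(electrode_id, samples, sampling_rate = 25000) {
  samples <- as.numeric(samples)
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_bad_arg("`sampling_rate` must be positive (Hz)")
  if (anyNA(samples)) stop_bad_arg("samples must not contain NA")
  structure(
    list(electrode_id = as.character(electrode_id)[1L], samples = samples,
         sampling_rate = sampling_rate),
    class = "raw_trace")
}

#' Spike-detection configuration
#'
#' Fixed-threshold detection on the raw signal. The default threshold of
#' -20 uV sits roughly 6-8 standard deviations below baseline noise on a
#' typical MEA recording; the waveform cutout spans 1 ms before to 2 ms after
#' the threshold crossing. A dead time (default: the post-crossing window)
#' suppresses re-triggering, so cutouts never overlap.
#'
#' @param threshold detection threshold in microvolts; must be negative
#'   (detection is on the negative-going phase of the extracellular spike).
#' @param pre_window,post_window cutout extent in seconds before/after the
#'   crossing.
#' @param dead_time minimum separation between accepted spikes, seconds.
#' @return An object of class `spike_detection_config`.
#' @export
spike_detection_config <- function(threshold = -20, pre_window = 0.001,
                                   post_window = 0.002,
                                   dead_time = post_window) {
  if (!is_number(threshold) || threshold >= 0)
    stop_bad_arg("`threshold` must be negative (microvolts)")
  for (nm in c("pre_window", "post_window", "dead_time")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) stop_bad_arg("`", nm, "` must be positive")
  }
  structure(
    list(threshold = threshold, pre_window = pre_window,
         post_window = post_window, dead_time = dead_time),
    class = "spike_detection_config")
}

#' Detect spikes on a raw trace
#'
#' Scans the trace left to right and accepts a spike at every sample below
#' `threshold` that lies at least `dead_time` after the previously accepted
#' spike (a signal that stays below threshold therefore re-triggers once per
#' dead time). Each accepted spike gets a waveform cutout of
#' `round(pre_window * rate) + round(post_window * rate) + 1` samples centred
#' on the crossing; crossings too close to either end of the trace for a full
#' cutout are discarded. Spike times are `(sample_index - 1) / sampling_rate`,
#' i.e. seconds from the first sample.
#'
#' @param trace a [raw_trace()].
#' @param config a [spike_detection_config()].
#' @param epoch_duration epoch length attached to the returned train; defaults
#'   to the trace duration.
#' @return A list with elements `train` (a [spike_train()]) and `cutouts`
#'   (numeric matrix, one row per spike).
#' @export
detect_spikes <- function(trace, config = spike_detection_config(),
                          epoch_duration = NULL) {
  if (!inherits(trace, "raw_trace")) stop_bad_arg("`trace` must be a raw_trace")
  if (!inherits(config, "spike_detection_config"))
    stop_bad_arg("`config` must be a spike_detection_config")
  v <- trace$samples
  n <- length(v)
  if (!n) stop_bad_arg("trace is empty")
  rate <- trace$sampling_rate
  npre <- round(config$pre_window * rate)
  npost <- round(config$post_window * rate)
  width <- npre + npost + 1L
  cand <- which(v < config$threshold)
  # full cutout must fit inside the trace
  cand <- cand[cand > npre & cand + npost <= n]
  accepted <- integer(0)
  last_k <- -Inf
  dead_smp <- config$dead_time * rate   # compare in samples: exact arithmetic
  for (k in cand) {
    if (k - last_k >= dead_smp - 1e-9) {
      accepted <- c(accepted, k)
      last_k <- k
    }
  }
  cut <- if (length(accepted)) {
    t(vapply(accepted, function(k) v[(k - npre):(k + npost)], numeric(width)))
  } else {
    matrix(numeric(0), nrow = 0L, ncol = width)
  }
  dur <- epoch_duration %||% (n / rate)
  list(train = new_spike_train(trace$electrode_id, (accepted - 1L) / rate, dur),
       cutouts = cut)
}
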