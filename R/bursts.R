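#' Max-interval burst-detection configuration
#'
#' Thresholds for the three-phase max-interval burst parser. The defaults are
#' the conventional values used with this algorithm family: a burst opens when
#' an interspike interval (ISI) drops to 0.17 s or less, extends while ISIs
#' stay at or below 0.30 s, candidate bursts closer than 0.20 s are merged,
#' and bursts shorter than 0.01 s or with fewer than 3 spikes are discarded.
#'
#' @param max_isi_start largest ISI that can open a burst, seconds.
#' @param max_isi_end largest ISI that can extend a burst, seconds; must be
#'   at least `max_isi_start`.
#' @param min_ibi_merge candidate bursts whose gap (next start minus previous
#'   end) is below this are merged, seconds.
#' @param min_burst_duration minimum burst span, seconds.
#' @param min_spikes_in_burst minimum member spikes (at least 2).
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(max_isi_start = 0.17, max_isi_end = 0.30,
                         min_ibi_merge = 0.20, min_burst_duration = 0.01,
                         min_spikes_in_burst = 3) {
  for (nm in c("max_isi_start", "max_isi_end", "min_ibi_merge",
               "min_burst_duration")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) stop_bad_arg("`", nm, "` must be positive")
  }
  if (max_isi_start > max_isi_end)
    stop_bad_arg("`max_isi_start` must not exceed `max_isi_end`")
  if (!is_number(min_spikes_in_burst) || min_spikes_in_burst < 2)
    stop_bad_arg("`min_spikes_in_burst` must be at least 2")
  structure(
    list(max_isi_start = max_isi_start, max_isi_end = max_isi_end,
         min_ibi_merge = min_ibi_merge,
         min_burst_duration = min_burst_duration,
         min_spikes_in_burst = as.integer(min_spikes_in_burst)),
    class = "burst_config")
}

empty_burst_df <- function() {
  data.frame(start = numeric(), end = numeric(), n_spikes = integer(),
             duration = numeric(), first_spike = integer(),
             last_spike = integer())
}

#' Detect bursts in one spike train (max-interval method)
#'
#' Three phases. Phase 1: scan spikes in order; a candidate burst opens at
#' spike *i* when the ISI to the next spike is at most `max_isi_start` and
#' extends while successive ISIs are at most `max_isi_end`. Phase 2:
#' consecutive candidates whose gap (next start minus previous end) is below
#' `min_ibi_merge` are merged; every spike inside the merged span is a member.
#' Phase 3: candidates shorter than `min_burst_duration` or with fewer than
#' `min_spikes_in_burst` members are discarded.
#'
#' @param train a [spike_train()] or a sorted numeric vector of spike times.
#' @param config a [burst_config()].
#' @return A data frame with one row per burst: `start`, `end` (times of the
#'   first and last member spike), `n_spikes`, `duration`, and the member
#'   index range `first_spike`/`last_spike`. Bursts are disjoint and
#'   time-ordered.
#' @export
detect_bursts <- function(train, config = burst_config()) {
  if (!inherits(config, "burst_config"))
    stop_bad_arg("`config` must be a burst_config")
  t <- if (inherits(train, "spike_train")) train$timestamps else as.numeric(train)
  n <- length(t)
  if (n < 2L) return(empty_burst_df())

  isi <- diff(t)
  run <- rle(isi <= config$max_isi_end)
  run_end <- cumsum(run$lengths)
  run_start <- run_end - run$lengths + 1L

  first <- integer(0)
  last <- integer(0)
  opens <- isi <= config$max_isi_start
  for (g in which(run$values)) {
    a <- run_start[g]; b <- run_end[g]
    f <- match(TRUE, opens[a:b])
    if (!is.na(f)) {
      # burst spans from the opening spike to the end of the <=max_isi_end run
      first <- c(first, a + f - 1L)
      last <- c(last, b + 1L)
    }
  }
  if (!length(first)) return(empty_burst_df())

  # phase 2: sequential left-to-right merge on the inter-candidate gap
  mf <- first[1L]; ml <- last[1L]
  out_f <- integer(0); out_l <- integer(0)
  if (length(first) > 1L) {
    for (k in 2:length(first)) {
      if (t[first[k]] - t[ml] < config$min_ibi_merge) {
        ml <- last[k]
      } else {
        out_f <- c(out_f, mf); out_l <- c(out_l, ml)
        mf <- first[k]; ml <- last[k]
      }
    }
  }
  out_f <- c(out_f, mf); out_l <- c(out_l, ml)

  dur <- t[out_l] - t[out_f]
  nsp <- out_l - out_f + 1L
  keep <- dur >= config$min_burst_duration & nsp >= config$min_spikes_in_burst
  data.frame(start = t[out_f][keep], end = t[out_l][keep],
             n_spikes = nsp[keep], duration = dur[keep],
             first_spike = out_f[keep], last_spike = out_l[keep])
}

#' Detect bursts on every electrode of a recording
#'
#' @param recording an [mea_recording()].
#' @param config a [burst_config()].
#' @return Named list (one burst data frame per electrode, layout order).
#' @export
detect_recording_bursts <- function(recording, config = burst_config()) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  lapply(recording$trains, detect_bursts, config = config)
}

#' Per-electrode burst summary
#'
#' Burst rate, durations and inter-burst intervals (IBIs) for one electrode.
#' IBIs are onset-to-onset by default; `ibi_mode = "gap"` measures previous
#' end to next onset instead.
#'
#' @param bursts a burst data frame from [detect_bursts()].
#' @param epoch_duration epoch length in seconds.
#' @param electrode_id optional label carried into the summary.
#' @param ibi_mode `"onset"` (onset-to-onset, default) or `"gap"`.
#' @return A list with `electrode_id`, `n_bursts`, `burst_rate_per_min`,
#'   `durations`, `ibis` and `mean_ibi` (`NA` with fewer than 2 bursts).
#' @export
summarize_bursts <- function(bursts, epoch_duration, electrode_id = NA_character_,
                             ibi_mode = c("onset", "gap")) {
  ibi_mode <- match.arg(ibi_mode)
  if (!is_number(epoch_duration) || epoch_duration <= 0)
    stop_bad_arg("`epoch_duration` must be positive")
  nb <- nrow(bursts)
  ibis <- if (nb >= 2L) {
    if (ibi_mode == "onset") diff(bursts$start)
    else bursts$start[-1L] - bursts$end[-nb]
  } else numeric(0)
  list(electrode_id = electrode_id,
       n_bursts = nb,
       burst_rate_per_min = nb / (epoch_duration / 60),
       durations = bursts$duration,
       ibis = ibis,
       mean_ibi = if (length(ibis)) mean(ibis) else NA_real_)
}

summarize_recording_bursts <- function(recording, bursts,
                                       ibi_mode = c("onset", "gap")) {
  ibi_mode <- match.arg(ibi_mode)
  Map(function(id, b) summarize_bursts(b, recording$epoch_duration, id,
                                       ibi_mode = ibi_mode),
      names(bursts), bursts)
}
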