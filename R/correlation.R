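#' Correlation-index configuration
#'
#' The correlation index counts near-coincident event pairs between two
#' electrodes within a half-window `delta_t` (0.1 ms by default) and
#' normalizes so that two independent stationary trains score about 1.
#'
#' @param delta_t coincidence half-window in seconds.
#' @param event_source which events enter the pairwise statistic: every spike
#'   (`"all_spikes"`, default), only spikes inside detected bursts
#'   (`"burst_spikes"`), or burst onset times (`"burst_onsets"`).
#' @param pair_inclusion electrode pairs entering the network mean:
#'   `"both_active"` (default; both electrodes have at least one event) or
#'   `"both_bursting"` (both electrodes have at least one detected burst).
#' @return An object of class `correlation_config`.
#' @export
correlation_config <- function(delta_t = 1e-4,
                               event_source = c("all_spikes", "burst_spikes",
                                                "burst_onsets"),
                               pair_inclusion = c("both_active",
                                                  "both_bursting")) {
  if (!is_number(delta_t) || delta_t <= 0)
    stop_bad_arg("`delta_t` must be positive (seconds)")
  structure(
    list(delta_t = delta_t, event_source = match.arg(event_source),
         pair_inclusion = match.arg(pair_inclusion)),
    class = "correlation_config")
}

# number of pairs (x in a, y in b) with |x - y| <= dt; a, b sorted
count_coincidences <- function(a, b, dt) {
  hi <- findInterval(a + dt, b)          # y <= x + dt
  lo <- findInterval(a - dt, b)          # y <= x - dt
  # findInterval counts y <= x - dt inclusively; re-admit exact ties at x - dt
  ties <- lo >= 1L & b[pmax(lo, 1L)] == a - dt
  sum(hi - lo + ties)
}

#' Pairwise correlation index
#'
#' `CI = N_ab * T / (N_a * N_b * 2 * delta_t)` where `N_ab` is the number of
#' event pairs across the two trains separated by at most `delta_t`. For two
#' independent homogeneous trains the expectation is 1; identical trains of
#' `N` isolated events score `T / (N * 2 * delta_t)`.
#'
#' @param a,b sorted numeric event-time vectors (seconds, within `[0, T]`).
#' @param delta_t coincidence half-window, seconds.
#' @param epoch_duration epoch length `T`, seconds.
#' @return The correlation index, or `NA` if either train is empty.
#' @export
correlation_index_pair <- function(a, b, delta_t = 1e-4,
                                   epoch_duration = 900) {
  if (!is_number(delta_t) || delta_t <= 0)
    stop_bad_arg("`delta_t` must be positive (seconds)")
  if (!is_number(epoch_duration) || epoch_duration <= 0)
    stop_bad_arg("`epoch_duration` must be positive (seconds)")
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(NA_real_)
  nab <- count_coincidences(a, b, delta_t)
  nab * epoch_duration / (na * nb * 2 * delta_t)
}

event_lists <- function(recording, bursts, config) {
  switch(config$event_source,
    all_spikes = lapply(recording$trains, `[[`, "timestamps"),
    burst_onsets = lapply(bursts, `[[`, "start"),
    burst_spikes = Map(function(tr, b) {
      if (!nrow(b)) return(numeric(0))
      idx <- unlist(Map(seq.int, b$first_spike, b$last_spike),
                    use.names = FALSE)
      tr$timestamps[idx]
    }, recording$trains, bursts))
}

#' Network correlation index
#'
#' Mean pairwise correlation index over all unordered electrode pairs passing
#' the inclusion rule of `config`.
#'
#' @param recording an [mea_recording()].
#' @param bursts per-electrode burst list (needed for burst-based event
#'   sources and the `"both_bursting"` inclusion rule); may be `NULL` with
#'   the default all-spikes configuration.
#' @param config a [correlation_config()].
#' @return Mean CI, or `NA` when no pair qualifies.
#' @export
correlation_index <- function(recording, bursts = NULL,
                              config = correlation_config()) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  needs_bursts <- config$event_source != "all_spikes" ||
    config$pair_inclusion == "both_bursting"
  if (needs_bursts && is.null(bursts))
    stop_bad_arg("`bursts` are required for this correlation configuration")
  ev <- event_lists(recording, bursts, config)
  ok <- vapply(ev, length, integer(1)) > 0L
  if (config$pair_inclusion == "both_bursting")
    ok <- ok & vapply(bursts, nrow, integer(1)) > 0L
  idx <- which(ok)
  if (length(idx) < 2L) return(NA_real_)
  TT <- recording$epoch_duration
  dt <- config$delta_t
  tot <- 0
  np <- 0L
  for (i in seq_len(length(idx) - 1L)) {
    a <- ev[[idx[i]]]
    for (j in (i + 1L):length(idx)) {
      tot <- tot + correlation_index_pair(a, ev[[idx[j]]], dt, TT)
      np <- np + 1L
    }
  }
  tot / np
}
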