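#' Percentage of spikes fired within bursts
#'
#' @param recording an [mea_recording()].
#' @param bursts per-electrode burst list from [detect_recording_bursts()],
#'   derived from the same recording.
#' @return Percent in `[0, 100]`; `NA` when the recording has no spikes.
#' @export
pct_spikes_in_bursts <- function(recording, bursts) {
  tot <- total_spikes(recording)
  if (tot == 0L) return(NA_real_)
  inside <- sum(vapply(bursts, function(b) sum(b$n_spikes), numeric(1)))
  100 * inside / tot
}

qualifying_rates <- function(summaries) {
  vapply(summaries, `[[`, numeric(1), "burst_rate_per_min")
}

#' Mean burst rate over actively bursting electrodes
#'
#' Average bursts per minute across all electrodes detecting more than one
#' burst per minute; `NA` when no electrode qualifies.
#'
#' @param summaries list of per-electrode summaries from
#'   [summarize_bursts()].
#' @return Bursts per minute or `NA`.
#' @export
burst_rate <- function(summaries) {
  r <- qualifying_rates(summaries)
  r <- r[r > 1]
  if (!length(r)) return(NA_real_)
  mean(r)
}

#' Mean burst duration over actively bursting electrodes
#'
#' Average duration of all bursts pooled over electrodes detecting more than
#' one burst per minute; `NA` when none qualify.
#'
#' @inheritParams burst_rate
#' @return Seconds or `NA`.
#' @export
burst_duration <- function(summaries) {
  r <- qualifying_rates(summaries)
  d <- unlist(lapply(summaries[r > 1], `[[`, "durations"), use.names = FALSE)
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Burst-pattern statistic (CV of the inter-burst interval)
#'
#' Each electrode with at least two bursts contributes its mean inter-burst
#' interval; the statistic is the coefficient of variation (sample standard
#' deviation over mean) of those per-electrode means. Higher values indicate
#' less temporal structure across the network. `mode = "within_electrode"`
#' instead averages each electrode's own IBI CV.
#'
#' @inheritParams burst_rate
#' @param mode `"across_electrodes"` (default) or `"within_electrode"`.
#' @return Dimensionless CV; `NA` when fewer than 2 electrodes (or, in the
#'   within-electrode mode, none) contribute.
#' @export
burst_pattern <- function(summaries,
                          mode = c("across_electrodes", "within_electrode")) {
  mode <- match.arg(mode)
  if (mode == "across_electrodes") {
    m <- vapply(summaries, `[[`, numeric(1), "mean_ibi")
    m <- m[!is.na(m)]
    if (length(m) < 2L || mean(m) == 0) return(NA_real_)
    stats::sd(m) / mean(m)
  } else {
    cvs <- vapply(summaries, function(s) {
      if (length(s$ibis) < 2L || mean(s$ibis) == 0) return(NA_real_)
      stats::sd(s$ibis) / mean(s$ibis)
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) return(NA_real_)
    mean(cvs)
  }
}

#' Network size
#'
#' The number of electrodes detecting at least one burst per minute — a proxy
#' for how many electrodes sit within the functional network.
#'
#' @inheritParams burst_rate
#' @return Integer electrode count.
#' @export
network_size <- function(summaries) {
  sum(qualifying_rates(summaries) >= 1)
}

#' Compute the network-activity parameter set
#'
#' Runs burst detection once and derives the seven network parameters —
#' total spikes, percentage of spikes in bursts, burst rate, burst duration,
#' burst pattern (IBI CV), network size and correlation index — consistently
#' from the same burst set. `params` restricts computation to a subset.
#' Undefined parameters (e.g. burst rate in a silent culture) are `NA`,
#' never zero.
#'
#' @param recording an [mea_recording()].
#' @param burst_cfg a [burst_config()].
#' @param corr_cfg a [correlation_config()].
#' @param params character vector of parameter names to compute.
#' @return An object of class `network_params`: a named list of parameter
#'   values with the configurations attached as attributes.
#' @export
compute_network_params <- function(recording, burst_cfg = burst_config(),
                                   corr_cfg = correlation_config(),
                                   params = c("total_spikes",
                                              "pct_spikes_in_bursts",
                                              "burst_rate", "burst_duration",
                                              "burst_pattern", "network_size",
                                              "correlation_index")) {
  params <- match.arg(params, several.ok = TRUE)
  bursts <- detect_recording_bursts(recording, burst_cfg)
  summaries <- summarize_recording_bursts(recording, bursts)
  out <- list()
  for (p in params) {
    out[[p]] <- switch(p,
      total_spikes = as.numeric(total_spikes(recording)),
      pct_spikes_in_bursts = pct_spikes_in_bursts(recording, bursts),
      burst_rate = burst_rate(summaries),
      burst_duration = burst_duration(summaries),
      burst_pattern = burst_pattern(summaries),
      network_size = as.numeric(network_size(summaries)),
      correlation_index = correlation_index(recording, bursts, corr_cfg))
  }
  structure(out, class = "network_params", burst_config = burst_cfg,
            correlation_config = corr_cfg)
}

#' @export
print.network_params <- function(x, digits = 4, ...) {
  cat("Network-activity parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(x[[nm]], digits = digits)))
  invisible(x)
}

#' Names of the seven network parameters
#' @return Character vector in canonical order.
#' @export
network_parameter_names <- function() {
  c("total_spikes", "pct_spikes_in_bursts", "burst_rate", "burst_duration",
    "burst_pattern", "network_size", "correlation_index")
}
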