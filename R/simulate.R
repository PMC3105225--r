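#' Simulation configuration
#'
#' Generative model of one MEA recording from a developing culture. Each
#' electrode fires tonic (out-of-burst) spikes as a homogeneous Poisson
#' process. Network-wide burst events arrive as a Poisson process at
#' `net_burst_rate`; each electrode joins each event with probability
#' `participation_prob`, its onset shifted by zero-mean Gaussian jitter, and
#' emits a burst of `max(3, Poisson(spikes_per_burst_mean))` spikes with
#' exponential intra-burst ISIs. Electrodes additionally emit asynchronous
#' bursts of the same shape at `indep_burst_rate`. Per-electrode excitability
#' is spread by a lognormal multiplier of unit mean and coefficient of
#' variation `rate_heterogeneity_cv`, applied to the tonic and independent
#' burst rates. All spikes are clipped to `[0, epoch_duration]`, merged,
#' sorted and de-duplicated at 1 microsecond resolution. A given `seed`
#' reproduces the recording exactly.
#'
#' @param layout an [mea_layout()].
#' @param epoch_duration epoch length, seconds (default 900 s = 15 min).
#' @param tonic_rate tonic firing rate per electrode, Hz.
#' @param net_burst_rate network burst-event rate, events per minute.
#' @param participation_prob probability an electrode joins a network event.
#' @param onset_jitter_sd SD of the per-electrode burst-onset jitter, seconds.
#' @param spikes_per_burst_mean mean spike count per burst (floor of 3).
#' @param intra_burst_isi_mean mean ISI inside a burst, seconds.
#' @param indep_burst_rate per-electrode asynchronous burst rate, events/min.
#' @param rate_heterogeneity_cv CV of the per-electrode excitability spread.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout = default_mea_layout(), epoch_duration = 900,
                       tonic_rate = 0.5, net_burst_rate = 2,
                       participation_prob = 0.8, onset_jitter_sd = 0.02,
                       spikes_per_burst_mean = 10,
                       intra_burst_isi_mean = 0.015, indep_burst_rate = 0.3,
                       rate_heterogeneity_cv = 0.3, seed = 1L) {
  if (!inherits(layout, "mea_layout")) stop_bad_arg("`layout` must be an mea_layout")
  for (nm in c("epoch_duration", "tonic_rate", "net_burst_rate",
               "onset_jitter_sd", "spikes_per_burst_mean",
               "intra_burst_isi_mean", "indep_burst_rate",
               "rate_heterogeneity_cv")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stop_bad_arg("`", nm, "` must be >= 0")
  }
  if (epoch_duration <= 0) stop_bad_arg("`epoch_duration` must be positive")
  if (!is_number(participation_prob) || participation_prob < 0 ||
      participation_prob > 1)
    stop_bad_arg("`participation_prob` must be in [0, 1]")
  if (!is_number(seed)) stop_bad_arg("`seed` must be a single integer")
  structure(
    list(layout = layout, epoch_duration = epoch_duration,
         tonic_rate = tonic_rate, net_burst_rate = net_burst_rate,
         participation_prob = participation_prob,
         onset_jitter_sd = onset_jitter_sd,
         spikes_per_burst_mean = spikes_per_burst_mean,
         intra_burst_isi_mean = intra_burst_isi_mean,
         indep_burst_rate = indep_burst_rate,
         rate_heterogeneity_cv = rate_heterogeneity_cv,
         seed = as.integer(seed)),
    class = "sim_config")
}

sim_numeric_fields <- function() {
  c("epoch_duration", "tonic_rate", "net_burst_rate", "participation_prob",
    "onset_jitter_sd", "spikes_per_burst_mean", "intra_burst_isi_mean",
    "indep_burst_rate", "rate_heterogeneity_cv")
}

# spike times for k bursts with onsets `onsets`; vectorized over bursts
burst_spike_times <- function(onsets, mean_spikes, isi_mean) {
  k <- length(onsets)
  if (!k) return(numeric(0))
  n <- pmax(3L, stats::rpois(k, mean_spikes))
  total <- sum(n)
  pos <- sequence(n)
  isis <- if (isi_mean > 0) stats::rexp(total, rate = 1 / isi_mean)
          else numeric(total)
  isis[pos == 1L] <- 0
  cs <- cumsum(isis)
  base <- rep.int(cs[pos == 1L], n)
  rep.int(onsets, n) + (cs - base)
}

#' Simulate one MEA recording
#'
#' Draws a recording from the generative model described in [sim_config()].
#'
#' @param config a [sim_config()].
#' @param div,condition,culture_id metadata attached to the result.
#' @return An [mea_recording()].
#' @export
simulate_recording <- function(config, div = NA_integer_,
                               condition = NA_character_,
                               culture_id = NA_character_) {
  if (!inherits(config, "sim_config"))
    stop_bad_arg("`config` must be a sim_config")
  with_seed(config$seed, {
    ids <- config$layout$electrode_ids
    nE <- length(ids)
    TT <- config$epoch_duration
    cv <- config$rate_heterogeneity_cv
    mult <- if (cv > 0) {
      s2 <- log(1 + cv^2)
      stats::rlnorm(nE, meanlog = -s2 / 2, sdlog = sqrt(s2))  # unit mean
    } else rep(1, nE)
    n_events <- stats::rpois(1L, config$net_burst_rate / 60 * TT)
    events <- sort(stats::runif(n_events, 0, TT))
    trains <- vector("list", nE)
    for (e in seq_len(nE)) {
      s <- stats::runif(stats::rpois(1L, config$tonic_rate * mult[e] * TT),
                        0, TT)
      if (n_events) {
        join <- stats::runif(n_events) < config$participation_prob
        onsets <- events[join]
        if (length(onsets) && config$onset_jitter_sd > 0)
          onsets <- onsets + stats::rnorm(length(onsets), 0,
                                          config$onset_jitter_sd)
        s <- c(s, burst_spike_times(onsets, config$spikes_per_burst_mean,
                                    config$intra_burst_isi_mean))
      }
      n_ind <- stats::rpois(1L, config$indep_burst_rate * mult[e] / 60 * TT)
      if (n_ind) {
        s <- c(s, burst_spike_times(stats::runif(n_ind, 0, TT),
                                    config$spikes_per_burst_mean,
                                    config$intra_burst_isi_mean))
      }
      s <- sort(s[s >= 0 & s <= TT])
      if (length(s) > 1L) s <- s[c(TRUE, diff(s) >= 1e-6)]
      trains[[e]] <- new_spike_train(ids[e], s, TT)
    }
    mea_recording(trains, layout = config$layout, div = div,
                  condition = condition, culture_id = culture_id,
                  epoch_duration = TT)
  })
}

#' Developmental trajectory of simulation parameters
#'
#' A pair of [sim_config()] endpoints at DIV 5 and DIV 12; configurations for
#' intermediate days are obtained by linear interpolation of every numeric
#' field ([trajectory_config()]).
#'
#' @param div5,div12 `sim_config` endpoints.
#' @return An object of class `div_trajectory`.
#' @export
div_trajectory <- function(div5, div12) {
  if (!inherits(div5, "sim_config") || !inherits(div12, "sim_config"))
    stop_bad_arg("trajectory endpoints must be sim_config objects")
  structure(list(div5 = div5, div12 = div12), class = "div_trajectory")
}

#' Default maturation trajectory
#'
#' Endpoints chosen to emulate the developmental transition of hippocampal
#' cultures between DIV 5 (sparse, weakly coordinated firing) and DIV 12
#' (dense synchronized network bursting): tonic rate 0.2 -> 1.0 Hz, network
#' events 0.5 -> 3 per minute, participation 0.3 -> 0.9, onset jitter
#' 50 -> 20 ms, 6 -> 12 spikes per burst with 20 -> 10 ms intra-burst ISIs,
#' and independent bursts 0.2 -> 0.5 per minute.
#'
#' @param layout an [mea_layout()].
#' @param epoch_duration epoch length, seconds.
#' @return A [div_trajectory()].
#' @export
default_trajectory <- function(layout = default_mea_layout(),
                               epoch_duration = 900) {
  div_trajectory(
    sim_config(layout = layout, epoch_duration = epoch_duration,
               tonic_rate = 0.2, net_burst_rate = 0.5,
               participation_prob = 0.3, onset_jitter_sd = 0.05,
               spikes_per_burst_mean = 6, intra_burst_isi_mean = 0.02,
               indep_burst_rate = 0.2, rate_heterogeneity_cv = 0.3),
    sim_config(layout = layout, epoch_duration = epoch_duration,
               tonic_rate = 1.0, net_burst_rate = 3,
               participation_prob = 0.9, onset_jitter_sd = 0.02,
               spikes_per_burst_mean = 12, intra_burst_isi_mean = 0.01,
               indep_burst_rate = 0.5, rate_heterogeneity_cv = 0.3))
}

#' Interpolated configuration for one day in vitro
#'
#' Linear interpolation of every numeric field between the DIV-5 and DIV-12
#' endpoints of a trajectory. `div` may be fractional inside `[5, 12]`.
#'
#' @param traj a [div_trajectory()].
#' @param div day in vitro in `[5, 12]`.
#' @param seed seed for the resulting configuration.
#' @return A [sim_config()].
#' @export
trajectory_config <- function(traj, div, seed = traj$div5$seed) {
  if (!inherits(traj, "div_trajectory"))
    stop_bad_arg("`traj` must be a div_trajectory")
  if (!is_number(div) || div < 5 || div > 12)
    stop_bad_arg("`div` must lie in [5, 12]")
  w <- (div - 5) / 7
  cfg <- traj$div5
  for (nm in sim_numeric_fields())
    cfg[[nm]] <- (1 - w) * traj$div5[[nm]] + w * traj$div12[[nm]]
  cfg$seed <- as.integer(seed)
  cfg
}

#' Knockdown condition presets
#'
#' Named presets describing how a condition perturbs the maturation
#' trajectory from an onset day onward: multiplicative factors and absolute
#' overrides on [sim_config()] fields, fields frozen at their value one day
#' before onset, an optional recovery day from which the perturbation is
#' lifted. `"control"` and `"ntc"` (non-targeting control) are identity
#' presets. The remaining presets emulate the qualitative knockdown
#' phenotypes: `"tnik_kd"` (from DIV 8: tighter, shorter bursts — halved
#' intra-burst ISI and tonic rate, reduced onset jitter, reduced independent
#' bursting and excitability spread, raising burst synchrony), `"dlg2_kd"`
#' (DIV 6-11: more and longer bursts, recovering by DIV 12), `"disc1_kd"`
#' (longer bursts at DIV 12 only) and `"dctn5_kd"` (from DIV 7: network
#' burst-event rate pinned to 5.8 per minute with full participation, so
#' every bursting electrode is driven at the elevated rate through DIV 12;
#' the knockdown's arrest of network-size growth is not modelled — see the
#' vignette). Effect sizes other than the
#' 5.8/min figure are package fixture constants, chosen to be large relative
#' to between-culture sampling variability at 8 cultures per condition.
#'
#' @param name one of `"control"`, `"ntc"`, `"tnik_kd"`, `"dlg2_kd"`,
#'   `"disc1_kd"`, `"dctn5_kd"`.
#' @return An object of class `condition_preset` with fields `name`,
#'   `effect_onset_div`, `recovery_div`, `multipliers`, `overrides`,
#'   `freeze_fields`.
#' @export
condition_preset <- function(name) {
  presets <- list(
    control = list(effect_onset_div = 5L, recovery_div = NA_integer_,
                   multipliers = numeric(), overrides = numeric(),
                   freeze_fields = character()),
    tnik_kd = list(effect_onset_div = 8L, recovery_div = NA_integer_,
                   multipliers = c(intra_burst_isi_mean = 0.5,
                                   tonic_rate = 0.5,
                                   onset_jitter_sd = 0.3,
                                   indep_burst_rate = 0.3,
                                   rate_heterogeneity_cv = 0.3),
                   overrides = numeric(), freeze_fields = character()),
    dlg2_kd = list(effect_onset_div = 6L, recovery_div = 12L,
                   multipliers = c(net_burst_rate = 1.8,
                                   spikes_per_burst_mean = 1.6),
                   overrides = numeric(), freeze_fields = character()),
    disc1_kd = list(effect_onset_div = 12L, recovery_div = NA_integer_,
                    multipliers = c(spikes_per_burst_mean = 1.8,
                                    intra_burst_isi_mean = 1.3),
                    overrides = numeric(), freeze_fields = character()),
    dctn5_kd = list(effect_onset_div = 7L, recovery_div = NA_integer_,
                    multipliers = numeric(),
                    overrides = c(net_burst_rate = 5.8,
                                  participation_prob = 1),
                    freeze_fields = character()))
  presets$ntc <- presets$control  # no control/NTC differences are modelled
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop_bad_arg("unknown condition preset '", paste(name, collapse = ","),
                 "'; choose one of ", paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  p$name <- name
  structure(p, class = "condition_preset")
}

#' Apply a condition preset to a trajectory at one DIV
#'
#' Starts from [trajectory_config()] at `div`; if `div` is at or past the
#' preset onset (and before any recovery day), frozen fields are reset to
#' their trajectory value one day before onset, multipliers are applied, and
#' overrides replace field values.
#'
#' @param preset a [condition_preset()] or preset name.
#' @param traj a [div_trajectory()].
#' @param div day in vitro in `[5, 12]`.
#' @param seed seed for the resulting configuration.
#' @return A [sim_config()].
#' @export
preset_config <- function(preset, traj, div, seed = traj$div5$seed) {
  if (is.character(preset)) preset <- condition_preset(preset)
  if (!inherits(preset, "condition_preset"))
    stop_bad_arg("`preset` must be a condition_preset or preset name")
  cfg <- trajectory_config(traj, div, seed = seed)
  active <- div >= preset$effect_onset_div &&
    (is.na(preset$recovery_div) || div < preset$recovery_div)
  if (active) {
    if (length(preset$freeze_fields)) {
      frozen_div <- max(5, preset$effect_onset_div - 1)
      frozen <- trajectory_config(traj, frozen_div, seed = seed)
      for (nm in preset$freeze_fields) cfg[[nm]] <- frozen[[nm]]
    }
    for (nm in names(preset$multipliers))
      cfg[[nm]] <- cfg[[nm]] * preset$multipliers[[nm]]
    for (nm in names(preset$overrides))
      cfg[[nm]] <- preset$overrides[[nm]]
  }
  cfg
}

#' Simulate a multi-condition experiment
#'
#' One recording per (condition, culture, DIV), with per-recording sub-seeds
#' derived deterministically from the master seed so cultures are independent
#' and the whole dataset reproduces exactly.
#'
#' @param presets named character vector mapping condition labels to preset
#'   names, e.g. `c(untransfected = "control", ntc = "ntc", kd = "dctn5_kd")`.
#' @param n_cultures cultures per condition (at least 2 for statistics).
#' @param divs integer days in vitro to record, within `[5, 12]`.
#' @param trajectory a [div_trajectory()].
#' @param seed master seed.
#' @return A list of [mea_recording()]s with a `manifest` attribute
#'   (data frame: condition, culture_id, div, seed).
#' @export
simulate_experiment <- function(presets, n_cultures = 8, divs = 5:12,
                                trajectory = default_trajectory(),
                                seed = 1L) {
  if (is.null(names(presets)) || any(names(presets) == ""))
    stop_bad_arg("`presets` must be a named vector: condition label -> preset")
  if (!is_number(n_cultures) || n_cultures < 2)
    stop_bad_arg("`n_cultures` must be at least 2")
  design <- expand.grid(div = as.integer(divs),
                        culture = seq_len(n_cultures),
                        condition = names(presets),
                        stringsAsFactors = FALSE)
  design <- design[order(design$condition, design$culture, design$div), ]
  seeds <- derive_seeds(seed, nrow(design))
  recs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    cfg <- preset_config(presets[[cond]], trajectory, design$div[i],
                         seed = seeds[i])
    recs[[i]] <- simulate_recording(
      cfg, div = design$div[i], condition = cond,
      culture_id = sprintf("%s_C%02d", cond, design$culture[i]))
  }
  manifest <- data.frame(condition = design$condition,
                         culture_id = sprintf("%s_C%02d", design$condition,
                                              design$culture),
                         div = design$div, seed = seeds,
                         stringsAsFactors = FALSE)
  attr(recs, "manifest") <- manifest
  recs
}

#' Network parameters for every recording of an experiment
#'
#' @param recordings list of [mea_recording()]s (e.g. from
#'   [simulate_experiment()]).
#' @param burst_cfg,corr_cfg configurations passed to
#'   [compute_network_params()].
#' @param params parameter subset to compute.
#' @return Data frame with one row per recording: `condition`, `culture_id`,
#'   `div` and one column per parameter.
#' @export
experiment_params <- function(recordings, burst_cfg = burst_config(),
                              corr_cfg = correlation_config(),
                              params = network_parameter_names()) {
  rows <- lapply(recordings, function(rec) {
    ps <- compute_network_params(rec, burst_cfg, corr_cfg, params = params)
    cbind(data.frame(condition = rec$condition, culture_id = rec$culture_id,
                     div = rec$div, stringsAsFactors = FALSE),
          as.data.frame(unclass(ps)[params]))
  })
  do.call(rbind, rows)
}
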