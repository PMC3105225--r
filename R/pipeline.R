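#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> burst-detect -> parameterize -> test -> barcode
#' and writes a deterministic output bundle: an experiment manifest, a
#' combined burst table, the per-recording network-parameter table, the
#' per-cell statistics report, the barcode matrix and a YAML provenance file
#' recording every configuration and the master seed. Re-running with the
#' same configuration and seed reproduces the bundle byte for byte.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulation}{list with `presets` (named condition -> preset map),
#'       `n_cultures`, `divs`; required unless `recordings` is supplied.}
#'     \item{burst}{optional overrides for [burst_config()] fields.}
#'     \item{correlation}{optional overrides for [correlation_config()].}
#'     \item{stats}{optional `alpha`, `protected`, `kd`, `ut`, `ntc`.}
#'     \item{out_dir}{output directory, created if needed.}
#'     \item{seed}{master seed.}
#'   }
#' @param recordings optional pre-loaded list of [mea_recording()]s; when
#'   given, the simulation stage is skipped.
#' @return Invisibly, a list with the computed objects (`manifest`,
#'   `param_table`, `barcode`) and the written file paths.
#' @export
run_pipeline <- function(config, recordings = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$out_dir))
    stop_bad_arg("`config` must be a list (or YAML file) with an `out_dir`")
  seed <- as.integer(config$seed %||% 1L)
  burst_cfg <- do.call(burst_config, config$burst %||% list())
  corr_cfg <- do.call(correlation_config, config$correlation %||% list())
  st <- config$stats %||% list()
  alpha <- st$alpha %||% 0.05
  protected <- st$protected %||% TRUE

  if (is.null(recordings)) {
    sim <- config$simulation
    if (is.null(sim) || is.null(sim$presets) || !length(sim$presets))
      stop_bad_arg("config must supply `recordings` or a non-empty ",
                   "`simulation$presets` map")
    presets <- unlist(sim$presets)
    recordings <- simulate_experiment(
      presets, n_cultures = sim$n_cultures %||% 8,
      divs = sim$divs %||% 5:12, seed = seed)
  } else if (!length(recordings)) {
    stop_bad_arg("`recordings` is empty")
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    manifest = file.path(out_dir, "manifest.csv"),
    bursts = file.path(out_dir, "bursts.csv"),
    params = file.path(out_dir, "network_params.csv"),
    stats = file.path(out_dir, "stats_report.csv"),
    barcode = file.path(out_dir, "barcode.csv"),
    provenance = file.path(out_dir, "provenance.yaml"))

  manifest <- attr(recordings, "manifest") %||% data.frame(
    condition = vapply(recordings, `[[`, character(1), "condition"),
    culture_id = vapply(recordings, `[[`, character(1), "culture_id"),
    div = vapply(recordings, `[[`, integer(1), "div"),
    seed = NA_integer_, stringsAsFactors = FALSE)
  utils::write.csv(manifest, paths$manifest, row.names = FALSE)

  all_bursts <- lapply(recordings, function(rec) {
    b <- burst_table(detect_recording_bursts(rec, burst_cfg))
    if (nrow(b))
      cbind(data.frame(condition = rec$condition, culture_id = rec$culture_id,
                       div = rec$div, stringsAsFactors = FALSE), b)
  })
  all_bursts <- do.call(rbind, all_bursts)
  if (is.null(all_bursts))
    all_bursts <- data.frame(condition = character(), culture_id = character(),
                             div = integer(), electrode_id = character(),
                             start_s = numeric(), end_s = numeric(),
                             n_spikes = integer())
  utils::write.csv(all_bursts, paths$bursts, row.names = FALSE)

  param_table <- experiment_params(recordings, burst_cfg, corr_cfg)
  utils::write.csv(param_table, paths$params, row.names = FALSE)

  conds <- unique(param_table$condition)
  kd <- st$kd %||% setdiff(conds, c("untransfected", "ntc"))[1L]
  ut <- st$ut %||% "untransfected"
  ntc <- st$ntc %||% "ntc"
  barcode <- NULL
  if (!is.na(kd) && all(c(kd, ut, ntc) %in% conds)) {
    barcode <- build_barcode(param_table, kd = kd, ut = ut, ntc = ntc,
                             alpha = alpha, protected = protected)
    utils::write.csv(as.data.frame(barcode), paths$stats, row.names = FALSE)
    utils::write.csv(as.matrix(barcode), paths$barcode)
  }

  yaml::write_yaml(list(
    package = "meaburst",
    version = as.character(utils::packageVersion("meaburst")),
    seed = seed,
    burst_config = unclass(burst_cfg),
    correlation_config = unclass(corr_cfg),
    stats = list(alpha = alpha, protected = protected,
                 kd = if (!is.na(kd)) kd else NULL, ut = ut, ntc = ntc),
    simulation = config$simulation), paths$provenance)

  invisible(list(manifest = manifest, param_table = param_table,
                 barcode = barcode, paths = paths))
}

#' Raster plot of a recording
#'
#' One row per electrode in layout order, a tick per spike; detected bursts
#' may be boxed. The standard view of synchronized network bursting: in a
#' mature culture, vertical stripes of closely packed ticks span most rows.
#'
#' @param recording an [mea_recording()].
#' @param bursts optional per-electrode burst list from
#'   [detect_recording_bursts()]; spans `[start, end]` are boxed.
#' @param xlim time range shown, seconds.
#' @param main title.
#' @param ... further arguments passed to `plot`.
#' @return `recording`, invisibly.
#' @export
plot_raster <- function(recording, bursts = NULL,
                        xlim = c(0, recording$epoch_duration),
                        main = NULL, ...) {
  if (!inherits(recording, "mea_recording"))
    stop_bad_arg("`recording` must be an mea_recording")
  ids <- names(recording$trains)
  nE <- length(ids)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nE + 0.5),
                 xlab = "time (s)", ylab = "electrode", yaxt = "n",
                 main = main %||% sprintf("%s DIV %s",
                                          recording$condition, recording$div),
                 ...)
  at <- pretty(seq_len(nE))
  at <- at[at >= 1 & at <= nE]
  graphics::axis(2, at = at, labels = ids[at], las = 1, cex.axis = 0.6)
  for (e in seq_len(nE)) {
    ts <- recording$trains[[e]]$timestamps
    if (length(ts))
      graphics::segments(ts, e - 0.4, ts, e + 0.4, lwd = 0.5)
    if (!is.null(bursts)) {
      b <- bursts[[ids[e]]]
      if (!is.null(b) && nrow(b))
        graphics::rect(b$start, e - 0.45, b$end, e + 0.45, border = "red",
                       lwd = 0.6)
    }
  }
  invisible(recording)
}

#' @export
plot.mea_recording <- function(x, ...) plot_raster(x, ...)
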