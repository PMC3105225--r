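small_layout <- function(n = 8) {
  mea_layout(paste0("e", seq_len(n)), cbind(row = seq_len(n), col = 1L))
}

test_that("the simulator is silent at zero rates and deterministic under seed", {
  cfg <- sim_config(layout = small_layout(), epoch_duration = 300,
                    tonic_rate = 0, net_burst_rate = 0,
                    participation_prob = 0, spikes_per_burst_mean = 0,
                    indep_burst_rate = 0, rate_heterogeneity_cv = 0, seed = 5)
  expect_equal(total_spikes(simulate_recording(cfg)), 0)

  cfg2 <- sim_config(layout = small_layout(), epoch_duration = 300, seed = 77)
  r1 <- simulate_recording(cfg2)
  r2 <- simulate_recording(cfg2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_spike_table(r1, p1); write_spike_table(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed changes the data
  cfg3 <- sim_config(layout = small_layout(), epoch_duration = 300, seed = 78)
  expect_false(identical(r1$trains, simulate_recording(cfg3)$trains))
})

test_that("simulated spikes are valid trains with expected Poisson counts", {
  cfg <- sim_config(layout = small_layout(20), epoch_duration = 900,
                    tonic_rate = 0.8, net_burst_rate = 2,
                    participation_prob = 0.5, onset_jitter_sd = 0.01,
                    spikes_per_burst_mean = 8, intra_burst_isi_mean = 0.01,
                    indep_burst_rate = 0.5, rate_heterogeneity_cv = 0,
                    seed = 12)
  rec <- simulate_recording(cfg)
  for (tr in rec$trains) {
    ts <- tr$timestamps
    expect_true(all(ts >= 0 & ts <= 900))
    if (length(ts) > 1) expect_true(all(diff(ts) >= 1e-6 - 1e-12))
  }
  # expectation: tonic + (network participation + independent) bursts
  en <- pmax(3, rpois(2e5, 8))          # minimum-3 clipping
  e_burst <- mean(en)
  expected <- 20 * (0.8 * 900 +
                    (2 / 60 * 900 * 0.5 + 0.5 / 60 * 900) * e_burst)
  expect_lt(abs(total_spikes(rec) - expected) / expected, 0.1)
})

test_that("trajectory interpolation is linear with exact endpoints", {
  traj <- default_trajectory(layout = small_layout(), epoch_duration = 600)
  expect_error(trajectory_config(traj, 4), "\\[5, 12\\]")
  c5 <- trajectory_config(traj, 5)
  c12 <- trajectory_config(traj, 12)
  for (nm in c("tonic_rate", "net_burst_rate", "participation_prob",
               "onset_jitter_sd", "spikes_per_burst_mean")) {
    expect_equal(c5[[nm]], traj$div5[[nm]])
    expect_equal(c12[[nm]], traj$div12[[nm]])
    expect_equal(trajectory_config(traj, 8.5)[[nm]],
                 (traj$div5[[nm]] + traj$div12[[nm]]) / 2)
  }
})

test_that("condition presets encode the documented perturbations", {
  expect_error(condition_preset("nope"), "unknown")
  ctrl <- condition_preset("control")
  expect_length(ctrl$multipliers, 0)
  expect_identical(unclass(condition_preset("ntc"))[c("multipliers", "overrides")],
                   unclass(ctrl)[c("multipliers", "overrides")])

  traj <- default_trajectory(layout = small_layout())
  # dctn5: burst-event rate pinned at 5.8/min with full participation from
  # DIV 7, untouched before onset
  d6 <- preset_config("dctn5_kd", traj, 6)
  d7 <- preset_config("dctn5_kd", traj, 7)
  expect_equal(d6$net_burst_rate, trajectory_config(traj, 6)$net_burst_rate)
  expect_equal(d6$participation_prob,
               trajectory_config(traj, 6)$participation_prob)
  expect_equal(d7$net_burst_rate, 5.8)
  expect_equal(d7$participation_prob, 1)
  # tnik: shorter, tighter bursts with reduced tonic firing from DIV 8
  t7 <- preset_config("tnik_kd", traj, 7)
  t9 <- preset_config("tnik_kd", traj, 9)
  base9 <- trajectory_config(traj, 9)
  expect_equal(t7$intra_burst_isi_mean,
               trajectory_config(traj, 7)$intra_burst_isi_mean)
  expect_lt(t9$intra_burst_isi_mean, base9$intra_burst_isi_mean)
  expect_lt(t9$tonic_rate, base9$tonic_rate)
  expect_lt(t9$onset_jitter_sd, base9$onset_jitter_sd)
  # dlg2: elevated bursting that recovers by DIV 12
  g8 <- preset_config("dlg2_kd", traj, 8)
  g12 <- preset_config("dlg2_kd", traj, 12)
  expect_gt(g8$net_burst_rate, trajectory_config(traj, 8)$net_burst_rate)
  expect_equal(g12$net_burst_rate, trajectory_config(traj, 12)$net_burst_rate)
  # disc1: longer bursts at DIV 12 only
  i11 <- preset_config("disc1_kd", traj, 11)
  i12 <- preset_config("disc1_kd", traj, 12)
  expect_equal(i11$spikes_per_burst_mean,
               trajectory_config(traj, 11)$spikes_per_burst_mean)
  expect_gt(i12$spikes_per_burst_mean,
            trajectory_config(traj, 12)$spikes_per_burst_mean)
})

test_that("simulate_experiment bookkeeping: one labelled recording per cell,
           reproducible under the master seed", {
  traj <- default_trajectory(layout = small_layout(), epoch_duration = 120)
  presets <- c(untransfected = "control", ntc = "ntc", kd = "dlg2_kd")
  recs <- simulate_experiment(presets, n_cultures = 2, divs = c(5, 12),
                              trajectory = traj, seed = 9)
  expect_length(recs, 12)
  man <- attr(recs, "manifest")
  expect_equal(nrow(man), 12)
  key <- paste(man$condition, man$culture_id, man$div)
  expect_false(anyDuplicated(key) > 0)
  expect_setequal(unique(man$condition), names(presets))
  # same master seed reproduces everything; cultures get distinct sub-seeds
  recs2 <- simulate_experiment(presets, n_cultures = 2, divs = c(5, 12),
                               trajectory = traj, seed = 9)
  expect_identical(lapply(recs, `[[`, "trains"),
                   lapply(recs2, `[[`, "trains"))
  expect_false(anyDuplicated(man$seed) > 0)
  # maturation built into the control trajectory: more spikes at DIV 12
  ctrl <- man$condition == "untransfected"
  n <- vapply(recs[ctrl], total_spikes, numeric(1))
  d <- man$div[ctrl]
  expect_gt(mean(n[d == 12]), mean(n[d == 5]))
})
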