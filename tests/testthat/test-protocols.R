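test_that("protocol validation enforces the estimator's breath budget", {
  expect_error(protocol_spec(c(0, 8, 0), breaths_per_level = 15), ">= 21")
  expect_error(protocol_spec(c(0, 8, 0), repetitions = 0), "repetitions")
  spec <- protocol_spec(c(0, 8.4, 0))
  expect_equal(spec$breaths_per_level, 25L)
})

test_that("capacity-limited steps are omitted exactly as at the bench", {
  cfg1 <- make_default_config(1, "normal")
  # single lung: the 0-12-0 procedure exceeds capacity and is omitted
  run <- run_protocol(cfg1, protocol_spec(c(0, 12.2, 0), repetitions = 1))
  expect_equal(run$omitted_levels, 12.2)
  # ... while 0-8-0 runs to completion
  run8 <- run_protocol(cfg1, protocol_spec(c(0, 8.4, 0), repetitions = 1))
  expect_equal(length(run8$omitted_levels), 0)
  expect_equal(run8$levels_run, c(0, 8.4, 0))

  # isolated single lung: 5-17-5 omitted, 5-13-5 runs
  iso <- isolated_lung_mode(cfg1)
  run17 <- run_protocol(iso, protocol_spec(c(5, 17, 5), repetitions = 1,
                                           isolated_lung = TRUE))
  expect_equal(run17$omitted_levels, 17)
  run13 <- run_protocol(iso, protocol_spec(c(5, 13, 5), repetitions = 1,
                                           isolated_lung = TRUE))
  expect_equal(length(run13$omitted_levels), 0)

  # two and three lungs accommodate every printed level
  for (n in 2:3) {
    cfg <- make_default_config(n, "stiff")
    run <- run_protocol(cfg, protocol_spec(c(0, 12.2, 0), repetitions = 1))
    expect_equal(length(run$omitted_levels), 0)
  }
})

test_that("transitions are annotated and a flat sequence has none", {
  cfg <- ref_config()
  run <- run_protocol(cfg, protocol_spec(c(0, 8.4, 0), repetitions = 1))
  ann <- run$reps[[1]]$annotations
  expect_equal(ann$breath, c(26, 51))
  expect_equal(ann$peep_new, c(8.4, 0))
  expect_equal(ann$sample, c(25, 50) * 400 + 1)

  flat <- run_protocol(cfg, protocol_spec(8.4, repetitions = 1))
  expect_equal(nrow(flat$reps[[1]]$annotations), 0)
})

test_that("isolated-lung mode removes the chest wall entirely", {
  iso <- isolated_lung_mode(ref_config())
  wf <- simulate_breaths(iso, rep(5, 10))
  expect_true(all(wf$ppl == 0))
  # airway pressure equals transpulmonary pressure; pause plateau = V/CL + PEEP
  br <- segment_breaths(wf)
  b <- utils::tail(br, 1)
  expect_equal(b$paw_ei, b$vlung_ei / 38, tolerance = 0.01)
  # equilibrium volume at PEEP 5 with two lungs: 5 x 38 = 190 ml
  expect_equal(equilibrium_solver(iso, 5)$lung_volume, 190)
})

test_that("isolated-lung P/V curve aligns with the full model's end-expiratory points", {
  # matched volume changes between the isolated lung (PEEP referenced to the
  # 5 cmH2O baseline) and the intact model (PEEP from ZEEP)
  cfg <- ref_config()
  iso <- isolated_lung_mode(cfg)
  run <- ref_step_run()
  br <- run$breaths
  dv_full <- mean(br$vlung_ee[46:50]) - mean(br$vlung_ee[21:25])
  dp_full <- mean(br$paw_ee[46:50]) - mean(br$paw_ee[21:25])
  # isolated-lung pressure at the same volume change above its baseline
  wf_iso <- simulate_breaths(iso, rep(c(5, 5 + 8.4), each = 21))
  bi <- segment_breaths(wf_iso)
  dv_iso <- mean(bi$vlung_ee[38:42]) - mean(bi$vlung_ee[17:21])
  p_iso_at_dv <- 8.4 * dv_full / dv_iso   # linear lung line through the points
  expect_lt(abs(p_iso_at_dv - dp_full), 0.5)
})

test_that("repetitions are bit-identical without noise and tight with it", {
  cfg <- ref_config()
  run <- run_protocol(cfg, protocol_spec(c(0, 8.4, 0), repetitions = 3))
  expect_identical(run$reps[[1]]$waveforms$flow, run$reps[[2]]$waveforms$flow)
  expect_identical(run$reps[[2]]$waveforms$paw, run$reps[[3]]$waveforms$paw)

  noisy <- run_protocol(cfg, protocol_spec(c(0, 8.4, 0), repetitions = 3,
                                           noise = noise_settings(seed = 5)))
  m <- measure_peep_steps(noisy)
  spread <- stats::aggregate(deelv ~ transition, data = m, FUN = stats::sd)
  expect_true(all(spread$deelv < 5))
})

test_that("preset configurations load and match the calibrated defaults", {
  arms <- arm_presets()
  expect_equal(nrow(arms), 6)
  cfg <- load_preset("2_lungs_normal")
  ref <- make_default_config(2, "normal")
  expect_equal(cfg$chest_wall$wall_compliance,
               ref$chest_wall$wall_compliance, tolerance = 1e-6)
  expect_equal(cfg$chest_wall$static_recoil_elastance,
               ref$chest_wall$static_recoil_elastance, tolerance = 1e-6)
  expect_error(load_preset("no_such_arm"), "unknown preset")
})
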