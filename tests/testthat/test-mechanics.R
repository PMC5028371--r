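test_that("tidal elastances follow their defining arithmetic", {
  # worked bench breath: dPAW 14.1, dPPL 5.3, VT 297 ml
  b <- list(paw_ee = 8.4, paw_ei = 22.5, ppl_ee = -5, ppl_ei = 0.3, vti = 297)
  te <- tidal_elastances(b)
  expect_equal(te$dptp, 8.8)
  expect_equal(te$el, 8.8 / 0.297, tolerance = 1e-9)
  expect_equal(te$etot, 14.1 / 0.297, tolerance = 1e-9)

  # partition identity to machine precision on simulated breaths
  br <- ref_step_run()$breaths
  for (i in seq(1, nrow(br), by = 7)) {
    te <- tidal_elastances(br[i, ])
    expect_equal(te$etot, te$ecw + te$el, tolerance = 1e-12)
  }
  # isolated lung: no pleural swing, EL = ETOT
  iso <- tidal_elastances(list(paw_ee = 5, paw_ei = 13, ppl_ee = 0,
                               ppl_ei = 0, vti = 300))
  expect_equal(iso$el, iso$etot)
  expect_error(tidal_elastances(list(vti = 0)), "elastance")
})

test_that("PEEP-step summaries obey their defining identities", {
  r <- peepstep_result(8.4, 281, 0)
  expect_equal(r$el_peepstep, 8.4 / 0.281, tolerance = 1e-9)
  expect_equal(r$dptp_ee, 8.4)

  # algebraic inverse: a step of dPEEP with dEELV = dPEEP/EL recovers EL
  for (el in c(15, 29.9, 52.6)) {
    r <- peepstep_result(4, 4 / el * 1000, 0)
    expect_equal(r$el_peepstep, el, tolerance = 1e-9)
  }
  expect_error(peepstep_result(8, 0, 0), "division")
})

test_that("the esophageal-free driving pressure matches the pleural route", {
  expect_equal(ptp_from_peepstep(8.4, 281, 297), 8.4 / 281 * 297)
  expect_equal(driving_ptp_via_peepstep(14.1, 0, 297), 14.1)

  # on simulation: dPAW - ECW*VT vs the directly measured dPAW - dPPL
  br <- ref_step_run()$breaths
  b <- br[25, ]
  te <- tidal_elastances(b)
  est <- driving_ptp_via_peepstep(te$dpaw, te$ecw, te$vt)
  expect_lt(abs(est - te$dptp), 0.3)
  # the PEEP-step route overestimates the tidal transpulmonary pressure by
  # exactly the (small) end-expiratory chest-wall term, ECW_EE x VT
  dpeep <- mean(br$paw_ee[46:50]) - mean(br$paw_ee[21:25])
  deelv <- mean(br$vlung_ee[46:50]) - mean(br$vlung_ee[21:25])
  dppl_ee <- mean(br$ppl_ee[46:50]) - mean(br$ppl_ee[21:25])
  est2 <- ptp_from_peepstep(dpeep, deelv, te$vt)
  ecw_ee <- peepstep_result(dpeep, deelv, dppl_ee)$ecw_ee
  expect_equal(est2 - te$dptp, ecw_ee * te$vt / 1000, tolerance = 0.05)
  expect_lt(abs(est2 - te$dptp), 0.5)
})

test_that("end-expiratory P/V points recover the static elastance line", {
  cfg <- ref_config()
  wf <- cached("staircase_run",
               simulate_breaths(cfg, rep(c(0, 4, 8, 12), each = 25)))
  pv <- pv_points(wf)
  e_static <- 1000 / 38 + 1000 * effective_static_elastance(cfg)
  expect_lt(abs(pv$slope - e_static) / e_static, 0.05)

  # end-inspiratory airway points sit right of the lung line by ~ dPPL
  fit <- pv$fit_points
  lung_line_p <- pv$intercept + pv$slope / 1000 * fit$vol_ei
  br <- segment_breaths(wf)
  dppl <- mean(br$ppl_ei[96:100] - br$ppl_ee[96:100])
  shift <- mean(fit$paw_ei - lung_line_p)
  expect_equal(shift, dppl, tolerance = 0.15 * dppl)

  expect_error(pv_points(cached("zeep_run",
    simulate_breaths(ref_config(), rep(0, 15)))), "fit error")
})

test_that("isolated-lung airway and transpulmonary points coincide", {
  iso <- isolated_lung_mode(ref_config())
  wf <- simulate_breaths(iso, rep(c(5, 9), each = 21))
  pv <- pv_points(wf)
  expect_equal(pv$points$paw_ee, pv$points$ptp_ee)
  expect_equal(pv$points$paw_ei, pv$points$ptp_ei)
})

test_that("the volume-change regression matches its brute-force oracle", {
  # perfect pairs: slope 1, r2 1
  d <- data.frame(deelv = c(100, 200, 300, 450),
                  dpeep = c(4, 8, 12, 18), el_tidal = 40)
  d$deelv <- d$dpeep / d$el_tidal * 1000
  reg <- eelv_regression(d)
  expect_equal(reg$slope, 1, tolerance = 1e-12)
  expect_equal(reg$r2, 1, tolerance = 1e-12)

  # brute-force grid minimisation of the zero-intercept SSE
  study <- ref_study()
  reg <- eelv_regression(study)
  x <- study$deelv; y <- study$dpeep / study$el_tidal * 1000
  grid <- seq(0.8, 1.3, by = 1e-5)
  sse <- vapply(grid, function(b) sum((y - b * x)^2), 0)
  expect_lt(abs(reg$slope - grid[which.min(sse)]), 1e-4)

  expect_error(eelv_regression(data.frame(deelv = c(0, 0, 0), dpeep = 1,
                                          el_tidal = 30)), "degenerate")
  expect_error(eelv_regression(d[1:2, ]), "3")
})

test_that("tidal and end-expiratory chest-wall elastance are different entities", {
  study <- ref_study()
  expect_true(all(study$ecw_tidal > 16 & study$ecw_tidal < 26))
  expect_true(all(abs(study$ecw_ee) < 2.5))
  # lung elastance agrees between the PEEP-step and tidal routes
  expect_true(all(abs(study$el_peepstep - study$el_tidal) /
                    study$el_tidal < 0.1))
})
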