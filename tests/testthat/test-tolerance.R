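test_that("drought ratios follow their definitions", {
  expect_equal(dti(50, 100), 50)
  expect_equal(dti(37, 37), 100)
  expect_gt(dti(108, 100), 100) # stress exceeding control is legitimate
  expect_error(dti(50, 0), "positive")

  expect_equal(residual_level(0.4, 0.8), 50)
  expect_equal(residual_level(0.61, 0.61), 100)
  expect_equal(residual_level(0.72, 0.703), 100 * 0.72 / 0.703)
  expect_error(residual_level(0.4, 0), "positive")

  expect_equal(soil_rwc(10, 2), 80)
  expect_error(soil_rwc(2, 10))
})

test_that("plate set-point schedule steps from 25 to 55 with a final hold", {
  pr <- heat_ramp_protocol()
  expect_equal(pr$duration, 2400)
  expect_equal(plate_setpoint(c(0, 299, 300, 899, 1500, 1799, 1800, 2400), pr),
               c(25, 25, 30, 35, 50, 50, 55, 55))
  expect_error(heat_ramp_protocol(step_temp = 0))
})

test_that("heat tolerance finds the decline temperature after the transient rise", {
  pr <- heat_ramp_protocol()
  times <- seq(60, 2400, by = 60)
  setp <- plate_setpoint(times, pr)
  # rises 10% above baseline from 30 degC on, crosses below during the
  # 50 degC step, halves by the end
  phi <- rep(0.4, length(times))
  phi[setp >= 30] <- 0.44
  phi[setp >= 50] <- 0.39
  phi[setp >= 55] <- 0.2
  res <- heat_tolerance(tibble::tibble(sample_id = "a", time_s = times,
                                       phi_psii = phi), pr)
  expect_equal(res$baseline, 0.4)
  expect_equal(res$t_dec, 50)
  expect_false(res$t_dec_censored)
  expect_equal(res$phi_psii_resid, 50)

  # monotone-increasing trace: t_dec censored at the end temperature
  phi_up <- seq(0.3, 0.6, length.out = length(times))
  expect_warning(
    res_up <- heat_tolerance(tibble::tibble(sample_id = "b", time_s = times,
                                            phi_psii = phi_up), pr),
    "censored"
  )
  expect_true(res_up$t_dec_censored)
  expect_equal(res_up$t_dec, 55)
  expect_gt(res_up$phi_psii_resid, 100)

  # a trace that only declines (never exceeds baseline) uses the first
  # crossing directly
  phi_down <- rep(0.4, length(times))
  phi_down[setp >= 35] <- 0.3
  res_down <- heat_tolerance(tibble::tibble(sample_id = "c", time_s = times,
                                            phi_psii = phi_down), pr)
  expect_equal(res_down$t_dec, 35)

  expect_error(
    heat_tolerance(tibble::tibble(sample_id = "d", time_s = times[1:10],
                                  phi_psii = phi[1:10]), pr),
    "shorter than"
  )
  expect_error(heat_tolerance(tibble::tibble(sample_id = "e",
                                             time_s = times,
                                             phi_psii = phi), pr,
                              baseline_window = 1000),
               "initial step")
})

test_that("lowering the thermal midpoint lowers the decline temperature", {
  tmids <- c(40, 45, 50, 53)
  tdecs <- vapply(tmids, function(tm) {
    specphen:::heat_truth(tm)$t_dec_true
  }, numeric(1))
  expect_true(all(diff(tdecs) >= 0))
  expect_lt(tdecs[1], tdecs[4])
})

test_that("extracted heat statistics match generator truth at zero noise", {
  p <- generate_panel(panel_config(noise_scale = 0, n_heat = 1),
                      seed = 77, what = "heat")
  res <- heat_tolerance(p$heat)
  res$cultivar <- sub("_heat1$", "", res$sample_id)
  cmp <- dplyr::left_join(res, p$heat_params, by = "cultivar")
  expect_equal(cmp$t_dec, cmp$t_dec_true)
  expect_lt(max(abs(cmp$phi_psii_resid / cmp$phi_psii_resid_true - 1)), 0.02)
})
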