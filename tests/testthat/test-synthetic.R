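test_that("identical config and seed give identical panels", {
  a <- generate_panel(panel_config(), seed = 14)
  b <- generate_panel(panel_config(), seed = 14)
  expect_identical(a$truth, b$truth)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$induction, b$induction)
  expect_identical(a$heat, b$heat)
  expect_identical(a$drought, b$drought)
  c <- generate_panel(panel_config(), seed = 15)
  expect_false(identical(a$truth, c$truth))
})

test_that("degenerate latents give perfectly coupled panels", {
  p <- generate_panel(panel_config(noise_scale = 0, rho_vigor_heat = -1),
                      seed = 42, what = c("heat", "drought"))
  tr <- p$truth
  # heat tolerance is an exact decreasing function of vigor: the continuous
  # thermal midpoint correlates -1 with dry weight, and the quantized
  # decline temperature is monotone non-increasing in it
  expect_equal(cor(tr$tmid, tr$dw), -1, tolerance = 1e-9)
  ord <- order(tr$dw)
  expect_true(all(diff(tr$t_dec_true[ord]) <= 0))
  expect_lt(cor(tr$t_dec_true, tr$dw), -0.8)
})

test_that("config validation rejects impossible settings", {
  expect_error(panel_config(rho_vigor_heat = 1.2), "\\[-1, 1\\]")
  expect_error(panel_config(drought_coupling = -2), "\\[-1, 1\\]")
  expect_error(panel_config(noise_scale = -1), "non-negative")
  expect_error(panel_config(noise = list(bogus = 1)), "Unknown noise")
  expect_error(generate_panel(list()), "panel_config")
})

test_that("generated PAM traces satisfy the fluorescence invariants", {
  p <- generate_panel(panel_config(), seed = 6, what = "induction")
  tr <- p$induction
  expect_true(all(tr$fm > tr$f0))
  expect_true(all(tr$f0 > 0))
  expect_true(all(tr$fm_prime >= tr$f))
  expect_true(all(tr$f > 0))
  ph <- phi_psii(tr$f, tr$fm_prime)
  expect_true(all(ph >= 0 & ph <= 1))
  expect_true(all(npq(tr$fm, tr$fm_prime) >= 0))

  h <- generate_panel(panel_config(), seed = 6, what = "heat")$heat
  expect_true(all(h$phi_psii >= 0 & h$phi_psii <= 1))
})

test_that("default panels couple fluorescence and tolerance to biomass with the right signs", {
  res <- vapply(1:10, function(s) {
    p <- generate_panel(panel_config(), seed = 100 + s,
                        what = c("induction", "heat", "drought"))
    tt <- p$trait_table
    c(cor(tt$phi_psii_ef_mean, tt$dw_control_mean),
      cor(tt$t_half_phi_mean, tt$dw_control_mean),
      cor(tt$t_dec_true_mean, tt$dw_control_mean))
  }, numeric(3))
  expect_gt(mean(res[1, ]), 0.5)   # quantum yield rises with biomass
  expect_lt(mean(res[2, ]), -0.4)  # slower induction in low-vigor plants
  expect_lt(mean(res[3, ]), -0.4)  # heat tolerance opposes biomass
})

test_that("bundled trait tables carry the printed cultivar means", {
  t1 <- load_fixture("chlf_control")
  expect_equal(nrow(t1), 11)
  expect_equal(t1$npq_max[t1$cultivar == "C1"], 1.727)
  expect_equal(t1$t_half_phi[t1$cultivar == "C10"], 104.9)

  t2 <- load_fixture("drought_residuals")
  expect_equal(t2$residual_dw[t2$cultivar == "C4"], 107.9)
  expect_equal(t2$residual_dw_sem[t2$cultivar == "C4"], 6.3)

  t4 <- load_fixture("heat_tolerance")
  expect_equal(t4$t_dec[t4$cultivar == "C9"], 55.0)
  expect_equal(t4$t_dec_sem[t4$cultivar == "C9"], 0.0)

  # aliases resolve to the same tables
  expect_identical(load_fixture("table1"), t1)
  expect_identical(load_fixture("table2"), t2)
  expect_identical(load_fixture("table4"), t4)
  expect_error(load_fixture("table9"), "Unknown fixture")
})
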