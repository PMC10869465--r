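test_that("PAM equations follow their definitions and reject bad yields", {
  expect_equal(phi_psii(f = 4, fm_prime = 4), 0)
  expect_equal(phi_psii(f = 0, fm_prime = 4), 1)
  expect_equal(phi_psii(f = 1, fm_prime = 4), 0.75)
  expect_error(phi_psii(1, 0), "positive")
  expect_error(phi_psii(5, 4), "exceed")

  expect_equal(npq(fm = 2, fm_prime = 2), 0)
  expect_equal(npq(fm = 3, fm_prime = 2), 0.5)
  expect_equal(npq(fm = 2, fm_prime = 1), 1)
  expect_error(npq(2, 0), "positive")

  expect_equal(fv_fm(f0 = 0.2 * 5, fm = 5), 0.8)
  expect_equal(fv_fm(f0 = 1, fm = 5), 0.8)
  expect_lt(fv_fm(f0 = 5 - 1e-9, fm = 5), 1e-8)
  expect_error(fv_fm(0, 5))
  expect_error(fv_fm(5, 5))
})

test_that("feature extraction recovers a closed-form saturating rise", {
  # long trace so the curve is fully saturated inside the steady window
  times <- seq(30, 3000, by = 30)
  phi <- 0.6 * (1 - 2^(-times / 150))
  npq_t <- 0.8 * (1 - exp(-times / 60))
  f <- chlf_features(make_trace(times, phi, npq_t))
  expect_equal(f$phi_psii_ef, 0.6, tolerance = 1e-4)
  expect_lt(abs(f$t_half_phi - 150), 1)
  expect_equal(f$fv_fm, 0.81)
  expect_equal(f$npq_s, 0.8, tolerance = 1e-4)
})

test_that("feature extraction finds the NPQ transient peak and steady level", {
  times <- seq(3, 900, by = 3) # cadence fine enough to hit t = 219 exactly
  phi <- 0.46 * (1 - 2^(-times / 180))
  npq_t <- specphen:::npq_curve(times, npq_max = 1.7, t_peak = 219,
                                npq_s = 0.76)
  f <- chlf_features(make_trace(times, phi, npq_t))
  expect_equal(f$npq_max, 1.7, tolerance = 0.01)
  expect_equal(f$t_npq_max, 219, tolerance = 3)
  expect_equal(f$npq_s, 0.76, tolerance = 0.02)
})

test_that("degenerate traces and malformed input are handled", {
  times <- seq(30, 600, by = 30)
  const <- rep(0.5, length(times))
  f <- chlf_features(make_trace(times, const, rep(0.3, length(times))))
  expect_equal(f$phi_psii_ef, 0.5)
  expect_equal(f$t_half_phi, 30) # already above half at the first pulse

  npq_flat <- rep(0.2, length(times))
  tr <- make_trace(times, const, npq_flat)
  expect_error(chlf_features(tibble::tibble(
    sample_id = "x", time_s = c(30, 30, 60), f = 1, fm_prime = 2,
    f0 = 0.5, fm = 4
  )), "strictly increasing")
  expect_error(chlf_features(tr[, -3]), "missing column")
  expect_error(chlf_features(tr, steady_window = 400),
               "twice the steady-state window")
})

test_that("half-rise time grows monotonically with the configured tau", {
  times <- seq(30, 2400, by = 30)
  taus <- c(80, 120, 160, 220, 300)
  t_halves <- vapply(taus, function(tau) {
    phi <- 0.55 * (1 - 2^(-times / tau))
    chlf_features(make_trace(times, phi, rep(0.4, length(times))))$t_half_phi
  }, numeric(1))
  expect_true(all(diff(t_halves) > 0))
})

test_that("extraction recovers generator ground truth at zero noise", {
  # 110 random parameter draws via 10 noise-free panels of 11 cultivars
  errs <- purrr::map_dfr(1:10, function(s) {
    p <- generate_panel(panel_config(noise_scale = 0, n_plants = 1),
                        seed = 1000 + s, what = "induction")
    f <- chlf_features(p$induction)
    f$cultivar <- sub("_plant1$", "", f$sample_id)
    truth <- dplyr::select(p$truth, "cultivar", dplyr::ends_with("_true"))
    dplyr::left_join(f, truth, by = "cultivar")
  })
  expect_gte(nrow(errs), 100)
  expect_false(anyNA(errs$phi_psii_ef_true))
  expect_lt(max(abs(errs$phi_psii_ef / errs$phi_psii_ef_true - 1)), 0.02)
  expect_lt(max(abs(errs$npq_max / errs$npq_max_true - 1)), 0.02)
  expect_lt(max(abs(errs$npq_s / errs$npq_s_true - 1)), 0.02)
  expect_lte(max(abs(errs$t_half_phi - errs$t_half_phi_true)), 15.5)
  expect_lte(max(abs(errs$t_npq_max - errs$t_npq_max_true)), 15.5)
  expect_lt(max(abs(errs$fv_fm - errs$fv_fm_true)), 1e-12)
})
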