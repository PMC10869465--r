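test_that("pearson_cor matches covariance and incomplete-beta oracles", {
  res <- pearson_cor(1:10, 2 * (1:10) + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  set.seed(21)
  for (k in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- pearson_cor(x, y)
    expect_lt(abs(got$r - pearson_oracle_r(x, y)), 1e-12)
    expect_lt(abs(got$p - pearson_oracle_p(got$r, n)), 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y))
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }

  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "variance")
})

test_that("correlation spectrum flags a trait planted at one band", {
  p <- generate_panel(panel_config(noise_scale = 0.2), seed = 5,
                      what = "spectra")
  sp <- mean_spectra(p$spectra)
  band <- 550
  trait <- sp[sp$wavelength_nm == band, c("sample_id", "reflectance")]
  cs <- correlation_spectrum(sp, trait, min_run = 1L)
  row <- cs[cs$wavelength_nm == band, ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  runs <- attr(cs, "runs")
  expect_true(any(runs$lambda_start <= band & runs$lambda_end >= band))
})

test_that("correlation spectrum links red-band contrast traits to the red band", {
  p <- generate_panel(panel_config(noise_scale = 0.2), seed = 8,
                      what = "spectra")
  sp <- mean_spectra(p$spectra)
  # trait built from red-band absorption contrast (vigor latent)
  trait <- setNames(p$truth$vigor, p$truth$cultivar)
  cs <- correlation_spectrum(sp, trait)
  runs <- attr(cs, "runs")
  expect_gt(nrow(runs), 0)
  expect_true(any(runs$lambda_start <= 670 & runs$lambda_end >= 650))
  # vigor deepens the absorption well: negative correlation in the red band
  expect_lt(cs$r[cs$wavelength_nm == 670], 0)
  expect_error(correlation_spectrum(sp[sp$sample_id %in% c("C1", "C2"), ],
                                    trait[1:2]), "at least 3")
})

test_that("NDI heatmap is exact for a trait equal to one NDI pair", {
  p <- generate_panel(panel_config(noise_scale = 0.3), seed = 9,
                      what = "spectra")
  sp <- mean_spectra(p$spectra) # restricted to 4 bands for speed
  sp_small <- sp[sp$wavelength_nm %in% as.numeric(default_grid())[c(1, 21, 41, 61)], ]
  # rebuild on an explicit small grid
  ndis <- lapply(split(sp_small, sp_small$sample_id), function(df) {
    ndi_matrix(df[, c("wavelength_nm", "reflectance")])
  })
  g <- attr(ndis[[1]], "grid")
  trait <- vapply(ndis, function(m) m[2, 4], numeric(1))
  hm <- ndi_correlation_heatmap(ndis, trait, min_area = 1)
  expect_equal(hm$r[2, 4], 1, tolerance = 1e-9)
  expect_equal(hm$r[4, 2], -1, tolerance = 1e-9)
  expect_equal(hm$p[2, 4], hm$p[4, 2])
  expect_true(all(is.na(diag(hm$r))))
  # antisymmetry of r, symmetry of p
  off <- !is.na(hm$r)
  expect_equal(hm$r[off], -t(hm$r)[off])
  expect_equal(hm$p[off], t(hm$p)[off])
  expect_error(ndi_correlation_heatmap(ndis, rep(1, length(ndis))),
               "zero variance")
})

test_that("vigor-linked panels give a positive FR-NIR vs visible NDI region", {
  p <- generate_panel(panel_config(), seed = 3, what = c("spectra", "drought"))
  ndis <- lapply(split(p$spectra, p$spectra$cultivar), function(df) {
    mean_ndi_matrix(ndi_matrices(df))
  })
  y <- setNames(p$truth$dw, p$truth$cultivar)
  hm <- ndi_correlation_heatmap(ndis[names(y)], y)
  g <- hm$grid
  frnir <- g >= 710 & g <= 800
  vis <- g >= 450 & g <= 650
  block_r <- hm$r[frnir, vis]
  block_p <- hm$p[frnir, vis]
  expect_gt(mean(block_r), 0.3)
  expect_gt(mean(block_p < hm$alpha), 0.5)
  # and a significant region overlapping that block exists
  reg <- hm$regions
  expect_true(any(reg$peak_r > 0 & reg$lambda1_max >= 710 &
                    reg$lambda2_min <= 650))
})

test_that("extract_regions labels 4-connected components with correct bounds", {
  g <- seq(400, 427, by = 3) # 10 bands
  p_mat <- matrix(1, 10, 10)
  expect_equal(nrow(extract_regions(p_mat, grid = g)), 0)

  p1 <- p_mat
  p1[3, 4] <- 0.01
  r1 <- extract_regions(p1, min_area = 1, grid = g)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_cells, 1L)
  expect_equal(c(r1$lambda1_min, r1$lambda2_min), c(g[3], g[4]))

  # two disjoint blocks: a 2x2 and an L-shaped 3-cell component
  p2 <- p_mat
  p2[1:2, 1:2] <- 0.01
  p2[8, 9] <- p2[9, 9] <- p2[9, 10] <- 0.01
  r2 <- extract_regions(p2, min_area = 1, grid = g)
  expect_equal(nrow(r2), 2)
  big <- r2[r2$n_cells == 4, ]
  expect_equal(c(big$lambda1_min, big$lambda1_max, big$lambda2_min,
                 big$lambda2_max), c(g[1], g[2], g[1], g[2]))
  ell <- r2[r2$n_cells == 3, ]
  expect_equal(c(ell$lambda1_min, ell$lambda1_max, ell$lambda2_min,
                 ell$lambda2_max), c(g[8], g[9], g[9], g[10]))
  # diagonal-only adjacency does not merge components
  p3 <- p_mat
  p3[1, 1] <- p3[2, 2] <- 0.01
  expect_equal(nrow(extract_regions(p3, min_area = 1, grid = g)), 2)
  expect_error(extract_regions(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("null panels keep the per-band false-positive rate near alpha", {
  fp <- vapply(1:40, function(s) {
    p <- generate_panel(panel_config(), seed = 3000 + s,
                        what = c("spectra", "drought"))
    sp <- mean_spectra(p$spectra)
    y <- setNames(p$trait_table$dti_mean, p$trait_table$cultivar)
    cs <- correlation_spectrum(sp, y)
    mean(cs$p < 0.05)
  }, numeric(1))
  # drought tolerance is decoupled from spectra: only chance-level hits
  expect_lt(mean(fp), 0.05 + 2.5 * sd(fp) / sqrt(length(fp)) + 0.02)
})
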