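#' Configuration for the synthetic cultivar-panel generator
#'
#' The generator emulates a laboratory screening of a small wheat cultivar
#' panel in which three latent factors drive the observables:
#' \describe{
#'   \item{vigor `V`}{Chlorophyll content / photosynthetic activity /
#'     biomass accumulation. Deepens the blue (450 nm) and red (670 nm)
#'     absorption wells and raises the NIR plateau of the reflectance
#'     spectrum; raises \eqn{\Phi_{PSIIef}} and dry weight; shortens the
#'     induction transients and lowers NPQ.}
#'   \item{heat tolerance `H`}{Shifts the thermal midpoint of the
#'     quantum-yield decline upward, raising `t_dec` and the residual
#'     quantum yield. Correlated with `V` at `rho_vigor_heat` (negative by
#'     default: vigorous cultivars are the heat-sensitive ones).}
#'   \item{drought tolerance `D`}{Drives the drought tolerance index and the
#'     residual fluorescence parameters. Independent of `V` and `H` unless
#'     `drought_coupling` is non-zero, so drought tolerance is by default
#'     not predictable from spectra or fluorescence — the null structure the
#'     correlation-mapping machinery must not turn into false positives.}
#' }
#'
#' @param n_cultivars Number of cultivars in the panel.
#' @param n_pots Pot replicates per cultivar (spectra, dry weights).
#' @param n_plants Plant replicates per cultivar (induction traces).
#' @param n_heat Plant replicates per cultivar (heat-ramp traces).
#' @param rho_vigor_heat Latent correlation between vigor and heat
#'   tolerance, in `[-1, 1]`.
#' @param drought_coupling Latent correlation between vigor and drought
#'   tolerance, in `[-1, 1]`; 0 makes drought tolerance unpredictable.
#' @param noise_scale Multiplier applied to every noise SD; 0 gives
#'   noise-free output.
#' @param grid Wavelength grid for spectra.
#' @param induction_times Pulse times (s) of the induction protocol.
#' @param heat_times Sample times (s) of the heat-ramp recording.
#' @param protocol [heat_ramp_protocol()] of the ramp.
#' @param noise Named list of noise SDs; any subset may be overridden.
#'   Replicate-level SDs of the fluorescence features default to printed
#'   SEM-times-sqrt(n) magnitudes for this kind of panel.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_cultivars = 11, n_pots = 4, n_plants = 20,
                         n_heat = 10, rho_vigor_heat = -0.7,
                         drought_coupling = 0, noise_scale = 1,
                         grid = default_grid(),
                         induction_times = seq(30, 900, by = 30),
                         heat_times = seq(60, 2400, by = 60),
                         protocol = heat_ramp_protocol(),
                         noise = list()) {
  if (abs(rho_vigor_heat) > 1 || abs(drought_coupling) > 1) {
    abort("Latent correlations must lie in [-1, 1].")
  }
  if (noise_scale < 0) abort("`noise_scale` must be non-negative.")
  if (n_cultivars < 2) abort("Need at least 2 cultivars.")
  noise_defaults <- list(
    spectrum = 0.008, pot_vigor = 0.25,
    curve_phi = 0.01, curve_npq = 0.02,
    phi_ef = 0.04, t_half = 40, npq_max = 0.16, t_npq_max = 33,
    npq_s = 0.12, fv_fm = 0.004,
    tmid = 2.5, heat_baseline = 0.02,
    dw_cv = 0.12, dti = 10, resid_phi = 18, resid_fv_fm = 5
  )
  unknown <- setdiff(names(noise), names(noise_defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown noise component(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  noise_defaults[names(noise)] <- noise
  structure(
    list(
      n_cultivars = n_cultivars, n_pots = n_pots, n_plants = n_plants,
      n_heat = n_heat, rho_vigor_heat = rho_vigor_heat,
      drought_coupling = drought_coupling, noise_scale = noise_scale,
      grid = grid, induction_times = induction_times,
      heat_times = heat_times, protocol = protocol,
      noise = noise_defaults
    ),
    class = "panel_config"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Cultivar-level parameter maps from the latents (centres and slopes chosen
# to span the magnitudes typical of juvenile wheat panels).
latent_to_params <- function(V, H, D) {
  tibble(
    vigor = V, heat = H, drought = D,
    fv_fm = clamp(0.810 + 0.003 * V, 0.78, 0.84),
    phi_psii_ef = clamp(0.53 + 0.045 * V, 0.40, 0.68),
    t_half_phi = clamp(170 - 38 * V, 60, 290),
    npq_max = clamp(1.55 - 0.17 * V, 0.9, 2.2),
    t_npq_max = clamp(185 - 28 * V, 90, 290),
    npq_s = clamp(0.62 - 0.10 * V, 0.15, 1.1),
    dw = clamp(53 + 16 * V, 15, 100),
    tmid = clamp(50 + 2.5 * H, 40, 58),
    dti = clamp(82 + 12 * D, 40, 130),
    resid_phi_psii_ef = clamp(51 + 15 * D, 5, 110),
    resid_fv_fm = clamp(96 + 4.5 * D, 75, 110)
  )
}

# Leaf reflectance model: visible background plus a logistic red edge onto
# the NIR plateau, minus Gaussian chlorophyll/carotenoid absorption wells at
# 450 and 670 nm whose depth grows with vigor.
leaf_spectrum <- function(grid, V) {
  lam <- as.numeric(grid)
  base <- 0.15
  nir <- 0.35 + 0.04 * V
  d450 <- 0.09 + 0.02 * V
  d670 <- 0.08 + 0.02 * V
  r <- base + nir / (1 + exp(-(lam - 705) / 16)) -
    d450 * exp(-(lam - 450)^2 / (2 * 25^2)) -
    d670 * exp(-(lam - 670)^2 / (2 * 18^2))
  pmax(r, 0.005)
}

# Quantum-yield induction curve: saturating rise with half-time tau.
phi_curve <- function(t, A, tau) A * (1 - 2^(-t / tau))

# NPQ induction curve: fast saturating baseline to the steady level plus a
# symmetric Gaussian transient bump peaking at t_peak, gated by the same
# fast onset ramp so NPQ(0) = 0. The width floor keeps the peak broad
# enough to be resolvable at typical 30 s pulse cadences.
npq_curve <- function(t, npq_max, t_peak, npq_s,
                      width = max(0.45 * t_peak, 80)) {
  tau_s <- t_peak / 8
  ramp <- 1 - exp(-t / tau_s)
  s <- npq_s * ramp
  bump_amp <- npq_max - npq_s * (1 - exp(-8))
  bump <- bump_amp * exp(-(t - t_peak)^2 / (2 * width^2)) * ramp
  pmax(s + bump, 0)
}

# Heat-ramp response in the temperature domain, relative to the level at the
# start temperature: a mild linear stimulation times a logistic shutdown
# centred at tmid.
heat_response <- function(temp, tmid, start_temp = 25, span = 30,
                          rise = 0.35, width = 3.5) {
  sigm <- function(x) 1 / (1 + exp((x - tmid) / width))
  (1 + rise * (temp - start_temp) / span) * sigm(temp) / sigm(start_temp)
}

# Plate temperature smoothed by first-order thermal lag (time constant s).
smoothed_plate_temp <- function(times, protocol, tau = 40) {
  dt <- 1
  tt <- seq(0, max(times), by = dt)
  setp <- plate_setpoint(tt, protocol)
  temp <- numeric(length(tt))
  temp[1L] <- setp[1L]
  k <- dt / tau
  for (i in seq_along(tt)[-1L]) {
    temp[i] <- temp[i - 1L] + k * (setp[i] - temp[i - 1L])
  }
  approx(tt, temp, xout = times, rule = 2)$y
}

# Ground-truth induction features of the continuous curves, via dense
# evaluation with the reference definitions (final-window means, earliest
# interpolated half-crossing, earliest maximum).
dense_induction_truth <- function(A, tau, npq_max, t_peak, npq_s, fv,
                                  t_end = 900, steady_window = 120) {
  t <- seq(0.5, t_end, by = 0.5)
  phi <- phi_curve(t, A, tau)
  nq <- npq_curve(t, npq_max, t_peak, npq_s)
  f <- features_from_curves(t, phi, nq, fv, steady_window = steady_window)
  names(f) <- paste0(names(f), "_true")
  f
}

# Ground-truth t_dec / residual for the heat model: the plate level whose
# step first carries a sample past the temperature where the response drops
# below 1. `cadence` is the recording interval; the margin accounts for the
# thermal lag never quite reaching the set-point between samples.
heat_truth <- function(tmid, protocol = heat_ramp_protocol(), tau = 40,
                       cadence = 60) {
  g <- function(temp) heat_response(temp, tmid, protocol$start_temp)
  # downward crossing of 1 beyond the transient peak
  peak <- stats::optimize(g, c(protocol$start_temp, protocol$end_temp + 5),
                          maximum = TRUE)$maximum
  upper <- protocol$end_temp + 5
  tc <- if (g(upper) >= 1) Inf else
    stats::uniroot(function(x) g(x) - 1, c(peak, upper), tol = 1e-10)$root
  margin <- protocol$step_temp *
    exp(-(protocol$step_duration - cadence) / tau)
  levels <- seq(protocol$start_temp + protocol$step_temp, protocol$end_temp,
                by = protocol$step_temp)
  reachable <- levels[levels - margin > tc]
  tibble(
    tc = tc,
    t_dec_true = if (length(reachable) > 0L) reachable[1L] else protocol$end_temp,
    t_dec_censored_true = length(reachable) == 0L,
    phi_psii_resid_true = 100 * g(protocol$end_temp)
  )
}

#' Generate a synthetic cultivar panel
#'
#' Draws latent vigor, heat-tolerance and drought-tolerance factors per
#' cultivar (see [panel_config()]), maps them to reflectance spectra, PAM
#' induction traces, heat-ramp quantum-yield traces and drought outcomes,
#' and adds replicate and measurement noise. Dark yields `f0`/`fm` are
#' back-computed so that the PAM equations recover the generated
#' \eqn{\Phi_{PSII}(t)} and \eqn{NPQ(t)} curves exactly.
#'
#' @param config A [panel_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   panels. `NULL` uses the current RNG state.
#' @param what Which data blocks to generate (subset of `"spectra"`,
#'   `"induction"`, `"heat"`, `"drought"`); the truth tables are always
#'   produced.
#' @return A `panel` list: `truth` (cultivar-level latents, configured
#'   parameters and dense-curve ground-truth features), `spectra`,
#'   `induction`, `heat`, `drought` tibbles, replicate-level parameter
#'   tables (`induction_params`, `heat_params`), a cultivar `trait_table`
#'   (means and SEMs over replicates), and the `config`.
#' @examples
#' p <- generate_panel(panel_config(), seed = 1)
#' p$trait_table
#' @export
generate_panel <- function(config = panel_config(), seed = NULL,
                           what = c("spectra", "induction", "heat", "drought")) {
  stopifnot(inherits(config, "panel_config"))
  what <- match.arg(what, several.ok = TRUE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  nc <- config$n_cultivars
  ns <- config$noise_scale
  nz <- lapply(config$noise, function(x) x * ns)
  cultivars <- sprintf("C%d", seq_len(nc))

  z1 <- rnorm(nc)
  z2 <- rnorm(nc)
  z3 <- rnorm(nc)
  rho <- config$rho_vigor_heat
  dc <- config$drought_coupling
  V <- z1
  H <- rho * z1 + sqrt(1 - rho^2) * z2
  D <- dc * z1 + sqrt(1 - dc^2) * z3

  truth <- dplyr::bind_cols(tibble(cultivar = cultivars),
                            latent_to_params(V, H, D))
  truth <- dplyr::bind_cols(
    truth,
    purrr::pmap_dfr(
      truth[, c("phi_psii_ef", "t_half_phi", "npq_max", "t_npq_max",
                "npq_s", "fv_fm")],
      function(phi_psii_ef, t_half_phi, npq_max, t_npq_max, npq_s, fv_fm) {
        dense_induction_truth(phi_psii_ef, t_half_phi, npq_max, t_npq_max,
                              npq_s, fv_fm,
                              t_end = max(config$induction_times))
      }
    ),
    purrr::map_dfr(truth$tmid, heat_truth, protocol = config$protocol,
                   cadence = stats::median(diff(config$heat_times)))
  )

  out <- list(truth = truth, config = config)

  if ("spectra" %in% what) {
    out$spectra <- purrr::map_dfr(seq_len(nc), function(i) {
      purrr::map_dfr(seq_len(config$n_pots), function(p) {
        v_pot <- V[i] + rnorm(1, sd = nz$pot_vigor)
        refl <- leaf_spectrum(config$grid, v_pot) +
          rnorm(length(config$grid), sd = nz$spectrum)
        tibble(
          cultivar = cultivars[i], pot = p,
          sample_id = sprintf("%s_pot%d", cultivars[i], p),
          wavelength_nm = as.numeric(config$grid),
          reflectance = pmax(refl, 0)
        )
      })
    })
  }

  if ("induction" %in% what) {
    tt <- config$induction_times
    params <- purrr::map_dfr(seq_len(nc), function(i) {
      tibble(
        cultivar = cultivars[i], plant = seq_len(config$n_plants),
        fv_fm = clamp(truth$fv_fm[i] + rnorm(config$n_plants, sd = nz$fv_fm), 0.5, 0.95),
        phi_psii_ef = clamp(truth$phi_psii_ef[i] + rnorm(config$n_plants, sd = nz$phi_ef), 0.05, 0.9),
        t_half_phi = clamp(truth$t_half_phi[i] + rnorm(config$n_plants, sd = nz$t_half), 20, 600),
        npq_s = clamp(truth$npq_s[i] + rnorm(config$n_plants, sd = nz$npq_s), 0.05, 2),
        t_npq_max = clamp(truth$t_npq_max[i] + rnorm(config$n_plants, sd = nz$t_npq_max), 60, 600)
      ) %>%
        mutate(npq_max = clamp(truth$npq_max[i] + rnorm(config$n_plants, sd = nz$npq_max),
                               .data$npq_s + 0.05, 3))
    })
    out$induction_params <- params
    fm_dark <- 4.0
    out$induction <- purrr::pmap_dfr(params, function(cultivar, plant, fv_fm,
                                                      phi_psii_ef, t_half_phi,
                                                      npq_s, t_npq_max, npq_max) {
      phi <- clamp(phi_curve(tt, phi_psii_ef, t_half_phi) +
                     rnorm(length(tt), sd = nz$curve_phi), 0.001, 0.98)
      nq <- pmax(npq_curve(tt, npq_max, t_npq_max, npq_s) +
                   rnorm(length(tt), sd = nz$curve_npq), 0)
      fm_prime <- fm_dark / (1 + nq)
      tibble(
        cultivar = cultivar, plant = plant,
        sample_id = sprintf("%s_plant%d", cultivar, plant),
        time_s = tt, f = fm_prime * (1 - phi), fm_prime = fm_prime,
        f0 = (1 - fv_fm) * fm_dark, fm = fm_dark
      )
    })
  }

  if ("heat" %in% what) {
    tt <- config$heat_times
    temp <- smoothed_plate_temp(tt, config$protocol)
    hp <- purrr::map_dfr(seq_len(nc), function(i) {
      tibble(
        cultivar = cultivars[i], plant = seq_len(config$n_heat),
        tmid = clamp(truth$tmid[i] + rnorm(config$n_heat, sd = nz$tmid), 35, 60),
        baseline = clamp(0.40 + rnorm(config$n_heat, sd = nz$heat_baseline), 0.1, 0.8)
      )
    })
    hp <- dplyr::bind_cols(
      hp,
      purrr::map_dfr(hp$tmid, heat_truth, protocol = config$protocol,
                     cadence = stats::median(diff(tt))) %>%
        select("t_dec_true", "t_dec_censored_true", "phi_psii_resid_true")
    )
    out$heat_params <- hp
    out$heat <- purrr::pmap_dfr(
      hp[, c("cultivar", "plant", "tmid", "baseline")],
      function(cultivar, plant, tmid, baseline) {
        phi <- baseline * heat_response(temp, tmid, config$protocol$start_temp)
        phi <- clamp(phi + rnorm(length(tt), sd = nz$curve_phi), 0.001, 0.99)
        tibble(
          cultivar = cultivar, plant = plant,
          sample_id = sprintf("%s_heat%d", cultivar, plant),
          time_s = tt, phi_psii = phi
        )
      }
    )
  }

  if ("drought" %in% what) {
    out$drought <- purrr::map_dfr(seq_len(nc), function(i) {
      dwc <- truth$dw[i] * pmax(1 + rnorm(config$n_pots, sd = nz$dw_cv), 0.2)
      dti_pot <- pmax(truth$dti[i] + rnorm(config$n_pots, sd = nz$dti), 5)
      tibble(
        cultivar = cultivars[i], pot = seq_len(config$n_pots),
        dw_control = dwc, dw_drought = dwc * dti_pot / 100,
        dti = dti_pot,
        residual_fv_fm = clamp(truth$resid_fv_fm[i] +
                                 rnorm(config$n_pots, sd = nz$resid_fv_fm), 40, 120),
        residual_phi_psii_ef = clamp(truth$resid_phi_psii_ef[i] +
                                       rnorm(config$n_pots, sd = nz$resid_phi), 2, 120)
      )
    })
  }

  out$trait_table <- panel_trait_table(out)
  structure(out, class = "panel")
}

# Cultivar means and SEMs over whatever replicate blocks were generated.
panel_trait_table <- function(panel) {
  agg <- function(df, cols) {
    df %>%
      group_by(.data$cultivar) %>%
      summarise(across(dplyr::all_of(cols),
                       list(mean = mean, sem = ~ sd(.x) / sqrt(length(.x)))),
                .groups = "drop")
  }
  tt <- tibble(cultivar = panel$truth$cultivar)
  if (!is.null(panel$induction_params)) {
    tt <- left_join(tt, agg(panel$induction_params,
                            c("fv_fm", "phi_psii_ef", "t_half_phi",
                              "npq_max", "t_npq_max", "npq_s")),
                    by = "cultivar")
  }
  if (!is.null(panel$heat_params)) {
    tt <- left_join(tt, agg(panel$heat_params,
                            c("t_dec_true", "phi_psii_resid_true")),
                    by = "cultivar")
  }
  if (!is.null(panel$drought)) {
    tt <- left_join(tt, agg(panel$drought,
                            c("dw_control", "dti", "residual_fv_fm",
                              "residual_phi_psii_ef")),
                    by = "cultivar")
  }
  tt
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf(
    "<panel> %d cultivars (vigor-heat rho = %g, drought coupling = %g)\n",
    x$config$n_cultivars, x$config$rho_vigor_heat, x$config$drought_coupling
  ))
  for (blk in c("spectra", "induction", "heat", "drought")) {
    if (!is.null(x[[blk]])) {
      cat(sprintf("  %s: %d rows\n", blk, nrow(x[[blk]])))
    }
  }
  invisible(x)
}
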