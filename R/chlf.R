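#' PAM chlorophyll fluorescence equations
#'
#' The standard saturation-pulse quantities derived from a PAM protocol:
#' \describe{
#'   \item{`phi_psii()`}{Effective quantum yield of photosystem II under
#'     actinic light, \eqn{\Phi_{PSII} = (F_m' - F)/F_m'}.}
#'   \item{`npq()`}{Non-photochemical quenching,
#'     \eqn{NPQ = (F_m - F_m')/F_m'}.}
#'   \item{`fv_fm()`}{Maximum quantum yield after dark adaptation,
#'     \eqn{F_v/F_m = (F_m - F_0)/F_m}.}
#' }
#' All are vectorized over their arguments.
#'
#' @param f Current fluorescence yield under light (a.u.).
#' @param fm_prime Maximum fluorescence yield under light, from a saturation
#'   pulse (a.u.); must be positive and `>= f`.
#' @param fm Maximum fluorescence yield after dark adaptation (a.u.).
#' @param f0 Dark fluorescence yield (a.u.); `0 < f0 < fm`.
#' @return A numeric vector. `phi_psii()` and `fv_fm()` lie in `[0, 1]`;
#'   `npq()` is non-negative whenever `fm >= fm_prime`.
#' @examples
#' phi_psii(f = 1, fm_prime = 4) # 0.75
#' npq(fm = 3, fm_prime = 2)     # 0.5
#' fv_fm(f0 = 1, fm = 5)         # 0.8
#' @name pam-equations
NULL

#' @rdname pam-equations
#' @export
phi_psii <- function(f, fm_prime) {
  if (any(fm_prime <= 0)) abort("`fm_prime` must be positive.")
  if (any(f > fm_prime + 1e-12)) {
    abort("Current yield `f` cannot exceed the saturation-pulse yield `fm_prime`.")
  }
  (fm_prime - f) / fm_prime
}

#' @rdname pam-equations
#' @export
npq <- function(fm, fm_prime) {
  if (any(fm_prime <= 0)) abort("`fm_prime` must be positive.")
  (fm - fm_prime) / fm_prime
}

#' @rdname pam-equations
#' @export
fv_fm <- function(f0, fm) {
  if (any(f0 <= 0) || any(fm <= f0)) {
    abort("Dark yields must satisfy fm > f0 > 0.")
  }
  (fm - f0) / fm
}

# Features of one induction trace given derived phi/npq curves.
# times must be strictly increasing; curves same length.
features_from_curves <- function(times, phi, npq_curve, fv_fm_value,
                                 steady_window = 120) {
  n <- length(times)
  stopifnot(length(phi) == n, length(npq_curve) == n)
  duration <- times[n] - times[1L]
  if (duration < 2 * steady_window) {
    abort("Trace must span at least twice the steady-state window.")
  }
  in_window <- times >= times[n] - steady_window
  phi_ef <- mean(phi[in_window])
  npq_s <- mean(npq_curve[in_window])

  i_max <- which.max(npq_curve)[1L] # earliest attaining time on ties
  npq_max <- npq_curve[i_max]
  t_npq_max <- times[i_max]

  half <- phi_ef / 2
  if (phi[1L] >= half) {
    t_half <- times[1L] # already induced at the first pulse
  } else {
    above <- which(phi >= half)
    if (length(above) == 0L) {
      abort("Non-inducing trace: quantum yield never reaches half its steady-state level.")
    }
    i <- above[1L]
    # earliest upward crossing, linearly interpolated between samples
    t_half <- times[i - 1L] +
      (half - phi[i - 1L]) / (phi[i] - phi[i - 1L]) * (times[i] - times[i - 1L])
  }

  tibble(
    fv_fm = fv_fm_value,
    phi_psii_ef = phi_ef,
    t_half_phi = t_half,
    npq_max = npq_max,
    t_npq_max = t_npq_max,
    npq_s = npq_s
  )
}

#' Extract induction-curve features from PAM pulse series
#'
#' Reduces each dark-to-light induction trace to six scalars that summarise
#' photosynthetic activity: the dark-adapted maximum quantum yield
#' (\eqn{F_v/F_m}), the steady-state effective quantum yield under actinic
#' light (\eqn{\Phi_{PSIIef}}), the half-rise time of \eqn{\Phi_{PSII}(t)}
#' (\eqn{t_{1/2}}), the NPQ transient maximum and its time, and the
#' steady-state NPQ level.
#'
#' Steady-state levels are means over the final `steady_window` seconds of
#' the light period. The half-rise time is the earliest upward crossing of
#' half the steady-state quantum yield, linearly interpolated between pulses;
#' the NPQ peak time is the earliest sample attaining the maximum.
#'
#' @param data Tibble with one row per saturation pulse and columns
#'   `sample_id`, `time_s` (seconds since actinic light on, strictly
#'   increasing within a sample), `f`, `fm_prime`, plus per-sample dark
#'   references `f0` and `fm` (constant within a sample).
#' @param steady_window Width of the steady-state averaging window, seconds.
#' @return A tibble with one row per sample: `sample_id`, `fv_fm`,
#'   `phi_psii_ef`, `t_half_phi` (s), `npq_max`, `t_npq_max` (s), `npq_s`.
#' @examples
#' tr <- tibble::tibble(
#'   sample_id = "p1", time_s = seq(30, 900, 30),
#'   f0 = 0.75, fm = 4
#' )
#' phi <- 0.6 * (1 - 2^(-tr$time_s / 150))
#' npq_t <- 0.8 * (1 - exp(-tr$time_s / 60))
#' tr$fm_prime <- tr$fm / (1 + npq_t)
#' tr$f <- tr$fm_prime * (1 - phi)
#' chlf_features(tr)
#' @export
chlf_features <- function(data, steady_window = 120) {
  needed <- c("sample_id", "time_s", "f", "fm_prime", "f0", "fm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  data %>%
    group_by(.data$sample_id) %>%
    arrange(.data$time_s, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$time_s) <= 0)) {
        abort("Pulse times must be strictly increasing within a sample.")
      }
      f0 <- d$f0[1L]
      fm <- d$fm[1L]
      features_from_curves(
        times = d$time_s,
        phi = phi_psii(d$f, d$fm_prime),
        npq_curve = npq(fm, d$fm_prime),
        fv_fm_value = fv_fm(f0, fm),
        steady_window = steady_window
      )
    }) %>%
    ungroup()
}
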