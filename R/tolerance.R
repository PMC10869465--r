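#' Drought tolerance ratios
#'
#' `dti()` is the drought tolerance index: dry weight under drought as a
#' percentage of the well-watered control. `residual_level()` is the same
#' stressed/control percentage applied to any physiological parameter (e.g.
#' \eqn{F_v/F_m} or \eqn{\Phi_{PSIIef}}). `soil_rwc()` is the relative water
#' content of soil, `100 (FW - DW) / FW`. All are vectorized; values above
#' 100% are legitimate (stress can coincide with higher values than control).
#'
#' @param dw_drought,dw_control Plant dry weights (mg) under drought and
#'   control; `dw_control` must be positive.
#' @param param_drought,param_control Parameter values under drought and
#'   control; `param_control` must be positive.
#' @param fw,dw Fresh and dry soil weight (g).
#' @return Percentages.
#' @examples
#' dti(50, 100)             # 50
#' residual_level(0.4, 0.8) # 50
#' @name drought-indices
NULL

#' @rdname drought-indices
#' @export
dti <- function(dw_drought, dw_control) {
  if (any(dw_control <= 0)) abort("Control dry weight must be positive.")
  100 * dw_drought / dw_control
}

#' @rdname drought-indices
#' @export
residual_level <- function(param_drought, param_control) {
  if (any(param_control <= 0)) abort("Control parameter value must be positive.")
  100 * param_drought / param_control
}

#' @rdname drought-indices
#' @export
soil_rwc <- function(fw, dw) {
  if (any(fw <= 0) || any(dw < 0) || any(dw > fw)) {
    abort("Soil weights must satisfy fw >= dw >= 0 and fw > 0.")
  }
  100 * (fw - dw) / fw
}

#' Stepped hot-plate heating protocol
#'
#' The plate set-point schedule used for the heat-ramp assay: temperature
#' raised in discrete increments at fixed intervals from a start to an end
#' temperature, then held at the end temperature. The default is 25 to 55
#' degrees C in 5-degree steps every 5 minutes with a 10-minute hold at 55,
#' i.e. a 40-minute ramp.
#'
#' @param start_temp,end_temp,step_temp Temperatures, degrees C.
#' @param step_duration Dwell time per step below `end_temp`, seconds.
#' @param final_hold Hold at `end_temp`, seconds.
#' @return A `heat_ramp_protocol` object.
#' @export
heat_ramp_protocol <- function(start_temp = 25, end_temp = 55, step_temp = 5,
                               step_duration = 300, final_hold = 600) {
  if (end_temp < start_temp || step_temp <= 0 || step_duration <= 0 ||
      final_hold < 0) {
    abort("Invalid heat-ramp protocol parameters.")
  }
  n_steps <- floor((end_temp - start_temp) / step_temp + 1e-9)
  structure(
    list(
      start_temp = start_temp, end_temp = end_temp, step_temp = step_temp,
      step_duration = step_duration, final_hold = final_hold,
      duration = n_steps * step_duration + final_hold
    ),
    class = "heat_ramp_protocol"
  )
}

#' @export
print.heat_ramp_protocol <- function(x, ...) {
  cat(sprintf(
    "<heat_ramp_protocol> %g-%g degC by %g degC every %g s, %g s hold (%g s total)\n",
    x$start_temp, x$end_temp, x$step_temp, x$step_duration, x$final_hold,
    x$duration
  ))
  invisible(x)
}

#' Plate set-point temperature at given times
#'
#' @param time_s Times since ramp start, seconds (vectorized).
#' @param protocol A [heat_ramp_protocol()].
#' @return Set-point temperatures (degrees C); times beyond the protocol end
#'   stay at `end_temp`, negative times at `start_temp`.
#' @export
plate_setpoint <- function(time_s, protocol = heat_ramp_protocol()) {
  stopifnot(inherits(protocol, "heat_ramp_protocol"))
  lvl <- floor(pmax(time_s, 0) / protocol$step_duration)
  temp <- protocol$start_temp + lvl * protocol$step_temp
  pmin(temp, protocol$end_temp)
}

#' Heat tolerance from quantum-yield traces under a stepped ramp
#'
#' Summarises \eqn{\Phi_{PSII}(t)} recorded during plate heating into two
#' tolerance statistics per sample:
#' \describe{
#'   \item{`t_dec`}{The plate set-point temperature at which
#'     \eqn{\Phi_{PSII}} first drops below its baseline level at the start
#'     temperature. \eqn{\Phi_{PSII}} typically rises transiently during
#'     early heating, so only crossings after the trace has exceeded its
#'     baseline count; traces that never exceed baseline use the first
#'     crossing directly. Reported in the protocol's step quanta.}
#'   \item{`phi_psii_resid`}{The mean \eqn{\Phi_{PSII}} over the final 60 s,
#'     as a percentage of baseline.}
#' }
#' The baseline is the mean over the last `baseline_window` seconds of the
#' initial (start-temperature) step. A trace that never falls below baseline
#' gets `t_dec = end_temp` and `t_dec_censored = TRUE`, flagged with a
#' warning.
#'
#' @param data Tibble with columns `sample_id`, `time_s`, `phi_psii`
#'   (values in `[0, 1]`), covering the full protocol.
#' @param protocol A [heat_ramp_protocol()].
#' @param baseline_window Seconds, within the initial step.
#' @return Tibble: `sample_id`, `baseline`, `t_dec` (degrees C),
#'   `t_dec_censored`, `phi_psii_resid` (%).
#' @export
heat_tolerance <- function(data, protocol = heat_ramp_protocol(),
                           baseline_window = 120) {
  needed <- c("sample_id", "time_s", "phi_psii")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (baseline_window <= 0 || baseline_window > protocol$step_duration) {
    abort("`baseline_window` must lie within the initial step.")
  }
  res <- data %>%
    group_by(.data$sample_id) %>%
    arrange(.data$time_s, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      t <- d$time_s
      phi <- d$phi_psii
      cadence <- if (length(t) > 1L) stats::median(diff(t)) else Inf
      if (max(t) < protocol$duration - cadence - 1e-9) {
        abort("Trace is shorter than the heating protocol.")
      }
      base_idx <- t >= protocol$step_duration - baseline_window &
        t < protocol$step_duration
      if (!any(base_idx)) {
        abort("No samples inside the baseline window of the initial step.")
      }
      baseline <- mean(phi[base_idx])

      # first index eligible for a decline: after the transient rise, i.e.
      # after the trace has exceeded baseline (if it ever does)
      after_base <- t >= protocol$step_duration
      rose <- which(after_base & phi > baseline)
      start_i <- if (length(rose) > 0L) rose[1L] else which(after_base)[1L]
      below <- which(after_base & phi < baseline & seq_along(t) >= start_i)
      if (length(below) == 0L) {
        warn(sprintf(
          "Sample '%s': quantum yield never fell below baseline; t_dec censored at %g degC.",
          key$sample_id, protocol$end_temp
        ))
        t_dec <- protocol$end_temp
        censored <- TRUE
      } else {
        t_dec <- plate_setpoint(t[below[1L]], protocol)
        censored <- FALSE
      }

      final_idx <- t >= max(t) - 60
      resid <- 100 * mean(phi[final_idx]) / baseline
      tibble(
        baseline = baseline, t_dec = t_dec, t_dec_censored = censored,
        phi_psii_resid = resid
      )
    }) %>%
    ungroup()
  res
}
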