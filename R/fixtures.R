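#' Bundled reference trait tables for an 11-cultivar wheat panel
#'
#' Curated cultivar-mean trait tables (means with SEM and, where available,
#' Tukey letter groupings) for a laboratory screening of eleven wheat
#' cultivars. Three tables ship with the package:
#' \describe{
#'   \item{`"chlf_control"` (alias `"table1"`)}{Induction-curve features of
#'     well-watered two-week-old seedlings: \eqn{F_v/F_m},
#'     \eqn{\Phi_{PSIIef}}, \eqn{NPQ_s}, \eqn{t_{1/2}(\Phi_{PSIIef})},
#'     \eqn{NPQ_{max}}, \eqn{t(NPQ_{max})}; n = 20 plants per cultivar.}
#'   \item{`"drought_residuals"` (alias `"table2"`)}{Residual (% of control)
#'     dry weight and chlorophyll-fluorescence parameters after a 14-day
#'     drought; residual dry weight is the drought tolerance index; n = 10.}
#'   \item{`"heat_tolerance"` (alias `"table4"`)}{Heat-ramp statistics:
#'     `t_dec` (plate temperature of quantum-yield decline, degrees C) and
#'     the residual quantum yield at the final temperature (%); n = 10.}
#' }
#'
#' @param name One of the table names or aliases above.
#' @return A tibble keyed by `cultivar` with trait means, `*_sem` columns,
#'   and `*_letters` columns where printed.
#' @examples
#' load_fixture("heat_tolerance")$t_dec
#' @export
load_fixture <- function(name) {
  files <- c(
    chlf_control = "panel_chlf_control.csv",
    table1 = "panel_chlf_control.csv",
    drought_residuals = "panel_drought_residuals.csv",
    table2 = "panel_drought_residuals.csv",
    heat_tolerance = "panel_heat_tolerance.csv",
    table4 = "panel_heat_tolerance.csv"
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(files)) {
    abort(sprintf(
      "Unknown fixture '%s'. Available: %s.",
      as.character(name)[1L],
      paste(unique(names(files)), collapse = ", ")
    ))
  }
  path <- system.file("extdata", files[[name]], package = "specphen",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
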