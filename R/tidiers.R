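#' Tidiers for specphen result objects
#'
#' broom-style methods: `tidy()` returns the per-unit table (per band, per
#' wavelength pair, per group), `glance()` a one-row summary.
#'
#' @param x A `corr_spectrum`, `corr_heatmap`, `anova_cld` or `ndi_matrix`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name specphen-tidiers
NULL

#' @rdname specphen-tidiers
#' @export
tidy.corr_spectrum <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname specphen-tidiers
#' @export
glance.corr_spectrum <- function(x, ...) {
  runs <- attr(x, "runs")
  tibble(
    n_bands = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_runs = nrow(runs),
    peak_r = if (all(is.na(x$r))) NA_real_ else x$r[which.max(abs(x$r))],
    alpha = attr(x, "alpha"),
    n = attr(x, "n")
  )
}

#' @rdname specphen-tidiers
#' @export
tidy.corr_heatmap <- function(x, ...) {
  g <- x$grid
  tibble(
    lambda1 = rep(g, times = length(g)),
    lambda2 = rep(g, each = length(g)),
    r = as.vector(x$r),
    p = as.vector(x$p)
  )
}

#' @rdname specphen-tidiers
#' @export
glance.corr_heatmap <- function(x, ...) {
  finite_r <- x$r[!is.na(x$r)]
  tibble(
    n_pairs = sum(!is.na(x$p)) / 2L,
    n_significant = sum(x$p < x$alpha, na.rm = TRUE) / 2L,
    n_regions = nrow(x$regions),
    peak_r = if (length(finite_r) == 0L) NA_real_ else
      finite_r[which.max(abs(finite_r))],
    alpha = x$alpha,
    n = x$n
  )
}

#' @rdname specphen-tidiers
#' @export
tidy.anova_cld <- function(x, ...) {
  x$letters
}

#' @rdname specphen-tidiers
#' @export
glance.anova_cld <- function(x, ...) {
  dplyr::bind_cols(x$anova, tibble(n_groups = nrow(x$letters),
                                   n_letters = length(unique(unlist(
                                     strsplit(x$letters$letters, "")
                                   ))),
                                   alpha = x$alpha))
}

#' @rdname specphen-tidiers
#' @export
tidy.ndi_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  tibble(
    lambda1 = rep(g, times = length(g)),
    lambda2 = rep(g, each = length(g)),
    ndi = as.vector(unclass(x))
  )
}

#' @export
generics::tidy

#' @export
generics::glance
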