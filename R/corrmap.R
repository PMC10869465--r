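#' Pearson correlation with two-tailed p-value
#'
#' Standard product-moment correlation; the p-value comes from the exact
#' t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with `n - 2` degrees of
#' freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @examples
#' pearson_cor(1:10, (1:10) * 2 + 1) # r = 1
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length.")
  if (n < 3L) abort("Pearson correlation needs at least 3 paired values.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  r <- cor(x, y)
  tibble(r = r, p = r_to_p(r, n), n = n)
}

# Two-tailed p for Pearson r at sample size n (t transform, df = n - 2).
r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t_stat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(t_stat, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}

# Correlate each column of X with y; returns list(r, p). Columns with zero
# variance get NA.
colwise_pearson <- function(X, y) {
  n <- length(y)
  sds <- apply(X, 2L, sd)
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[sds == 0] <- NA_real_
  p <- r_to_p(r, n)
  p[is.na(r)] <- NA_real_
  list(r = r, p = p)
}

# Match a trait to sample ids; trait may be a named vector or a two-column
# data frame (id, value).
align_trait <- function(trait, ids) {
  if (is.data.frame(trait)) {
    stopifnot(ncol(trait) >= 2L)
    vals <- setNames(trait[[2L]], trait[[1L]])
  } else if (!is.null(names(trait))) {
    vals <- trait
  } else {
    if (length(trait) != length(ids)) {
      abort("Unnamed trait vector length must match the number of samples.")
    }
    return(as.numeric(trait))
  }
  miss <- setdiff(ids, names(vals))
  if (length(miss) > 0L) {
    abort(sprintf("Trait has no value for sample(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  as.numeric(vals[ids])
}

#' Trait-reflectance correlation spectrum
#'
#' Correlates a per-cultivar trait with reflectance at every band of the
#' grid, giving a spectrum of Pearson coefficients with per-band two-tailed
#' p-values and the maximal contiguous runs of significant bands.
#'
#' @param spectra Long tibble of cultivar-mean spectra: `sample_id`,
#'   `wavelength_nm`, `reflectance` (one row per cultivar and band).
#' @param trait Per-cultivar trait values: a named vector or a two-column
#'   data frame `(sample_id, value)` covering every cultivar in `spectra`.
#' @param alpha Significance level for the band mask.
#' @param min_run Minimum number of contiguous significant bands for a run to
#'   be reported (shorter runs are speckle and are dropped).
#' @return A `corr_spectrum` object: a tibble `wavelength_nm`, `r`, `p`,
#'   `significant`, with the run table in `attr(, "runs")`
#'   (`lambda_start`, `lambda_end`, `n_bands`, `peak_r`).
#' @export
correlation_spectrum <- function(spectra, trait, alpha = 0.05, min_run = 2L) {
  stopifnot(all(c("sample_id", "wavelength_nm", "reflectance") %in% names(spectra)))
  wide <- tidyr::pivot_wider(spectra[, c("sample_id", "wavelength_nm", "reflectance")],
                             names_from = "wavelength_nm",
                             values_from = "reflectance")
  ids <- wide$sample_id
  if (length(ids) < 3L) abort("Need at least 3 cultivars for a correlation spectrum.")
  X <- as.matrix(wide[, -1L, drop = FALSE])
  bands <- as.numeric(colnames(X))
  o <- order(bands)
  X <- X[, o, drop = FALSE]
  bands <- bands[o]
  y <- align_trait(trait, ids)
  if (sd(y) == 0) abort("Trait has zero variance across cultivars.")

  cp <- colwise_pearson(X, y)
  sig <- !is.na(cp$p) & cp$p < alpha
  runs <- significant_runs(bands, sig, cp$r, min_run = min_run)

  out <- tibble(wavelength_nm = bands, r = cp$r, p = cp$p, significant = sig)
  structure(out, runs = runs, alpha = alpha, n = length(ids),
            class = c("corr_spectrum", class(out)))
}

# Maximal contiguous runs of TRUE in `sig` along ordered bands.
significant_runs <- function(bands, sig, r, min_run = 2L) {
  empty <- tibble(lambda_start = numeric(), lambda_end = numeric(),
                  n_bands = integer(), peak_r = numeric())
  if (!any(sig)) return(empty)
  rl <- rle(sig)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values & rl$lengths >= min_run
  if (!any(keep)) return(empty)
  purrr::map_dfr(which(keep), function(k) {
    i <- starts[k]:ends[k]
    tibble(
      lambda_start = bands[starts[k]], lambda_end = bands[ends[k]],
      n_bands = length(i), peak_r = r[i][which.max(abs(r[i]))]
    )
  })
}

#' Trait-NDI correlation heatmap over all wavelength pairs
#'
#' Correlates a per-cultivar trait with the NDI at every wavelength pair,
#' giving matrices of Pearson r and p over \eqn{(\lambda_1, \lambda_2)} and
#' the 4-connected regions of significant pairs. The r matrix inherits the
#' NDI's antisymmetry; the p matrix is symmetric; the diagonal is undefined
#' (NDI of a band with itself is identically 0) and stored as `NA`.
#'
#' @param panel_ndis Named list of per-cultivar [ndi_matrix()] means, one per
#'   cultivar, all on the same grid.
#' @param trait Per-cultivar trait values (named vector or two-column data
#'   frame), covering every cultivar in `panel_ndis`.
#' @param alpha Significance level.
#' @param min_area Minimum number of cells for a significant region to be
#'   reported.
#' @return A `corr_heatmap` object: list with `grid`, matrices `r` and `p`,
#'   `regions` (tibble: `region`, `n_cells`, `lambda1_min`, `lambda1_max`,
#'   `lambda2_min`, `lambda2_max`, `peak_r`), `alpha`, `n`.
#' @export
ndi_correlation_heatmap <- function(panel_ndis, trait, alpha = 0.05,
                                    min_area = 4L) {
  stopifnot(is.list(panel_ndis), length(panel_ndis) >= 3L)
  g <- attr(panel_ndis[[1L]], "grid")
  for (m in panel_ndis) {
    if (!same_grid(attr(m, "grid"), g)) abort("NDI matrices are on different grids.")
  }
  ids <- names(panel_ndis)
  y <- align_trait(trait, ids)
  if (sd(y) == 0) abort("Trait has zero variance across cultivars.")
  nb <- length(g)

  # stack upper triangle only; mirror with sign flip afterwards
  ut <- upper.tri(matrix(0, nb, nb))
  X <- vapply(panel_ndis, function(m) unclass(m)[ut], numeric(sum(ut)))
  cp <- colwise_pearson(t(X), y)

  r_mat <- matrix(NA_real_, nb, nb)
  p_mat <- matrix(NA_real_, nb, nb)
  r_mat[ut] <- cp$r
  p_mat[ut] <- cp$p
  r_mat[lower.tri(r_mat)] <- -t(r_mat)[lower.tri(r_mat)]
  p_mat[lower.tri(p_mat)] <- t(p_mat)[lower.tri(p_mat)]
  dimnames(r_mat) <- dimnames(p_mat) <-
    list(lambda1 = as.character(g), lambda2 = as.character(g))

  regions <- extract_regions(p_mat, alpha = alpha, min_area = min_area,
                             grid = g, r = r_mat)
  structure(
    list(grid = g, r = r_mat, p = p_mat, regions = regions,
         alpha = alpha, n = length(ids)),
    class = "corr_heatmap"
  )
}

#' @export
print.corr_heatmap <- function(x, ...) {
  cat(sprintf(
    "<corr_heatmap> %d x %d wavelength pairs, n = %d cultivars, alpha = %g\n",
    nrow(x$r), ncol(x$r), x$n, x$alpha
  ))
  cat(sprintf("%d significant region(s)\n", nrow(x$regions)))
  if (nrow(x$regions) > 0L) print(x$regions)
  invisible(x)
}

#' Connected significant regions of a p-value matrix
#'
#' Labels the 4-connected components of the sub-threshold mask `p < alpha`
#' and summarises each component's wavelength bounding box and peak
#' correlation. Used to turn a significance heatmap into a short list of
#' candidate wavelength-pair regions.
#'
#' @param p_matrix Matrix of p-values in `[0, 1]`; `NA` cells (e.g. the
#'   diagonal) never belong to a region.
#' @param alpha Significance threshold.
#' @param min_area Minimum component size in cells.
#' @param grid Wavelengths labelling rows/columns; defaults to row count
#'   indices when absent.
#' @param r Optional matrix of correlation coefficients for the `peak_r`
#'   summary.
#' @return Tibble: `region`, `n_cells`, `lambda1_min`, `lambda1_max`,
#'   `lambda2_min`, `lambda2_max`, `peak_r` (NA when `r` is missing),
#'   ordered by decreasing size.
#' @export
extract_regions <- function(p_matrix, alpha = 0.05, min_area = 4L,
                            grid = NULL, r = NULL) {
  stopifnot(is.matrix(p_matrix))
  if (any(p_matrix < 0 | p_matrix > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  if (is.null(grid)) grid <- seq_len(nrow(p_matrix))
  mask <- !is.na(p_matrix) & p_matrix < alpha
  lab <- label_components(mask)
  empty <- tibble(region = integer(), n_cells = integer(),
                  lambda1_min = numeric(), lambda1_max = numeric(),
                  lambda2_min = numeric(), lambda2_max = numeric(),
                  peak_r = numeric())
  if (max(lab) == 0L) return(empty)
  out <- purrr::map_dfr(seq_len(max(lab)), function(k) {
    cells <- which(lab == k, arr.ind = TRUE)
    if (nrow(cells) < min_area) return(NULL)
    peak <- if (is.null(r)) NA_real_ else {
      vals <- r[cells]
      vals[which.max(abs(vals))]
    }
    tibble(
      region = k, n_cells = nrow(cells),
      lambda1_min = grid[min(cells[, 1L])], lambda1_max = grid[max(cells[, 1L])],
      lambda2_min = grid[min(cells[, 2L])], lambda2_max = grid[max(cells[, 2L])],
      peak_r = peak
    )
  })
  if (nrow(out) == 0L) return(empty)
  out <- out[order(-out$n_cells), ]
  out$region <- seq_len(nrow(out))
  out
}

# 4-connected component labelling of a logical matrix (iterative flood fill).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    current <- current + 1L
    stack <- start
    lab[start] <- current
    while (length(stack) > 0L) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      nbrs <- c(
        if (i > 1L) cell - 1L,
        if (i < nr) cell + 1L,
        if (j > 1L) cell - nr,
        if (j < nc) cell + nr
      )
      nbrs <- nbrs[mask[nbrs] & lab[nbrs] == 0L]
      lab[nbrs] <- current
      stack <- c(stack, nbrs)
    }
  }
  lab
}
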