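#' Normalized difference index (NDI)
#'
#' `ndi()` computes the normalized difference index
#' \deqn{NDI = (I_{\lambda_1} - I_{\lambda_2}) / (I_{\lambda_1} + I_{\lambda_2})}
#' for a pair of reflectance intensities. Classic vegetation indices (NDVI,
#' GNDVI, RNDVI) are special cases for particular wavelength pairs. When both
#' intensities are zero the pair carries no contrast information and the index
#' is defined as 0, so downstream correlation maps stay finite.
#'
#' @param i1,i2 Non-negative reflectance intensities (vectorized).
#' @return `(i1 - i2) / (i1 + i2)`, in `[-1, 1]`; 0 where `i1 + i2 == 0`.
#' @examples
#' ndi(0.6, 0.2) # 0.5
#' ndi(0.3, 0.3) # 0
#' @export
ndi <- function(i1, i2) {
  if (any(i1 < 0, na.rm = TRUE) || any(i2 < 0, na.rm = TRUE)) {
    abort("Reflectance intensities must be non-negative.")
  }
  s <- i1 + i2
  out <- ifelse(s == 0, 0, (i1 - i2) / s)
  as.numeric(out)
}

#' Exhaustive NDI wavelength-pair matrix
#'
#' Computes the NDI for every ordered pair of bands of one reflectance
#' spectrum. The result is antisymmetric (`m[i, j] == -m[j, i]`) with a zero
#' diagonal; rows index \eqn{\lambda_1}, columns \eqn{\lambda_2}.
#'
#' @param spectrum Either a numeric vector of band reflectances, or a
#'   one-sample spectrum tibble with columns `wavelength_nm` and
#'   `reflectance`.
#' @param grid Band wavelengths (nm); taken from the tibble when `spectrum`
#'   is one, otherwise defaults to [default_grid()].
#' @return An `ndi_matrix`: a numeric matrix with wavelengths as dimnames and
#'   the grid stored in `attr(, "grid")`.
#' @examples
#' m <- ndi_matrix(c(0.6, 0.2), grid = wavelength_grid(400, 403, 3))
#' m[1, 2] # 0.5
#' @export
ndi_matrix <- function(spectrum, grid = NULL) {
  if (is.data.frame(spectrum)) {
    stopifnot(all(c("wavelength_nm", "reflectance") %in% names(spectrum)))
    if ("sample_id" %in% names(spectrum) &&
        length(unique(spectrum$sample_id)) > 1L) {
      abort("`spectrum` contains several samples; use `ndi_matrices()`.")
    }
    spectrum <- spectrum[order(spectrum$wavelength_nm), ]
    grid <- spectrum$wavelength_nm
    values <- spectrum$reflectance
  } else {
    values <- as.numeric(spectrum)
    if (is.null(grid)) grid <- default_grid()
  }
  if (length(values) != length(grid)) {
    abort("Spectrum length does not match the wavelength grid.")
  }
  if (any(values < 0)) {
    abort("Reflectance values must be non-negative.")
  }
  s <- outer(values, values, "+")
  d <- outer(values, values, "-")
  m <- ifelse(s == 0, 0, d / s)
  # enforce exact antisymmetry against rounding in the outer sums
  m <- (m - t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(lambda1 = as.character(as.numeric(grid)),
                      lambda2 = as.character(as.numeric(grid)))
  structure(m, grid = as.numeric(grid), class = c("ndi_matrix", "matrix", "array"))
}

#' Per-sample NDI matrices for a panel of spectra
#'
#' @param spectra Long spectrum tibble with columns `sample_id`,
#'   `wavelength_nm`, `reflectance` (one row per sample and band).
#' @return A named list of [ndi_matrix()] objects, one per sample, in the
#'   order samples first appear.
#' @export
ndi_matrices <- function(spectra) {
  stopifnot(all(c("sample_id", "wavelength_nm", "reflectance") %in% names(spectra)))
  ids <- unique(spectra$sample_id)
  out <- lapply(ids, function(id) {
    ndi_matrix(spectra[spectra$sample_id == id,
                       c("wavelength_nm", "reflectance")])
  })
  setNames(out, ids)
}

#' Average NDI matrices (e.g. pot-level matrices into a cultivar mean)
#'
#' @param mats A list of [ndi_matrix()] objects on the same grid.
#' @return Their elementwise mean, an `ndi_matrix`.
#' @export
mean_ndi_matrix <- function(mats) {
  stopifnot(length(mats) >= 1L)
  g <- attr(mats[[1L]], "grid")
  for (m in mats) {
    if (!same_grid(attr(m, "grid"), g)) abort("NDI matrices are on different grids.")
  }
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  structure(avg, grid = g, class = c("ndi_matrix", "matrix", "array"))
}

#' White-standard normalization of raw band intensities
#'
#' Divides raw per-band intensities by the spectrum of a calibrated white
#' reference panel recorded on the same grid, yielding unitless reflectance.
#' Values that come out negative (sensor noise below the dark level) are
#' clipped to zero with a warning.
#'
#' @param raw Numeric vector of raw per-band intensities.
#' @param white Numeric vector of white-standard intensities, strictly
#'   positive at every band.
#' @param grid Band wavelengths (nm); defaults to [default_grid()].
#' @param sample_id Label for the resulting spectrum.
#' @return A spectrum tibble with columns `sample_id`, `wavelength_nm`,
#'   `reflectance`.
#' @export
normalize_to_white <- function(raw, white, grid = default_grid(),
                               sample_id = "sample") {
  raw <- as.numeric(raw)
  white <- as.numeric(white)
  if (length(raw) != length(white) || length(raw) != length(grid)) {
    abort("`raw`, `white` and `grid` must have the same length.")
  }
  bad <- which(white <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "White standard is not positive at band(s) %s nm.",
      paste(as.numeric(grid)[bad], collapse = ", ")
    ))
  }
  refl <- raw / white
  if (any(refl < 0)) {
    warn(sprintf("Clipped %d negative reflectance value(s) to 0.",
                 sum(refl < 0)))
    refl[refl < 0] <- 0
  }
  tibble(
    sample_id = sample_id,
    wavelength_nm = as.numeric(grid),
    reflectance = refl
  )
}

#' Mean spectrum over a region of interest of a hyperspectral cube
#'
#' @param cube Numeric array `[rows, cols, bands]` of reflectance.
#' @param mask Logical matrix `[rows, cols]`; `TRUE` pixels belong to the ROI.
#' @param grid Band wavelengths (nm), length matching `dim(cube)[3]`.
#' @param sample_id Label for the resulting spectrum.
#' @return A spectrum tibble (`sample_id`, `wavelength_nm`, `reflectance`)
#'   with the per-band mean over masked pixels.
#' @export
roi_mean_spectrum <- function(cube, mask, grid = default_grid(),
                              sample_id = "roi") {
  stopifnot(length(dim(cube)) == 3L)
  if (!is.logical(mask)) mask <- mask != 0
  if (!all(dim(mask) == dim(cube)[1:2])) {
    abort("`mask` dimensions must match the cube's spatial dimensions.")
  }
  if (dim(cube)[3L] != length(grid)) {
    abort("Cube band axis does not match the wavelength grid.")
  }
  if (!any(mask)) abort("ROI mask selects no pixels.")
  flat <- matrix(cube, nrow = prod(dim(cube)[1:2]), ncol = dim(cube)[3L])
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  tibble(sample_id = sample_id, wavelength_nm = as.numeric(grid),
         reflectance = vals)
}

#' Convenience vegetation mask from an NDVI-style threshold
#'
#' Flags pixels whose NDI between a near-infrared and a red band exceeds a
#' threshold — a quick way to separate green tissue from background when no
#' externally drawn ROI is available.
#'
#' @inheritParams roi_mean_spectrum
#' @param nir,red Band wavelengths (nm) used for the index; the nearest grid
#'   band is taken.
#' @param threshold Minimum NDI for a pixel to count as vegetation.
#' @return Logical matrix `[rows, cols]`.
#' @export
ndvi_mask <- function(cube, grid = default_grid(), nir = 770, red = 670,
                      threshold = 0.3) {
  stopifnot(length(dim(cube)) == 3L)
  i_nir <- which.min(abs(as.numeric(grid) - nir))
  i_red <- which.min(abs(as.numeric(grid) - red))
  a <- cube[, , i_nir]
  b <- cube[, , i_red]
  s <- a + b
  idx <- ifelse(s == 0, 0, (a - b) / s)
  matrix(idx > threshold, nrow = dim(cube)[1L])
}

#' Cultivar-mean spectra from replicate (pot-level) spectra
#'
#' @param spectra Long spectrum tibble with `sample_id`, `wavelength_nm`,
#'   `reflectance` and a grouping column naming the cultivar.
#' @param by Name of the grouping column (default `"cultivar"`).
#' @return Tibble `sample_id` (the group), `wavelength_nm`, `reflectance`
#'   with per-band group means.
#' @export
mean_spectra <- function(spectra, by = "cultivar") {
  stopifnot(by %in% names(spectra))
  spectra %>%
    group_by(.data[[by]], .data$wavelength_nm) %>%
    summarise(reflectance = mean(.data$reflectance), .groups = "drop") %>%
    rename(sample_id = !!by)
}
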