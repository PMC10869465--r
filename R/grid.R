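#' Wavelength grids
#'
#' A wavelength grid is the ordered set of spectral bands on which all
#' reflectance and NDI computations operate. The canonical acquisition grid of
#' the supported push-broom cameras spans the visible to near-infrared range,
#' 400-800 nm sampled every 3 nm, which yields 134 bands
#' (400, 403, ..., 799 nm; the next step, 802 nm, would fall outside the
#' range, so there is no 800 nm band).
#'
#' @param start First band, nm.
#' @param end Upper end of the range, nm (inclusive; a band is emitted only if
#'   it falls on the step lattice).
#' @param step Band spacing, nm.
#'
#' @return A numeric vector of class `wavelength_grid`: strictly increasing,
#'   equally spaced band centres in nm.
#' @examples
#' g <- default_grid()
#' length(g) # 134
#' range(g)  # 400 799
#' @export
wavelength_grid <- function(start = 400, end = 800, step = 3) {
  if (!is.numeric(start) || !is.numeric(end) || !is.numeric(step) ||
      step <= 0 || end < start) {
    abort("`start`, `end` must satisfy start <= end and `step` must be > 0.")
  }
  bands <- seq(from = start, to = end, by = step)
  structure(bands, class = c("wavelength_grid", "numeric"), step = step)
}

#' @rdname wavelength_grid
#' @export
default_grid <- function() {
  wavelength_grid(400, 800, 3)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %g-%g nm, step %g nm\n",
    length(x), min(x), max(x), attr(x, "step")
  ))
  invisible(x)
}

# Validate that a numeric vector is a usable grid; returns the step.
grid_step <- function(bands) {
  if (length(bands) < 2L) {
    abort("A wavelength grid needs at least two bands.")
  }
  d <- diff(bands)
  if (any(d <= 0)) {
    abort("Wavelength grid must be strictly increasing.")
  }
  if (diff(range(d)) > 1e-9) {
    abort("Wavelength grid must have a constant step.")
  }
  d[1L]
}

# Check two band vectors describe the same grid.
same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) < 1e-9)
}
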