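#' Read and write the package's CSV formats
#'
#' Long-format CSV readers/writers for the three measurement types:
#' \describe{
#'   \item{spectra}{`sample_id, wavelength_nm, reflectance` (optional extra
#'     grouping columns such as `cultivar` are preserved).}
#'   \item{induction traces}{`sample_id, time_s, f, fm_prime, f0, fm`.}
#'   \item{heat-ramp traces}{`sample_id, time_s, phi_psii`.}
#' }
#' Readers validate the required columns and report the file name on
#' failure.
#'
#' @param path File path.
#' @param data Tibble to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name csv-io
NULL

read_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: '%s'.", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("File '%s' is missing column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @rdname csv-io
#' @export
read_spectra <- function(path) {
  read_checked(path, c("sample_id", "wavelength_nm", "reflectance"))
}

#' @rdname csv-io
#' @export
read_induction <- function(path) {
  read_checked(path, c("sample_id", "time_s", "f", "fm_prime", "f0", "fm"))
}

#' @rdname csv-io
#' @export
read_heat_ramp <- function(path) {
  read_checked(path, c("sample_id", "time_s", "phi_psii"))
}

#' @rdname csv-io
#' @export
write_panel_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read an ENVI-style hyperspectral cube
#'
#' Minimal reader for the ENVI header + flat-binary cube format written by
#' many imaging spectrometers: a text header (`key = value` pairs, with
#' `samples`, `lines`, `bands`, `data type`, `interleave`, optional
#' `wavelength = {...}`) next to a raw binary file. Supported layouts are
#' BSQ/BIL/BIP with data types 4 (float32), 5 (float64), 2 (int16),
#' 12 (uint16) and 1 (uint8), little or big endian.
#'
#' @param header_path Path to the `.hdr` file; the binary is looked up as
#'   the same path without `.hdr` (or with `.dat`/`.img`/`.raw` appended).
#' @return List: `cube` (array `[lines, samples, bands]`), `wavelength_nm`
#'   (numeric or `NULL`).
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) {
    abort(sprintf("ENVI header not found: '%s'.", header_path))
  }
  hdr <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(hdr[[key]])) {
      abort(sprintf("ENVI header '%s' lacks required field '%s'.",
                    header_path, key))
    }
  }
  ns <- as.integer(hdr$samples)
  nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr$interleave)
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1L) "big" else "little"

  base <- sub("\\.hdr$", "", header_path)
  candidates <- c(base, paste0(base, c(".dat", ".img", ".raw", ".bin")))
  data_path <- candidates[file.exists(candidates)][1L]
  if (is.na(data_path)) {
    abort(sprintf("No binary cube found next to header '%s'.", header_path))
  }

  spec <- switch(as.character(dtype),
    "1" = list(what = "integer", size = 1L, signed = FALSE),
    "2" = list(what = "integer", size = 2L, signed = TRUE),
    "4" = list(what = "numeric", size = 4L, signed = TRUE),
    "5" = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    abort(sprintf("Unsupported ENVI data type %d.", dtype))
  )
  n_values <- ns * nl * nb
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  raw_vals <- readBin(con, what = spec$what, n = n_values, size = spec$size,
                      signed = spec$signed, endian = endian)
  if (length(raw_vals) != n_values) {
    abort(sprintf("Cube '%s' is truncated: expected %d values, got %d.",
                  data_path, n_values, length(raw_vals)))
  }
  cube <- switch(interleave,
    bsq = aperm(array(raw_vals, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw_vals, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(raw_vals, dim = c(nb, ns, nl)), c(3L, 2L, 1L)),
    abort(sprintf("Unsupported interleave '%s'.", interleave))
  )
  wl <- if (!is.null(hdr$wavelength)) {
    as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1L]])
  } else NULL
  list(cube = cube, wavelength_nm = wl)
}

parse_envi_header <- function(path) {
  lines_raw <- readLines(path, warn = FALSE)
  # fold multi-line { ... } values onto one line
  txt <- paste(lines_raw, collapse = "\n")
  out <- list()
  pos <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1L]]
  if (pos[1L] == -1L) return(out)
  starts <- as.integer(pos)
  lens <- attr(pos, "match.length")
  for (k in seq_along(starts)) {
    piece <- substr(txt, starts[k], starts[k] + lens[k] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    out[[key]] <- val
  }
  out
}

#' Write an ENVI-style cube (for round-trip tests and interchange)
#'
#' @param cube Array `[lines, samples, bands]`.
#' @param path Output stem; writes `<path>.hdr` and the raw binary `<path>`.
#' @param wavelength_nm Optional band wavelengths for the header.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, path, wavelength_nm = NULL,
                            interleave = "bsq") {
  stopifnot(length(dim(cube)) == 3L)
  nl <- dim(cube)[1L]
  ns <- dim(cube)[2L]
  nb <- dim(cube)[3L]
  interleave <- match.arg(interleave, c("bsq", "bil", "bip"))
  perm <- switch(interleave,
    bsq = c(2L, 1L, 3L),
    bil = c(2L, 3L, 1L),
    bip = c(3L, 2L, 1L)
  )
  vals <- as.numeric(aperm(cube, perm))
  con <- file(path, "wb")
  writeBin(vals, con, size = 8L, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", ns),
    sprintf("lines = %d", nl),
    sprintf("bands = %d", nb),
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0"
  )
  if (!is.null(wavelength_nm)) {
    hdr <- c(hdr, sprintf("wavelength = {%s}",
                          paste(wavelength_nm, collapse = ", ")))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(paste0(path, ".hdr"))
}
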