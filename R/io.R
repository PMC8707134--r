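META_COLS <- c("spot", "plot", "block", "main", "sub", "x", "y")

#' Container for a set of reflectance spectra on a common wavelength grid
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param reflectance Numeric matrix, one row per measurement spot, one
#'   column per wavelength; all values finite, expected in \[0, 1\] (values
#'   outside produce a warning, not an error).
#' @param meta Data frame of per-row metadata with columns `spot`, `plot`,
#'   `block`, `main`, `sub`, `x`, `y`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, reflectance, meta) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(reflectance))
    stop("wavelength count (", length(wavelengths),
         ") does not match spectrum width (", ncol(reflectance), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(reflectance)))
    stop("reflectance contains missing or non-finite values")
  missing_meta <- setdiff(META_COLS, names(meta))
  if (length(missing_meta))
    stop("metadata is missing columns: ", paste(missing_meta, collapse = ", "))
  meta <- as.data.frame(meta)[, META_COLS]
  if (nrow(meta) != nrow(reflectance))
    stop("metadata rows (", nrow(meta), ") do not match spectra rows (",
         nrow(reflectance), ")")
  if (any(reflectance < 0 | reflectance > 1))
    warning("reflectance values outside [0, 1] present")
  rownames(meta) <- NULL
  dimnames(reflectance) <- NULL
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", nrow(x$reflectance), "spectra x",
      length(x$wavelengths), "bands (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  invisible(x)
}

#' Read / write wide-format spectra CSV
#'
#' The CSV dialect has one row per measurement spot: the metadata columns
#' `spot, plot, block, main, sub, x, y` followed by one numeric column per
#' wavelength, headed by the wavelength in nm. `read_spectra_csv()` validates
#' the header (strictly increasing numeric wavelengths), completeness and
#' numeric content, reporting offending rows/columns on failure;
#' `write_spectra_csv()` writes the same dialect, so synthetic data exercise
#' the real I/O path.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a [spectrum_set()];
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  missing_meta <- setdiff(META_COLS, names(dt))
  if (length(missing_meta))
    stop("spectra CSV is missing metadata columns: ",
         paste(missing_meta, collapse = ", "))
  wl_names <- setdiff(names(dt), META_COLS)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl))
    stop("non-numeric wavelength headers: ",
         paste(head(wl_names[is.na(wl)], 5), collapse = ", "))
  if (any(diff(wl) <= 0))
    stop("wavelength headers are not strictly increasing (first violation after ",
         wl[which(diff(wl) <= 0)[1]], " nm)")
  refl <- as.matrix(dt[wl_names])
  if (!is.numeric(refl) || !all(is.finite(refl))) {
    bad <- which(!is.finite(refl), arr.ind = TRUE)
    stop("non-numeric or missing reflectance values, e.g. row ",
         bad[1, 1], ", wavelength ", wl[bad[1, 2]], " nm")
  }
  spectrum_set(wl, refl, dt[META_COLS])
}

#' @rdname read_spectra_csv
#' @param s A [spectrum_set()].
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  refl <- as.data.frame(s$reflectance)
  names(refl) <- as.character(s$wavelengths)
  data.table::fwrite(cbind(s$meta, refl), path)
  invisible(path)
}
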