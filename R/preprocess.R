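#' Splice correction across detector boundaries
#'
#' Field spectroradiometers assemble each spectrum from several detectors
#' (typically VIS-NIR up to 1000 nm, then two SWIR detectors switching at
#' 1800 nm), which can leave small jumps at the transition wavelengths. This
#' correction offsets each longer-wavelength segment additively so that the
#' value at the first point of the segment equals the linear extrapolation
#' from the last two points of the (already corrected) preceding segment.
#' Segment shapes are otherwise unchanged.
#'
#' @param s A [spectrum_set()] on any grid containing the boundaries.
#' @param boundaries Wavelengths (nm) at which detectors switch; each must
#'   lie on the grid, strictly inside the wavelength range.
#' @return A corrected `spectrum_set`.
#' @export
splice_correct <- function(s, boundaries = c(1000, 1800)) {
  stopifnot(inherits(s, "spectrum_set"))
  wl <- s$wavelengths
  x <- s$reflectance
  for (b in sort(boundaries)) {
    i <- match(b, wl)
    if (is.na(i))
      stop("splice boundary ", b, " nm is not on the wavelength grid")
    if (i < 3 || i > length(wl))
      stop("splice boundary ", b, " nm needs two grid points before it")
    # linear extrapolation from the two points preceding the boundary
    slope <- (x[, i - 1] - x[, i - 2]) / (wl[i - 1] - wl[i - 2])
    pred <- x[, i - 1] + slope * (wl[i] - wl[i - 1])
    offset <- pred - x[, i]
    x[, i:ncol(x)] <- x[, i:ncol(x)] + offset
  }
  s$reflectance <- x
  s
}

#' Average a 1-nm grid into 10-nm bins
#'
#' Reduces a full-resolution 350-2500 nm spectrum (2151 bands) to 215 bands
#' by arithmetic averaging over 10-nm intervals: bin k covers
#' \[350 + 10k, 360 + 10k) for k = 0..214, with the final 2500 nm point
#' folded into the last bin (which therefore averages 11 members). Output
#' wavelength labels are the mean wavelength of each bin's members.
#'
#' @param s A `spectrum_set` on the 1-nm 350-2500 nm grid.
#' @return A 215-band `spectrum_set`.
#' @export
bin_to_10nm <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  wl <- s$wavelengths
  if (!isTRUE(all.equal(wl, 350:2500)))
    stop("binning requires the full 1-nm grid 350-2500 nm")
  bin <- pmin(floor((wl - 350) / 10), 214)
  counts <- as.vector(table(bin))
  # column-group means via rowsum on the transpose
  binned <- t(rowsum(t(s$reflectance), bin) / counts)
  wl_out <- as.vector(rowsum(wl, bin) / counts)
  spectrum_set(wl_out, binned, s$meta)
}

#' Multiplicative scatter correction
#'
#' Removes additive and multiplicative scatter effects by regressing every
#' spectrum on a reference spectrum, \eqn{x_i \approx a_i + b_i r}, and
#' returning \eqn{(x_i - a_i)/b_i}. The reference defaults to the column-wise
#' mean spectrum of the set.
#'
#' @param s A `spectrum_set` with at least 2 rows (unless `reference` given).
#' @param reference Optional reference spectrum (length = band count).
#' @return A corrected `spectrum_set`.
#' @export
msc_correct <- function(s, reference = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  x <- s$reflectance
  if (is.null(reference)) {
    if (nrow(x) < 2)
      stop("MSC needs >= 2 spectra when no reference is supplied")
    reference <- colMeans(x)
  }
  stopifnot(length(reference) == ncol(x))
  rc <- reference - mean(reference)
  b <- as.vector(x %*% rc) / sum(rc^2)
  bad <- abs(b) < 1e-8
  if (any(bad))
    stop("degenerate scatter fit (|slope| < 1e-8) for rows: ",
         paste(head(which(bad), 10), collapse = ", "))
  a <- rowMeans(x) - b * mean(reference)
  s$reflectance <- (x - a) / b
  s
}

# least-squares polynomial smoothing weights: fitted value at position `at`
# from a polynomial of degree `order` on offsets `offsets`
.polyfit_weights <- function(offsets, order, at = 0) {
  A <- outer(offsets, 0:order, `^`)
  a0 <- (at)^(0:order)
  as.vector(A %*% solve(crossprod(A), a0))
}

#' Savitzky-Golay smoothing
#'
#' Smooths each spectrum with a moving least-squares polynomial fit of the
#' given order over a window of `w = 2n + 1` points. Near the edges the
#' polynomial is fitted on the truncated asymmetric window (no padding), so
#' polynomials up to the given order are reproduced exactly everywhere.
#'
#' @param s A `spectrum_set`.
#' @param w Odd window size (points), `w > order`, `w <=` band count.
#' @param order Polynomial order.
#' @return A smoothed `spectrum_set`.
#' @export
savitzky_golay <- function(s, w = 11, order = 2) {
  stopifnot(inherits(s, "spectrum_set"))
  if (w %% 2 != 1) stop("Savitzky-Golay window size must be odd")
  nb <- ncol(s$reflectance)
  stopifnot(w > order, w <= nb)
  half <- (w - 1) / 2
  S <- matrix(0, nb, nb)
  interior <- .polyfit_weights(-half:half, order)
  for (p in seq_len(nb)) {
    lo <- max(1, p - half)
    hi <- min(nb, p + half)
    if (lo == p - half && hi == p + half) {
      S[p, lo:hi] <- interior
    } else {
      S[p, lo:hi] <- .polyfit_weights((lo:hi) - p, order)
    }
  }
  s$reflectance <- s$reflectance %*% t(S)
  s
}

#' Preprocessing configuration and driver
#'
#' Applies the standard preprocessing chain to a raw full-resolution
#' spectrum set: splice correction, 10-nm bin averaging, and optionally
#' multiplicative scatter correction and Savitzky-Golay smoothing. The
#' default chain is splice + binning only: downstream analysis of raw
#' (rather than scatter-corrected) spectra is the default because, at equal
#' numbers of retained components, raw contact-probe spectra typically
#' explain more variance; MSC and SG remain available as switches.
#'
#' @param s A raw `spectrum_set` on the 1-nm grid.
#' @param splice_boundaries Detector transition wavelengths (nm).
#' @param apply_msc,apply_sg Logical switches for the optional steps.
#' @param sg_w,sg_order Savitzky-Golay window size (odd, `2n + 1`) and
#'   polynomial order.
#' @return A preprocessed (binned) `spectrum_set`.
#' @export
preprocess_spectra <- function(s, splice_boundaries = c(1000, 1800),
                               apply_msc = FALSE, apply_sg = FALSE,
                               sg_w = 11, sg_order = 2) {
  s <- splice_correct(s, splice_boundaries)
  s <- bin_to_10nm(s)
  if (apply_msc) s <- msc_correct(s)
  if (apply_sg) s <- savitzky_golay(s, sg_w, sg_order)
  s
}
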