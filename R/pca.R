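#' Principal component analysis on the correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of `x`. Loadings are scaled
#' as eigenvector times the square root of the eigenvalue (so squared
#' loadings per variable sum to its communality), and raw component scores
#' are the standardized data projected on the eigenvectors.
#'
#' @param x Numeric matrix (rows = observations) with >= 2 rows and no
#'   zero-variance column.
#' @return List with `eigenvalues` (descending), `loadings`
#'   (variables x components), `scores`, `cum_var` (cumulative variance
#'   proportions) and `cor` (the correlation matrix).
#' @export
correlation_pca <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance columns: ",
         paste(head(which(sds == 0), 10), collapse = ", "))
  R <- cor(x)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Z <- scale(x)
  list(eigenvalues = ev,
       loadings = sweep(e$vectors, 2, sqrt(ev), `*`),
       scores = Z %*% e$vectors,
       cum_var = cumsum(ev) / length(ev),
       cor = R)
}

#' Number of components to retain
#'
#' Kaiser candidates are the components with eigenvalue > 1; among them the
#' smallest prefix whose cumulative variance proportion exceeds
#' `cum_threshold` is retained. If even all candidates fall short of the
#' threshold, all candidates are retained with a warning.
#'
#' @param eigenvalues Descending eigenvalues of a correlation PCA.
#' @param cum_threshold Cumulative variance proportion to exceed.
#' @return Integer count of retained components.
#' @export
retain_components <- function(eigenvalues, cum_threshold = 0.97) {
  stopifnot(all(diff(eigenvalues) <= 1e-8))
  cand <- sum(eigenvalues > 1)
  if (cand == 0) return(0L)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  ok <- which(cum[seq_len(cand)] > cum_threshold)
  if (length(ok) == 0) {
    warning("all ", cand, " Kaiser candidates explain only ",
            sprintf("%.1f%%", 100 * cum[cand]),
            " cumulative variance; retaining all of them")
    return(as.integer(cand))
  }
  as.integer(min(ok))
}

#' VARIMAX rotation of retained loadings
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion, with
#' Kaiser row normalization by default. After rotation each component's sign
#' is fixed so that its largest-magnitude loading is positive, making
#' results reproducible across eigen-solvers. With a single component the
#' rotation is the identity.
#'
#' @param loadings Variables x components loading matrix (>= 1 component).
#' @param normalize Apply Kaiser normalization (default `TRUE`).
#' @return List with `loadings` (rotated) and `rotmat` (orthogonal).
#' @export
varimax_rotate <- function(loadings, normalize = TRUE) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (k < 2) {
    rot <- list(loadings = loadings, rotmat = diag(k))
  } else {
    v <- stats::varimax(loadings, normalize = normalize, eps = 1e-8)
    rot <- list(loadings = loadings %*% v$rotmat, rotmat = unclass(v$rotmat))
  }
  # sign convention: dominant loading of each component positive
  flip <- vapply(seq_len(k), function(j) {
    lj <- rot$loadings[, j]
    sign(lj[which.max(abs(lj))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot$loadings <- sweep(rot$loadings, 2, flip, `*`)
  rot$rotmat <- sweep(rot$rotmat, 2, flip, `*`)
  rot
}

#' Regression-method component scores from rotated loadings
#'
#' Thomson regression scores: standardized data times
#' \eqn{R^{-1} \Lambda}, where \eqn{R} is the correlation matrix and
#' \eqn{\Lambda} the (rotated) loading matrix. Each score column is then
#' centered to mean exactly 0 (no rescaling).
#'
#' @param x The data matrix the PCA was computed from.
#' @param loadings Rotated loading matrix.
#' @param R Optional precomputed correlation matrix of `x`.
#' @return Scores matrix (rows = observations, columns = components).
#' @export
score_samples <- function(x, loadings, R = NULL) {
  x <- as.matrix(x)
  loadings <- as.matrix(loadings)
  stopifnot(nrow(loadings) == ncol(x))
  if (is.null(R)) R <- cor(x)
  B <- tryCatch(solve(R, loadings), error = function(e)
    stop("correlation matrix is computationally singular; ",
         "cannot form regression scores", call. = FALSE))
  scores <- scale(x) %*% B
  scale(scores, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Salient wavelength intervals from rotated loadings
#'
#' Reports, per component, the maximal runs of contiguous bands whose
#' loading x 100 magnitude reaches `threshold`, as nm intervals. An empty
#' interval list is a legitimate outcome (a component may carry
#' interpretable structure without any loading exceeding the limit).
#'
#' @param loadings Rotated loading matrix (natural scale, not x 100).
#' @param wavelengths Band wavelengths (nm), one per loading row.
#' @param threshold Salience limit on the x 100 loading scale.
#' @return Data frame with columns `pc`, `start_nm`, `end_nm`.
#' @export
select_salient_bands <- function(loadings, wavelengths, threshold = 80) {
  loadings <- as.matrix(loadings)
  stopifnot(length(wavelengths) == nrow(loadings))
  out <- list()
  for (j in seq_len(ncol(loadings))) {
    hit <- abs(loadings[, j]) * 100 >= threshold
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- which(r$values)
    out[[length(out) + 1]] <- data.frame(
      pc = j, start_nm = wavelengths[starts[sel]], end_nm = wavelengths[ends[sel]])
  }
  if (length(out) == 0)
    return(data.frame(pc = integer(), start_nm = numeric(), end_nm = numeric()))
  do.call(rbind, out)
}

#' Full spectral PCA stage
#'
#' Runs correlation PCA on the binned reflectance of a [spectrum_set()],
#' retains components by the Kaiser + cumulative-variance rule, rotates them
#' with VARIMAX, computes regression scores (centered to mean 0) and selects
#' salient wavelength intervals.
#'
#' @param s A (binned) `spectrum_set`.
#' @param cum_threshold Cumulative variance proportion for retention.
#' @param loading_threshold Salience limit on the loading x 100 scale.
#' @return An object of class `pca_result` with elements `eigenvalues`,
#'   `n_retained`, `cum_var`, `loadings` (rotated, bands x retained),
#'   `rotmat`, `scores` (data frame: spot metadata + `PC1..PCk` columns),
#'   `salient`, `wavelengths`.
#' @export
spectra_pca <- function(s, cum_threshold = 0.97, loading_threshold = 80) {
  stopifnot(inherits(s, "spectrum_set"))
  p <- correlation_pca(s$reflectance)
  k <- retain_components(p$eigenvalues, cum_threshold)
  if (k < 1) stop("no component retained (no eigenvalue > 1)")
  rot <- varimax_rotate(p$loadings[, seq_len(k), drop = FALSE])
  sc <- score_samples(s$reflectance, rot$loadings, R = p$cor)
  colnames(sc) <- paste0("PC", seq_len(k))
  scores <- cbind(s$meta, as.data.frame(sc))
  structure(list(eigenvalues = p$eigenvalues, n_retained = k,
                 cum_var = p$cum_var,
                 loadings = rot$loadings, rotmat = rot$rotmat,
                 scores = scores,
                 salient = select_salient_bands(rot$loadings, s$wavelengths,
                                                loading_threshold),
                 wavelengths = s$wavelengths),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- x$n_retained
  cat("Correlation PCA with VARIMAX rotation\n")
  cat(sprintf("  retained %d component(s); eigenvalues: %s\n", k,
              paste(sprintf("%.2f", x$eigenvalues[seq_len(k)]), collapse = ", ")))
  cat(sprintf("  cumulative variance of retained set: %.1f%%\n",
              100 * x$cum_var[k]))
  if (nrow(x$salient)) {
    for (j in unique(x$salient$pc)) {
      iv <- x$salient[x$salient$pc == j, ]
      cat(sprintf("  PC%d salient bands: %s\n", j,
                  paste(sprintf("%g-%g nm", iv$start_nm, iv$end_nm),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
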