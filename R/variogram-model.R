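#' Isotropic variogram / covariance models
#'
#' Constructs a stationary isotropic residual covariance model of the
#' spherical-with-nugget or pure-nugget family. The model is parameterized by
#' the nugget variance `nugget` (\eqn{\sigma_0}), the partial sill `psill`
#' (\eqn{\sigma}) and, for the spherical family, the range `range`
#' (\eqn{\rho}, metres). Its semivariogram is
#' \deqn{\gamma(h) = \sigma_0 + \sigma\,(1.5\,h/\rho - 0.5\,(h/\rho)^3)}
#' for \eqn{0 < h < \rho}, \eqn{\gamma(h) = \sigma_0 + \sigma} for
#' \eqn{h \ge \rho}, and \eqn{\gamma(0) = 0}. The covariance is
#' \eqn{c(h) = \sigma_0 + \sigma - \gamma(h)}, so the nugget contributes only
#' at exactly zero distance.
#'
#' @param family `"spherical"` or `"nugget"`.
#' @param nugget Nugget variance, \eqn{\ge 0}.
#' @param psill Partial sill, \eqn{\ge 0} (forced to 0 for the nugget family).
#' @param range Range in metres, required positive for the spherical family.
#' @param se Optional named numeric vector of parameter standard errors
#'   (attached by the fitting routines).
#' @return An object of class `variogram_model`.
#' @seealso [vgm_semivariance()], [vgm_covariance()], [fit_variogram_lse()]
#' @export
#' @examples
#' m <- variogram_model("spherical", nugget = 0.376, psill = 0.053, range = 6.41)
#' vgm_semivariance(m, c(0, 3.205, 10)) # 0, 0.41244, 0.429
variogram_model <- function(family = c("spherical", "nugget"),
                            nugget, psill = 0, range = NA_real_, se = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(nugget), length(nugget) == 1, nugget >= 0,
            is.numeric(psill), length(psill) == 1, psill >= 0)
  if (family == "spherical") {
    stopifnot(is.numeric(range), length(range) == 1, !is.na(range), range > 0)
  } else {
    psill <- 0
    range <- NA_real_
  }
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, se = se),
            class = "variogram_model")
}

#' @rdname variogram_model
#' @param m A `variogram_model`.
#' @param h Vector of non-negative distances (metres).
#' @export
vgm_semivariance <- function(m, h) {
  stopifnot(inherits(m, "variogram_model"), all(h >= 0))
  sill <- m$nugget + m$psill
  if (m$family == "nugget") {
    g <- ifelse(h > 0, m$nugget, 0)
  } else {
    u <- pmin(h / m$range, 1)
    g <- ifelse(h > 0, m$nugget + m$psill * (1.5 * u - 0.5 * u^3), 0)
  }
  g
}

#' @rdname variogram_model
#' @export
vgm_covariance <- function(m, h) {
  sill <- m$nugget + m$psill
  ifelse(h == 0, sill, sill - vgm_semivariance(m, h))
}

# fast covariance matrix over a pairwise-distance matrix of DISTINCT
# locations (diagonal gets the full sill; branchless for speed)
.cov_matrix <- function(m, D) {
  n <- nrow(D)
  sill <- m$nugget + m$psill
  if (m$family == "nugget" || m$psill == 0) {
    C <- diag(sill, n)
  } else {
    u <- D / m$range
    u[u > 1] <- 1
    C <- m$psill * (1 - 1.5 * u + 0.5 * u^3)
    diag(C) <- sill
  }
  C
}

#' Variance shares of a variogram model
#'
#' `nugget_share()` is the nugget as a fraction of the total sill
#' \eqn{\sigma_0/(\sigma_0+\sigma)}; `structured_share()` is its complement
#' \eqn{\sigma/(\sigma_0+\sigma)}, the spatially structured fraction of the
#' residual variance.
#'
#' @param m A `variogram_model`.
#' @return A fraction in \[0, 1\].
#' @export
nugget_share <- function(m) {
  stopifnot(inherits(m, "variogram_model"))
  m$nugget / (m$nugget + m$psill)
}

#' @rdname nugget_share
#' @export
structured_share <- function(m) 1 - nugget_share(m)

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram model: nugget = %.4g", x$family, x$nugget))
  if (x$family == "spherical")
    cat(sprintf(", partial sill = %.4g, range = %.4g m", x$psill, x$range))
  cat("\n")
  if (!is.null(x$fit_table)) {
    print(x$fit_table, row.names = FALSE)
  }
  invisible(x)
}
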