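#' Empirical (experimental) semivariogram
#'
#' Method-of-moments semivariance estimate
#' \eqn{\hat\gamma_k = \frac{1}{2 N_k}\sum_{(i,j) \in k}(z_i - z_j)^2}
#' over distance classes of width `lag_width` up to `max_dist`. Lag centers
#' are the mean pair distance within each class. Lags with fewer than 30
#' pairs are flagged as unreliable (and ignored by the fitting routines).
#'
#' @param values Numeric vector (typically OLS residuals).
#' @param locations Data frame/matrix with columns `x`, `y`.
#' @param lag_width Distance class width in metres (default 0.5, the spot
#'   spacing of the canonical design).
#' @param max_dist Maximum pair distance considered; defaults to half the
#'   maximum pairwise distance.
#' @return An object of class `empirical_variogram`: data frame with
#'   columns `lag` (mean pair distance), `gamma`, `n_pairs`, `reliable`,
#'   plus attributes `lag_width` and `max_dist`.
#' @export
empirical_variogram <- function(values, locations, lag_width = 0.5,
                                max_dist = NULL) {
  xy <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  stopifnot(length(values) == nrow(xy), lag_width > 0)
  if (nrow(xy) < 30)
    warning("empirical variogram from fewer than 30 points is unstable")
  d <- dist(xy)
  dz2 <- dist(values)^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d <= max_dist & d > 0
  if (!any(keep))
    stop("max_dist ", max_dist, " m is below the smallest pairwise distance")
  d <- d[keep]
  dz2 <- dz2[keep]
  k <- factor(ceiling(d / lag_width - 1e-12))
  k <- factor(k, levels = levels(k)[order(as.numeric(levels(k)))])
  n_pairs <- as.vector(table(k))
  out <- data.frame(lag = as.vector(tapply(d, k, mean)),
                    gamma = as.vector(tapply(dz2, k, sum)) / (2 * n_pairs),
                    n_pairs = n_pairs)
  out$reliable <- out$n_pairs >= 30
  structure(out, class = c("empirical_variogram", "data.frame"),
            lag_width = lag_width, max_dist = max_dist)
}

# weighted least-squares objective and analytic Jacobian for the spherical
# semivariogram gamma(h) = s0 + ps * (1.5 u - 0.5 u^3), u = min(h/rho, 1)
.sph_gamma <- function(par, h) {
  u <- pmin(h / par[3], 1)
  par[1] + par[2] * (1.5 * u - 0.5 * u^3)
}

.sph_jac <- function(par, h) {
  u <- pmin(h / par[3], 1)
  inside <- h < par[3]
  cbind(1,
        1.5 * u - 0.5 * u^3,
        ifelse(inside, par[2] * 1.5 * (u^3 - u) / par[3], 0))
}

#' Weighted least-squares fit of a variogram model
#'
#' Fits a pure-nugget or spherical-with-nugget model to an empirical
#' semivariogram by weighted least squares with pair-count weights
#' \eqn{N_k}, using only reliable lags (>= 30 pairs). The spherical fit is
#' bounded (\eqn{\sigma_0, \sigma \ge 0}, \eqn{0 < \rho \le} `max_range`)
#' and multistarted over 5 deterministic range initializations; approximate
#' standard errors, t values and p values come from the Gauss-Newton
#' covariance at the optimum. If no spherical start converges, a
#' pure-nugget fallback is returned with a warning.
#'
#' @param ev An [empirical_variogram()].
#' @param family `"spherical"` or `"nugget"`.
#' @param max_range Upper bound for the range; defaults to the largest lag
#'   distance.
#' @return A [variogram_model()] with a `fit_table` component (parameter,
#'   estimate, se, t, p) and attributes `wrss` (weighted residual sum of
#'   squares) and `range_interior`.
#' @export
fit_variogram_lse <- function(ev, family = c("spherical", "nugget"),
                              max_range = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(ev, "empirical_variogram"))
  use <- ev[ev$reliable, , drop = FALSE]
  if (nrow(use) == 0) use <- ev
  h <- use$lag
  g <- use$gamma
  nk <- use$n_pairs
  if (is.null(max_range)) max_range <- max(h)

  if (family == "nugget" || nrow(use) < 3) {
    if (family == "spherical")
      warning("fewer than 3 usable lags; falling back to a pure-nugget fit")
    return(.nugget_fit(h, g, nk))
  }

  wrss <- function(par) sum(nk * (g - .sph_gamma(par, h))^2)
  sill0 <- max(mean(g), 1e-8)
  best <- NULL
  for (rho0 in max_range * c(0.15, 0.3, 0.5, 0.75, 1.0)) {
    init <- c(max(min(g), 0.25 * sill0, 1e-8), max(sill0 - min(g), 1e-8), rho0)
    fit <- tryCatch(
      optim(init, wrss, method = "L-BFGS-B",
            lower = c(0, 0, 1e-6), upper = c(Inf, Inf, max_range),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("spherical variogram fit failed to converge; returning a ",
            "pure-nugget fit")
    return(.nugget_fit(h, g, nk))
  }
  par <- best$par
  # Gauss-Newton covariance with weighted residual variance
  J <- .sph_jac(par, h)
  dfree <- max(nrow(use) - 3, 1)
  s2 <- best$value / dfree
  V <- tryCatch(s2 * solve(crossprod(J * sqrt(nk))), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, 3) else sqrt(pmax(diag(V), 0))
  tval <- par / se
  m <- variogram_model("spherical", nugget = par[1], psill = par[2],
                       range = par[3],
                       se = setNames(se, c("nugget", "psill", "range")))
  m$fit_table <- data.frame(parameter = c("nugget", "psill", "range"),
                            estimate = par, se = se, t = tval,
                            p = 2 * pt(-abs(tval), dfree))
  attr(m, "wrss") <- best$value
  attr(m, "range_interior") <- par[3] < 0.999 * max_range
  m
}

.nugget_fit <- function(h, g, nk) {
  s0 <- sum(nk * g) / sum(nk)
  dfree <- max(length(g) - 1, 1)
  s2 <- sum(nk * (g - s0)^2) / dfree
  se <- sqrt(s2 / sum(nk))
  tval <- s0 / se
  m <- variogram_model("nugget", nugget = s0, se = c(nugget = se))
  m$fit_table <- data.frame(parameter = "nugget", estimate = s0, se = se,
                            t = tval,
                            p = if (se > 0) 2 * pt(-abs(tval), dfree) else 0)
  attr(m, "wrss") <- sum(nk * (g - s0)^2)
  m
}

#' Select between spherical and pure-nugget residual models
#'
#' Fits the spherical model and accepts it only when its partial sill is
#' significantly different from zero (t-test p < `alpha`) and the fitted
#' range is interior to its bounds, and at least 3 reliable lags were
#' available; otherwise the pure-nugget fit is returned. The decision and
#' its triggering statistic are recorded in the `"selection"` attribute.
#'
#' @param ev An [empirical_variogram()].
#' @param alpha Significance level for the partial-sill test.
#' @param max_range Upper bound for the range (see [fit_variogram_lse()]).
#' @return A fitted [variogram_model()].
#' @export
select_model <- function(ev, alpha = 0.05, max_range = NULL) {
  stopifnot(inherits(ev, "empirical_variogram"))
  if (sum(ev$reliable) < 3) {
    m <- fit_variogram_lse(ev, "nugget", max_range)
    attr(m, "selection") <- "nugget (fewer than 3 reliable lags)"
    return(m)
  }
  sph <- fit_variogram_lse(ev, "spherical", max_range)
  if (sph$family == "spherical") {
    p_sill <- sph$fit_table$p[sph$fit_table$parameter == "psill"]
    if (is.finite(p_sill) && p_sill < alpha &&
        isTRUE(attr(sph, "range_interior"))) {
      attr(sph, "selection") <- sprintf(
        "spherical (partial-sill p = %.4g < %.2g, range interior)",
        p_sill, alpha)
      return(sph)
    }
    reason <- if (!is.finite(p_sill) || p_sill >= alpha)
      sprintf("partial-sill p = %.4g >= %.2g", p_sill, alpha)
    else "range at bound"
  } else {
    reason <- "spherical fit unavailable"
  }
  m <- fit_variogram_lse(ev, "nugget", max_range)
  attr(m, "selection") <- paste0("nugget (", reason, ")")
  m
}
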