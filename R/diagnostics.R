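#' Composite-null normality tests
#'
#' Kolmogorov-Smirnov (Lilliefors), Cramer-von Mises and Anderson-Darling
#' tests of normality with mean and variance estimated from the sample,
#' using the standard tabulated / asymptotic p-value approximations for the
#' composite case (Lilliefors-type for KS, Stephens-type modifications for
#' CvM and AD).
#'
#' @param x Numeric vector, n >= 8, non-constant.
#' @return Data frame with columns `test`, `statistic`, `p`.
#' @export
normality_tests <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8) stop("normality tests need n >= 8")
  if (sd(x) == 0) stop("normality tests are undefined for constant input")
  # the CvM/AD approximations floor out near 7.4e-10; the truncated value is
  # kept (decisions only compare p to alpha)
  ks <- suppressWarnings(nortest::lillie.test(x))
  cvm <- suppressWarnings(nortest::cvm.test(x))
  ad <- suppressWarnings(nortest::ad.test(x))
  data.frame(test = c("Kolmogorov-Smirnov", "Cramer-von Mises",
                      "Anderson-Darling"),
             statistic = c(ks$statistic, cvm$statistic, ad$statistic),
             p = c(ks$p.value, cvm$p.value, ad$p.value),
             row.names = NULL)
}

#' Blom rank-based inverse-normal scores
#'
#' Transforms a sample to normal scores by Blom's formula
#' \eqn{y_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))}, where \eqn{r_i} is the rank
#' of observation i (ties receive average ranks) and n the number of
#' non-missing values.
#'
#' @param x Numeric vector (may contain `NA`, which propagate).
#' @return List of class `normal_scores` with `y` (transformed values),
#'   `r` (ranks) and `n`.
#' @export
blom_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  stopifnot(n >= 1)
  r <- rep(NA_real_, length(x))
  r[ok] <- rank(x[ok], ties.method = "average")
  y <- qnorm((r - 3 / 8) / (n + 1 / 4))
  structure(list(y = y, r = r, n = n), class = "normal_scores")
}

#' Levene's test of variance homogeneity
#'
#' Classical Levene test: a one-way ANOVA of the absolute deviations from
#' the group means. `df1 = k - 1`, `df2 = n - k`.
#'
#' @param x Numeric vector.
#' @param groups Group labels, >= 2 groups with >= 2 observations each.
#' @return Data frame with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, groups) {
  groups <- factor(groups)
  stopifnot(length(x) == length(groups))
  counts <- table(groups)
  if (length(counts) < 2) stop("Levene's test needs >= 2 groups")
  if (any(counts < 2))
    stop("groups with < 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  absdev <- abs(x - ave(x, groups))
  a <- anova(lm(absdev ~ groups))
  data.frame(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
             p = a$`Pr(>F)`[1])
}

#' Spatial weight matrix from a distance cutoff
#'
#' Builds a symmetric, zero-diagonal spatial weight matrix over a set of
#' locations: `binary` weights are 1 for all pairs with
#' `0 < d_ij <= cutoff`; `inverse-distance` weights are `1/d_ij` on the same
#' support. Locations left without any neighbor at the chosen cutoff are an
#' error. The weight sums `S0`, `S1`, `S2` used by the normality-null
#' moments of Moran's I and Geary's c are precomputed.
#'
#' @param locations Data frame/matrix with columns `x`, `y` (>= 2 distinct
#'   points).
#' @param method `"binary"` or `"inverse"`.
#' @param cutoff Neighborhood distance cutoff in metres.
#' @return An object of class `weight_spec` with the sparse symmetric weight
#'   matrix `W` and sums `S0`, `S1`, `S2`.
#' @export
build_weight_matrix <- function(locations, method = c("binary", "inverse"),
                                cutoff = 1.0) {
  method <- match.arg(method)
  xy <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  n <- nrow(xy)
  stopifnot(n >= 2, cutoff > 0)
  d <- as.matrix(dist(xy))
  w <- (d > 0 & d <= cutoff) * 1
  if (method == "inverse") w <- ifelse(w > 0, 1 / d, 0)
  deg <- rowSums(w > 0)
  if (any(deg == 0))
    stop("locations without neighbors at cutoff ", cutoff, " m: ",
         paste(head(which(deg == 0), 10), collapse = ", "))
  W <- Matrix::Matrix(w, sparse = TRUE)
  row_sums <- rowSums(w)
  structure(list(W = W, n = n,
                 S0 = sum(row_sums),
                 S1 = 2 * sum(w^2),        # symmetric: 0.5 * sum((w + t(w))^2)
                 S2 = sum((2 * row_sums)^2),
                 method = method, cutoff = cutoff),
            class = "weight_spec")
}

#' Moran's I test of global spatial autocorrelation
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}
#'   {\sum_i (x_i - \bar x)^2}}
#' with null expectation \eqn{-1/(n-1)} and standard deviation from the
#' normality-assumption moment formula; the two-sided Z test is reported.
#'
#' @param x Numeric non-constant vector, one value per weight-matrix
#'   location.
#' @param w A [build_weight_matrix()] result.
#' @return Data frame of class `autocorr_test` with `statistic`, `observed`,
#'   `expected`, `sd`, `Z`, `p`.
#' @export
morans_i <- function(x, w) {
  stopifnot(inherits(w, "weight_spec"), length(x) == w$n)
  n <- w$n
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("Moran's I is undefined for constant input")
  obs <- (n / w$S0) * sum(xc * as.numeric(w$W %*% xc)) / ss
  expd <- -1 / (n - 1)
  v <- (n^2 * w$S1 - n * w$S2 + 3 * w$S0^2) / ((n^2 - 1) * w$S0^2) - expd^2
  autocorr_result("Moran's I", obs, expd, sqrt(v))
}

#' Geary's c test of global spatial autocorrelation
#'
#' \deqn{c = \frac{n - 1}{2 S_0} \frac{\sum_{ij} w_{ij}(x_i - x_j)^2}
#'   {\sum_i (x_i - \bar x)^2}}
#' with null expectation 1 and standard deviation from the
#' normality-assumption moment formula; the two-sided Z test is reported.
#' Values below 1 (negative Z) indicate positive spatial association.
#'
#' @inheritParams morans_i
#' @return Data frame of class `autocorr_test`.
#' @export
gearys_c <- function(x, w) {
  stopifnot(inherits(w, "weight_spec"), length(x) == w$n)
  n <- w$n
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("Geary's c is undefined for constant input")
  W <- w$W
  # sum_ij w_ij (x_i - x_j)^2 = 2 x' (D - W) x with D = diag(row sums)
  num <- 2 * (sum(Matrix::rowSums(W) * xc^2) -
                sum(xc * as.numeric(W %*% xc)))
  obs <- ((n - 1) / (2 * w$S0)) * num / ss
  v <- ((2 * w$S1 + w$S2) * (n - 1) - 4 * w$S0^2) / (2 * (n + 1) * w$S0^2)
  autocorr_result("Geary's c", obs, 1, sqrt(v))
}

autocorr_result <- function(statistic, obs, expd, sd0) {
  z <- (obs - expd) / sd0
  structure(data.frame(statistic = statistic, observed = obs,
                       expected = expd, sd = sd0, Z = z,
                       p = 2 * pnorm(-abs(z)), row.names = NULL),
            class = c("autocorr_test", "data.frame"))
}
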