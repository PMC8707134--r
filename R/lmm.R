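#' Fixed-effects design matrix for a two-way layout
#'
#' Builds the full indicator design `M` (intercept, one column per
#' main-plot level, per sub-plot level and per interaction cell; entries 0/1,
#' first column all ones) together with the reduced full-rank design `X`
#' obtained by the reference-level constraint: the last level of each factor
#' (and any interaction cell involving it) is constrained to zero. With the
#' canonical 2 x 5 layout, `M` is n x 18 and `X` has rank 10. Factors with a
#' single level drop out of the design, down to an intercept-only model.
#'
#' @param data Data frame with character/factor columns `main` and `sub`.
#' @param main_levels,sub_levels Level orderings (default: order of first
#'   appearance in `data`).
#' @return An object of class `fixed_design` with elements `M`, `X`,
#'   `assign` (effect of each reduced column), `main_levels`, `sub_levels`
#'   and `cell_rows` (an a x b x ncol(X) array of reduced-design rows for
#'   each cell mean, used for LS-means).
#' @export
build_fixed_design <- function(data, main_levels = NULL, sub_levels = NULL) {
  stopifnot(all(c("main", "sub") %in% names(data)))
  main_levels <- main_levels %||% unique(as.character(data$main))
  sub_levels <- sub_levels %||% unique(as.character(data$sub))
  if (!all(data$main %in% main_levels))
    stop("unseen main level(s): ",
         paste(setdiff(unique(data$main), main_levels), collapse = ", "))
  if (!all(data$sub %in% sub_levels))
    stop("unseen sub level(s): ",
         paste(setdiff(unique(data$sub), sub_levels), collapse = ", "))
  a <- length(main_levels)
  b <- length(sub_levels)
  n <- nrow(data)
  mi <- match(data$main, main_levels)
  si <- match(data$sub, sub_levels)

  ind <- function(idx, k) {
    m <- matrix(0, n, k)
    m[cbind(seq_len(n), idx)] <- 1
    m
  }
  Mm <- ind(mi, a)
  Ms <- ind(si, b)
  Mint <- ind((mi - 1) * b + si, a * b)
  M <- cbind(1, Mm, Ms, Mint)
  colnames(M) <- c("(Intercept)", paste0("main:", main_levels),
                   paste0("sub:", sub_levels),
                   paste0(rep(main_levels, each = b), ":", rep(sub_levels, a)))

  # reduced design: reference level = last level of each factor
  keep_m <- if (a > 1) seq_len(a - 1) else integer()
  keep_s <- if (b > 1) seq_len(b - 1) else integer()
  X <- cbind(`(Intercept)` = rep(1, n),
             Mm[, keep_m, drop = FALSE],
             Ms[, keep_s, drop = FALSE])
  assign <- c("(Intercept)", rep("main", length(keep_m)),
              rep("sub", length(keep_s)))
  cn <- c("(Intercept)",
          if (length(keep_m)) paste0("main", main_levels[keep_m]),
          if (length(keep_s)) paste0("sub", sub_levels[keep_s]))
  if (a > 1 && b > 1) {
    for (i in keep_m) for (j in keep_s) {
      X <- cbind(X, Mm[, i] * Ms[, j])
      cn <- c(cn, paste0("main", main_levels[i], ":sub", sub_levels[j]))
      assign <- c(assign, "interaction")
    }
  }
  colnames(X) <- cn
  p <- ncol(X)

  cell_rows <- array(0, c(a, b, p), dimnames = list(main_levels, sub_levels, cn))
  for (i in seq_len(a)) for (j in seq_len(b)) {
    r <- numeric(p)
    r[1] <- 1
    for (nm in c(paste0("main", main_levels[i]), paste0("sub", sub_levels[j]),
                 paste0("main", main_levels[i], ":sub", sub_levels[j]))) {
      if (nm %in% cn) r[match(nm, cn)] <- 1
    }
    cell_rows[i, j, ] <- r
  }

  structure(list(M = M, X = X, assign = assign,
                 main_levels = main_levels, sub_levels = sub_levels,
                 cell_rows = cell_rows),
            class = "fixed_design")
}

# restricted log-likelihood machinery ---------------------------------------

# assemble per-group Cholesky-based pieces of the REML criterion
.reml_pieces <- function(models, parts) {
  logdet <- 0
  p <- ncol(parts[[1]]$X)
  A <- matrix(0, p, p)
  bv <- numeric(p)
  q <- 0
  for (g in seq_along(parts)) {
    pt <- parts[[g]]
    C <- .cov_matrix(models[[g]], pt$D)
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdet <- logdet + 2 * sum(log(diag(R)))
    Xi <- backsolve(R, pt$X, transpose = TRUE)
    zi <- backsolve(R, pt$z, transpose = TRUE)
    A <- A + crossprod(Xi)
    bv <- bv + as.vector(crossprod(Xi, zi))
    q <- q + sum(zi^2)
  }
  list(logdet = logdet, A = A, b = bv, q = q)
}

.reml_loglik_from_pieces <- function(pc, n) {
  p <- ncol(pc$A)
  ldA <- determinant(pc$A, logarithm = TRUE)
  if (ldA$sign <= 0) return(NA_real_)
  beta <- solve(pc$A, pc$b)
  quad <- pc$q - sum(pc$b * beta)
  -0.5 * (pc$logdet + as.numeric(ldA$modulus) + quad +
            (n - p) * log(2 * pi))
}

.pack_theta <- function(models, families) {
  unlist(lapply(seq_along(families), function(g) {
    m <- models[[g]]
    if (families[g] == "nugget") log(max(m$nugget, 1e-6))
    else c(log(max(m$nugget, 1e-6)), log(max(m$psill, 1e-6)),
           log(max(m$range, 1e-3)))
  }))
}

.unpack_theta <- function(theta, families) {
  out <- vector("list", length(families))
  k <- 0
  for (g in seq_along(families)) {
    if (families[g] == "nugget") {
      out[[g]] <- variogram_model("nugget", nugget = exp(theta[k + 1]))
      k <- k + 1
    } else {
      out[[g]] <- variogram_model("spherical", nugget = exp(theta[k + 1]),
                                  psill = exp(theta[k + 2]),
                                  range = exp(theta[k + 3]))
      k <- k + 3
    }
  }
  out
}

#' REML fit of the spatial linear mixed model
#'
#' Fits `z = M beta + eps` where the residual vector is a zero-mean Gaussian
#' field with isotropic spherical-with-nugget (or pure-nugget) covariance,
#' by restricted maximum likelihood: the covariance parameters maximize the
#' restricted log-likelihood (bounded quasi-Newton on log-transformed
#' parameters, deterministic multistart from the supplied initialization and
#' two perturbations of it), and the fixed effects are the generalized
#' least-squares estimates at the optimum. With a grouping factor, each
#' group gets its own covariance parameters (and possibly family) and the
#' residual covariance is block-diagonal across groups — cross-group
#' covariance zero — while the fixed effects remain jointly estimated.
#'
#' With a single pure-nugget group the fit is closed-form and coincides with
#' ordinary least squares: `beta = OLS` and `sigma0 = RSS / (n - rank)`.
#'
#' @param z Response vector.
#' @param fd A [build_fixed_design()] result.
#' @param locations Data frame/matrix with columns `x`, `y`.
#' @param family Covariance family: a single string or one per group level
#'   (`"spherical"` or `"nugget"`).
#' @param groups Optional grouping factor (e.g. the main-plot level) for
#'   heteroscedastic, group-specific residual covariance.
#' @param init Initial [variogram_model()] (or named list, one per group),
#'   typically the least-squares variogram fit of the OLS residuals. A
#'   moment-based default is used when omitted.
#' @param reltol Convergence tolerance on the restricted log-likelihood.
#' @param max_iter Iteration cap for the optimizer.
#' @param starts Number of deterministic optimizer starts (1-3): the
#'   initialization itself plus shrunken (x 1/4) and inflated (x 4)
#'   perturbations of it. The default explores all three; simulation loops
#'   with trustworthy initializations can use 1.
#' @return An object of class `lmm_fit`: coefficients `beta` with
#'   covariance `vcov_beta`, per-group residual `models` (with Wald
#'   z-tests), `reml_loglik`, `fitted`, `residuals`, `df_resid`,
#'   `converged`, and the design/group bookkeeping used by
#'   [fixed_effect_f_tests()] and [lsmean_differences()].
#' @export
reml_fit <- function(z, fd, locations, family = "spherical", groups = NULL,
                     init = NULL, reltol = 1e-8, max_iter = 200, starts = 3) {
  stopifnot(inherits(fd, "fixed_design"))
  X <- fd$X
  n <- length(z)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("reduced fixed-effects design is singular")
  xy <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  stopifnot(nrow(xy) == n)

  if (is.null(groups)) groups <- factor(rep("all", n))
  groups <- droplevels(factor(groups))
  glev <- levels(groups)
  nG <- length(glev)
  if (length(family) == 1) family <- setNames(rep(family, nG), glev)
  stopifnot(all(glev %in% names(family)),
            all(family %in% c("spherical", "nugget")))
  family <- family[glev]

  # closed-form iid case
  if (nG == 1 && family[[1]] == "nugget") {
    return(.iid_fit(z, fd, family_label = "nugget", groups = groups,
                    locations = xy))
  }

  parts <- lapply(glev, function(g) {
    idx <- which(groups == g)
    list(idx = idx, X = X[idx, , drop = FALSE], z = z[idx],
         D = as.matrix(dist(xy[idx, , drop = FALSE])))
  })
  names(parts) <- glev
  max_d <- vapply(parts, function(p) max(p$D), numeric(1))

  # initialization: supplied models or moment-based defaults
  if (is.null(init)) {
    init <- lapply(seq_len(nG), function(g) {
      v <- var(parts[[g]]$z)
      if (family[g] == "nugget") variogram_model("nugget", nugget = v)
      else variogram_model("spherical", nugget = 0.7 * v, psill = 0.3 * v,
                           range = max_d[g] / 4)
    })
    names(init) <- glev
  } else if (inherits(init, "variogram_model")) {
    init <- setNames(rep(list(init), nG), glev)
  }
  init <- lapply(seq_len(nG), function(g) {
    m <- init[[glev[g]]]
    if (m$family != family[g]) {
      v <- m$nugget + m$psill
      if (family[g] == "nugget") variogram_model("nugget", nugget = v)
      else variogram_model("spherical", nugget = 0.8 * v, psill = 0.2 * v,
                           range = max_d[g] / 4)
    } else m
  })

  nll <- function(theta) {
    # any numerically infeasible proposal is an (internally) rejected step
    tryCatch({
      pc <- .reml_pieces(.unpack_theta(theta, family), parts)
      if (is.null(pc) || !all(is.finite(pc$A))) return(1e10)
      ll <- .reml_loglik_from_pieces(pc, n)
      if (!is.finite(ll)) return(1e10)
      -ll
    }, error = function(e) 1e10)
  }

  theta0 <- .pack_theta(init, family)
  lower <- rep(log(1e-8), length(theta0))
  upper <- numeric(0)
  for (g in seq_len(nG)) {
    upper <- c(upper, if (family[g] == "nugget") log(1e6)
               else c(log(1e6), log(1e6), log(max_d[g])))
  }
  theta0 <- pmin(pmax(theta0, lower + 0.01), upper - 0.01)

  starts <- head(list(theta0, theta0 + log(0.25), theta0 + log(4)),
                 max(1, starts))
  starts <- lapply(starts, function(s) pmin(pmax(s, lower + 0.01), upper - 0.01))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = max_iter, factr = reltol / 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("REML optimization failed for every start")
  converged <- best$convergence == 0
  if (!converged)
    warning("REML optimizer did not report convergence (code ",
            best$convergence, ")")

  models <- .unpack_theta(best$par, family)
  names(models) <- glev
  pc <- .reml_pieces(models, parts)
  beta <- solve(pc$A, pc$b)
  vcov_beta <- solve(pc$A)
  ll_opt <- .reml_loglik_from_pieces(pc, n)
  ll_init <- -nll(theta0)

  models <- .attach_cov_wald(models, family, nll, best$par, glev)

  fitted <- as.vector(X %*% beta)
  structure(list(beta = setNames(as.vector(beta), colnames(X)),
                 vcov_beta = vcov_beta, models = models,
                 reml_loglik = ll_opt, loglik_init = ll_init,
                 fitted = fitted, residuals = z - fitted,
                 df_resid = n - ncol(X), n = n, fd = fd,
                 groups = groups, locations = xy,
                 method = "REML", converged = converged),
            class = "lmm_fit")
}

# Wald z tests for covariance parameters from a finite-difference Hessian of
# the negative restricted log-likelihood on the natural parameter scale
.attach_cov_wald <- function(models, family, nll_theta, theta_hat, glev) {
  natural <- unlist(lapply(models, function(m)
    if (m$family == "nugget") m$nugget else c(m$nugget, m$psill, m$range)))
  to_theta <- function(nat) {
    # natural -> packed log scale, guarding non-positive proposals
    log(pmax(nat, 1e-10))
  }
  f <- function(nat) nll_theta(to_theta(nat))
  H <- tryCatch(.num_hessian(f, natural), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se_all <- if (is.null(V)) rep(NA_real_, length(natural))
            else sqrt(ifelse(diag(V) > 0, diag(V), NA_real_))
  k <- 0
  for (g in seq_along(models)) {
    m <- models[[g]]
    npar <- if (m$family == "nugget") 1 else 3
    se <- se_all[k + seq_len(npar)]
    k <- k + npar
    est <- if (npar == 1) m$nugget else c(m$nugget, m$psill, m$range)
    zval <- est / se
    models[[g]]$se <- setNames(se, c("nugget", "psill", "range")[seq_len(npar)])
    models[[g]]$fit_table <- data.frame(
      group = glev[g],
      parameter = c("nugget", "psill", "range")[seq_len(npar)],
      estimate = est, se = se, z = zval, p = pnorm(-zval))
  }
  models
}

.num_hessian <- function(f, x, rel = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x) * rel, 1e-7)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      xp <- xm <- x
      xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
      H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    } else {
      xpp <- xpm <- xmp <- xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# closed-form iid (OLS / pure-nugget REML) fit
.iid_fit <- function(z, fd, family_label, groups, locations) {
  X <- fd$X
  n <- length(z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("reduced fixed-effects design is singular")
  beta <- qr.coef(qx, z)
  fitted <- as.vector(X %*% beta)
  rss <- sum((z - fitted)^2)
  p <- ncol(X)
  s0 <- rss / (n - p)
  XtXi <- chol2inv(qr.R(qx))
  m <- variogram_model("nugget", nugget = s0)
  # REML z test for the iid variance: Var(sigma0_hat) = 2 sigma0^2 / (n - p)
  se <- s0 * sqrt(2 / (n - p))
  m$se <- c(nugget = se)
  m$fit_table <- data.frame(group = levels(groups)[1], parameter = "nugget",
                            estimate = s0, se = se, z = s0 / se,
                            p = pnorm(-s0 / se))
  # restricted log-likelihood at the optimum: logdet(Sigma) = n log s0
  ll <- -0.5 * (n * log(s0) +
                  as.numeric(determinant(crossprod(X) / s0)$modulus) +
                  rss / s0 + (n - p) * log(2 * pi))
  structure(list(beta = setNames(as.vector(beta), colnames(X)),
                 vcov_beta = s0 * XtXi,
                 models = setNames(list(m), levels(groups)[1]),
                 reml_loglik = ll, loglik_init = ll,
                 fitted = fitted, residuals = z - fitted,
                 df_resid = n - p, n = n, fd = fd, groups = groups,
                 locations = locations,
                 method = if (family_label == "ols") "OLS" else "REML",
                 converged = TRUE),
            class = "lmm_fit")
}

#' Ordinary least squares comparison fit
#'
#' The classical fit that ignores spatial correlation: `Sigma = sigma^2 I`,
#' `beta` by OLS, `sigma^2 = RSS / (n - rank)`. Shares the F-test and
#' contrast machinery of [reml_fit()], providing the traditional-ANOVA
#' comparison against the spatial model.
#'
#' @inheritParams reml_fit
#' @return An `lmm_fit` (method `"OLS"`).
#' @export
ols_fit <- function(z, fd, locations = NULL) {
  n <- length(z)
  xy <- if (is.null(locations)) matrix(NA_real_, n, 2,
                                       dimnames = list(NULL, c("x", "y")))
        else as.matrix(as.data.frame(locations)[, c("x", "y")])
  .iid_fit(z, fd, family_label = "ols", groups = factor(rep("all", n)),
           locations = xy)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("%s linear mixed model fit: n = %d, %d fixed coefficient(s)\n",
              x$method, x$n, length(x$beta)))
  cat(sprintf("  restricted log-likelihood: %.4f%s\n", x$reml_loglik,
              if (x$converged) "" else " (NOT converged)"))
  for (g in names(x$models)) {
    m <- x$models[[g]]
    cat(sprintf("  residual model [%s]: %s nugget = %.4g", g, m$family,
                m$nugget))
    if (m$family == "spherical")
      cat(sprintf(", psill = %.4g, range = %.4g m", m$psill, m$range))
    cat("\n")
  }
  invisible(x)
}

# LS-mean row vectors -------------------------------------------------------

.lsmean_rows <- function(fd, effect) {
  cr <- fd$cell_rows
  a <- length(fd$main_levels)
  b <- length(fd$sub_levels)
  switch(effect,
    main = {
      rows <- t(vapply(seq_len(a),
                       function(i) colMeans(matrix(cr[i, , ], nrow = b)),
                       numeric(dim(cr)[3])))
      rownames(rows) <- fd$main_levels
      rows
    },
    sub = {
      rows <- t(vapply(seq_len(b), function(j) colMeans(matrix(cr[, j, ], nrow = a)),
                       numeric(dim(cr)[3])))
      rownames(rows) <- fd$sub_levels
      rows
    },
    interaction = {
      rows <- matrix(aperm(cr, c(2, 1, 3)), a * b, dim(cr)[3])
      rownames(rows) <- paste(rep(fd$main_levels, each = b),
                              rep(fd$sub_levels, a), sep = ":")
      rows
    },
    stop("unknown effect: ", effect))
}

#' Wald F tests of the fixed effects
#'
#' One F test per fixed effect (main, sub, interaction): the main and
#' sub-plot effects are tested through contrasts of their least-squares
#' means (averaging over the other factor), the interaction through its
#' reduced-design coefficients; both are Wald quadratic forms in the GLS
#' coefficient covariance. The denominator degrees of freedom are the
#' residual df, `n - rank(X)`.
#'
#' @param fit An `lmm_fit`.
#' @return Data frame with columns `effect`, `df1`, `df2`, `F`, `p` (empty
#'   for an intercept-only design).
#' @export
fixed_effect_f_tests <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fd <- fit$fd
  a <- length(fd$main_levels)
  b <- length(fd$sub_levels)
  out <- list()
  wald <- function(L, label) {
    q <- nrow(L)
    est <- L %*% fit$beta
    Fv <- as.numeric(crossprod(est, solve(L %*% fit$vcov_beta %*% t(L), est))) / q
    data.frame(effect = label, df1 = q, df2 = fit$df_resid, F = Fv,
               p = pf(Fv, q, fit$df_resid, lower.tail = FALSE))
  }
  if (a > 1) {
    lm_rows <- .lsmean_rows(fd, "main")
    L <- lm_rows[-a, , drop = FALSE] -
      matrix(lm_rows[a, ], a - 1, ncol(lm_rows), byrow = TRUE)
    out$main <- wald(L, "main")
  }
  if (b > 1) {
    ls_rows <- .lsmean_rows(fd, "sub")
    L <- ls_rows[-b, , drop = FALSE] -
      matrix(ls_rows[b, ], b - 1, ncol(ls_rows), byrow = TRUE)
    out$sub <- wald(L, "sub")
  }
  if (a > 1 && b > 1) {
    sel <- which(fd$assign == "interaction")
    L <- matrix(0, length(sel), length(fit$beta))
    L[cbind(seq_along(sel), sel)] <- 1
    out$interaction <- wald(L, "interaction")
  }
  if (length(out) == 0)
    return(data.frame(effect = character(), df1 = integer(), df2 = integer(),
                      F = numeric(), p = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pairwise least-squares-mean differences
#'
#' All pairwise differences between the LS-means of an effect's levels (or
#' of the interaction cells): estimate `L' beta`, standard error
#' `sqrt(L' Cov(beta) L)`, t statistic with residual df, two-sided p. The
#' full table is returned with a `significant` flag at `alpha`.
#'
#' @param fit An `lmm_fit`.
#' @param which `"main"`, `"sub"` or `"interaction"`.
#' @param alpha Significance flag level.
#' @return Data frame with columns `effect`, `level1`, `level2`,
#'   `estimate`, `se`, `t`, `df`, `p`, `significant`.
#' @export
lsmean_differences <- function(fit, which = c("main", "sub", "interaction"),
                               alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  which <- match.arg(which)
  fd <- fit$fd
  k <- switch(which, main = length(fd$main_levels),
              sub = length(fd$sub_levels),
              interaction = length(fd$main_levels) * length(fd$sub_levels))
  if (k < 2) stop("effect '", which, "' has fewer than 2 levels")
  rows <- .lsmean_rows(fd, which)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    L <- rows[i, ] - rows[j, ]
    est <- sum(L * fit$beta)
    se <- sqrt(as.numeric(t(L) %*% fit$vcov_beta %*% L))
    tval <- est / se
    data.frame(effect = which, level1 = rownames(rows)[i],
               level2 = rownames(rows)[j], estimate = est, se = se,
               t = tval, df = fit$df_resid,
               p = 2 * pt(-abs(tval), fit$df_resid))
  })
  out <- do.call(rbind, out)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
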