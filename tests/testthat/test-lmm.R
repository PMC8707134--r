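test_that("the fixed design has the documented indicator structure", {
  d <- generate_design(seed = 1)
  fd <- build_fixed_design(d$spots)
  expect_equal(dim(fd$M), c(480, 18))
  expect_true(all(fd$M %in% c(0, 1)))
  expect_true(all(fd$M[, 1] == 1))
  expect_equal(dim(fd$X), c(480, 10))
  expect_equal(qr(fd$X)$rank, 10)
  # balanced column sums: 240 per main level, 96 per sub level
  expect_true(all(colSums(fd$M[, 2:3]) == 240))
  expect_true(all(colSums(fd$M[, 4:8]) == 96))
  expect_error(build_fixed_design(data.frame(main = "A", sub = "B"),
                                  main_levels = "Z", sub_levels = "B"),
               "unseen")
  # degenerate single-treatment design: intercept only
  fd0 <- build_fixed_design(data.frame(main = rep("NO", 4),
                                       sub = rep("CTR", 4)))
  expect_equal(ncol(fd0$X), 1)
})

test_that("REML under a single nugget group is exactly OLS / classical ANOVA", {
  tr <- simulate_trial(seed = 21, n_blocks = 2)
  lat <- tr$latents
  fd <- build_fixed_design(lat)
  xy <- lat[, c("x", "y")]
  o <- ols_fit(lat$vis, fd, xy)
  r <- reml_fit(lat$vis, fd, xy, family = "nugget")
  expect_equal(r$beta, o$beta, tolerance = 1e-8)
  expect_equal(r$models[[1]]$nugget,
               sum(o$residuals^2) / (nrow(lat) - ncol(fd$X)),
               tolerance = 1e-10)
  # F table equals the classical two-way ANOVA on this balanced design
  a <- anova(lm(z ~ main * sub, data = transform(lat, z = vis)))
  f <- fixed_effect_f_tests(o)
  expect_equal(f$F[f$effect == "main"], a["main", "F value"],
               tolerance = 1e-8)
  expect_equal(f$F[f$effect == "sub"], a["sub", "F value"], tolerance = 1e-8)
  expect_equal(f$F[f$effect == "interaction"], a["main:sub", "F value"],
               tolerance = 1e-8)
  expect_equal(f$df2, rep(a["Residuals", "Df"], 3))
})

test_that("contrasts match emmeans on the OLS fit and are antisymmetric", {
  tr <- simulate_trial(seed = 22, n_blocks = 2)
  lat <- transform(tr$latents, z = swir)
  fd <- build_fixed_design(lat)
  o <- ols_fit(lat$z, fd, lat[, c("x", "y")])
  ours <- lsmean_differences(o, "sub")
  em <- as.data.frame(pairs(emmeans::emmeans(lm(z ~ main * sub, data = lat),
                                             "sub"), adjust = "none"))
  em_key <- gsub(" - ", " ", em$contrast)
  m1 <- match(paste(ours$level1, ours$level2), em_key)
  m2 <- match(paste(ours$level2, ours$level1), em_key)
  idx <- ifelse(is.na(m1), m2, m1)
  sgn <- ifelse(is.na(m1), -1, 1)
  expect_false(anyNA(idx))
  expect_equal(ours$estimate, sgn * em$estimate[idx], tolerance = 1e-8)
  expect_equal(ours$se, em$SE[idx], tolerance = 1e-8)
  expect_equal(ours$p, em$p.value[idx], tolerance = 1e-8)
  # antisymmetry through level reordering
  fd2 <- build_fixed_design(lat, main_levels = rev(unique(lat$main)),
                            sub_levels = unique(lat$sub))
  o2 <- ols_fit(lat$z, fd2, lat[, c("x", "y")])
  a1 <- lsmean_differences(o, "main")
  a2 <- lsmean_differences(o2, "main")
  expect_equal(a1$estimate, -a2$estimate, tolerance = 1e-8)
  expect_equal(a1$se, a2$se, tolerance = 1e-8)
})

test_that("a two-group iid contrast reproduces the pooled two-sample t test", {
  d <- generate_design(n_blocks = 2, main_levels = c("NO", "YES"),
                       sub_levels = "CTR", seed = 3)
  z <- withr::with_seed(30, rnorm(nrow(d$spots)) +
                          0.3 * (d$spots$main == "YES"))
  fd <- build_fixed_design(d$spots)
  o <- ols_fit(z, fd, d$spots[, c("x", "y")])
  ct <- lsmean_differences(o, "main")
  tt <- t.test(z[d$spots$main == "NO"], z[d$spots$main == "YES"],
               var.equal = TRUE)
  expect_equal(ct$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_equal(abs(ct$t), unname(abs(tt$statistic)), tolerance = 1e-10)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
})

test_that("REML estimates are invariant to row permutation", {
  tr <- simulate_trial(seed = 23, n_blocks = 2)
  lat <- tr$latents
  perm <- withr::with_seed(8, sample(nrow(lat)))
  fd <- build_fixed_design(lat)
  fdp <- build_fixed_design(lat[perm, ], main_levels = fd$main_levels,
                            sub_levels = fd$sub_levels)
  f1 <- reml_fit(lat$swir, fd, lat[, c("x", "y")], family = "spherical",
                 starts = 1)
  f2 <- reml_fit(lat$swir[perm], fdp, lat[perm, c("x", "y")],
                 family = "spherical", starts = 1)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-8)
  expect_equal(f1$models[[1]]$range, f2$models[[1]]$range, tolerance = 1e-4)
})

test_that("the spatial REML fit attains at least the nlme::gls optimum", {
  d <- reduced_design(seed = 9)
  truth <- variogram_model("spherical", nugget = 0.2, psill = 0.2, range = 4)
  spec <- effect_spec(main = c(NO = 0.2, YES = -0.2),
                      sub = c(TRI = 0, LAM = 0, CER = 0, CHE = 0.2,
                              CTR = -0.2),
                      residual = truth)
  dat <- compose_response(d, spec, seed = 44)
  fd <- build_fixed_design(dat)
  fit <- reml_fit(dat$z, fd, dat[, c("x", "y")], family = "spherical")
  g <- nlme::gls(z ~ main * sub, data = dat,
                 correlation = nlme::corSpher(form = ~ x + y, nugget = TRUE),
                 method = "REML")
  # evaluate our restricted likelihood at the gls covariance estimate
  cs <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  s2 <- g$sigma^2
  gls_model <- variogram_model("spherical",
                               nugget = s2 * cs[["nugget"]],
                               psill = s2 * (1 - cs[["nugget"]]),
                               range = cs[["range"]])
  ll_at_gls <- spatspec:::.reml_loglik_from_pieces(
    spatspec:::.reml_pieces(list(gls_model),
                            list(list(X = fd$X, z = dat$z,
                                      D = as.matrix(dist(dat[, c("x", "y")]))))),
    nrow(dat))
  expect_gte(fit$reml_loglik, ll_at_gls - 1e-4)
  # covariance parameters land near the generating model
  m <- fit$models[[1]]
  expect_equal(m$nugget, 0.2, tolerance = 0.5)
  expect_equal(m$psill, 0.2, tolerance = 0.5)
  expect_equal(m$range, 4, tolerance = 0.5)
  # the main-effect contrast sits within sampling error of the truth (0.4)
  ct <- lsmean_differences(fit, "main")
  expect_lt(abs(ct$estimate - 0.4), 3 * ct$se)
})

test_that("grouped REML recovers heteroscedastic ground truth structure", {
  d <- generate_design(seed = 13)
  spec <- default_latent_specs()$swir
  dat <- compose_response(d, spec, seed = 91)
  fd <- build_fixed_design(dat)
  fit <- reml_fit(dat$z, fd, dat[, c("x", "y")],
                  family = c(NO = "nugget", YES = "spherical"),
                  groups = dat$main, starts = 1)
  expect_named(fit$models, c("NO", "YES"))
  expect_equal(fit$models$NO$family, "nugget")
  expect_equal(fit$models$YES$family, "spherical")
  expect_equal(fit$models$NO$nugget, 0.259, tolerance = 0.35)
  expect_equal(fit$models$YES$nugget, 0.256, tolerance = 0.35)
  # restricted log-likelihood did not decrease from the initialization
  expect_gte(fit$reml_loglik, fit$loglik_init - 1e-6)
  # Wald table is populated
  rt <- do.call(rbind, lapply(fit$models, `[[`, "fit_table"))
  expect_true(all(is.finite(rt$estimate)))
  expect_true(all(c("group", "parameter", "estimate", "se", "z", "p")
                  %in% names(rt)))
})

test_that("intercept-only fits degrade gracefully", {
  d <- generate_design(n_blocks = 1, main_levels = "NO", sub_levels = "CTR",
                       seed = 2)
  z <- withr::with_seed(14, rnorm(12, mean = 3))
  fd <- build_fixed_design(d$spots)
  o <- ols_fit(z, fd, d$spots[, c("x", "y")])
  expect_equal(unname(o$beta), mean(z))
  expect_equal(nrow(fixed_effect_f_tests(o)), 0)
})
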