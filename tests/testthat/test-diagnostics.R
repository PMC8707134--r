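test_that("Blom scores match hand-evaluated normal quantiles", {
  expect_equal(blom_transform(5)$y, 0)
  x5 <- c(3, 1, 4, 1.5, 2)
  b <- blom_transform(x5)
  expect_equal(b$n, 5)
  expect_equal(b$y[x5 == 2.0], 0)                       # median rank 3
  expect_equal(b$y[x5 == 4], qnorm(4.625 / 5.25))       # max rank 5
  expect_equal(qnorm(4.625 / 5.25), 1.1798, tolerance = 1e-4)
  # ties get average ranks
  bt <- blom_transform(c(1, 2, 2, 3))
  expect_equal(bt$r, c(1, 2.5, 2.5, 4))
  expect_equal(bt$y[2], bt$y[3])
  # strictly monotone on tie-free input
  xs <- withr::with_seed(1, rnorm(50))
  expect_equal(order(blom_transform(xs)$y), order(xs))
  # rank-idempotent: transforming twice preserves the ordering and ranks
  expect_equal(blom_transform(blom_transform(xs)$y)$r, blom_transform(xs)$r)
})

test_that("normality tests are calibrated, powered, and scale-invariant", {
  rejections <- vapply(1:200, function(s) {
    x <- withr::with_seed(7000 + s, rnorm(480))
    normality_tests(x)$p < 0.05
  }, logical(3))
  rates <- rowMeans(rejections)
  expect_true(all(rates >= 0.01 & rates <= 0.10))
  # left-skewed samples at skewness ~ -1.2 are rejected decisively
  hits <- vapply(1:30, function(s) {
    all(normality_tests(skewed_sample(480, 8000 + s))$p < 0.01)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # location-scale invariance of the statistics
  x <- withr::with_seed(3, rnorm(100))
  expect_equal(normality_tests(x)$statistic,
               normality_tests(5 + 2.5 * x)$statistic, tolerance = 1e-12)
  expect_error(normality_tests(rep(1, 50)), "constant")
  expect_error(normality_tests(rnorm(5)), "n >= 8")
})

test_that("Levene's test matches its definition and an independent implementation", {
  # two identical groups: F exactly 0
  x <- c(1, 3, 7, 2, 1, 3, 7, 2)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(levene_test(x, g)$F, 0)
  # cross-check against car's mean-centered Levene test
  y <- withr::with_seed(2, c(rnorm(40, sd = 1), rnorm(40, sd = 2)))
  gg <- rep(c("a", "b"), each = 40)
  ours <- levene_test(y, gg)
  cc <- car::leveneTest(y ~ factor(gg), center = mean)
  expect_equal(ours$F, cc$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, cc$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(ours$df1, 1)
  expect_equal(ours$df2, 78)
  # power: variance ratio 4 at n = 240 per group is detected
  hits <- vapply(1:25, function(s) {
    z <- withr::with_seed(9000 + s, c(rnorm(240), rnorm(240, sd = 2)))
    levene_test(z, rep(1:2, each = 240))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(levene_test(1:5, c(1, 1, 1, 1, 2)), "< 2 observations")
})

test_that("weight matrices encode cutoff neighborhoods exactly", {
  # 2 points at distance 1, cutoff 2: S0 = 2
  w2 <- build_weight_matrix(data.frame(x = c(0, 1), y = 0), "binary", 2)
  expect_equal(w2$S0, 2)
  # 6 x 2 grid at 0.5 m, cutoff 0.5: rook adjacency, 16 edges
  g <- expand.grid(x = (0:5) * 0.5, y = (0:1) * 0.5)
  wg <- build_weight_matrix(g, "binary", 0.5)
  deg <- Matrix::rowSums(wg$W)
  expect_equal(sum(deg), 2 * 16)
  expect_true(all(deg >= 2 & deg <= 3))
  # inverse-distance weights
  wi <- build_weight_matrix(data.frame(x = c(0, 2), y = 0), "inverse", 2)
  expect_equal(wi$S0, 1)
  # isolated point rejected
  expect_error(build_weight_matrix(data.frame(x = c(0, 1, 10), y = 0),
                                   "binary", 2), "without neighbors")
})

test_that("Moran's I and Geary's c match brute-force double sums", {
  xy <- withr::with_seed(4, data.frame(x = runif(40, 0, 5),
                                       y = runif(40, 0, 5)))
  w <- build_weight_matrix(xy, "binary", 2)
  Wd <- as.matrix(w$W)
  for (s in 1:3) {
    x <- withr::with_seed(100 + s, rnorm(40))
    expect_equal(morans_i(x, w)$observed, moran_brute(x, Wd),
                 tolerance = 1e-12)
    expect_equal(gearys_c(x, w)$observed, geary_brute(x, Wd),
                 tolerance = 1e-12)
  }
  # observed I agrees with an independent implementation on an equal-degree
  # graph (where row-standardization only rescales all weights uniformly)
  ring <- data.frame(x = cos(2 * pi * (1:24) / 24),
                     y = sin(2 * pi * (1:24) / 24))
  wr <- build_weight_matrix(ring, "binary", 0.27)
  expect_true(all(Matrix::rowSums(wr$W) == 2))
  xr <- withr::with_seed(9, rnorm(24))
  ref <- ape::Moran.I(xr, as.matrix(wr$W))
  mi <- morans_i(xr, wr)
  expect_equal(mi$observed, ref$observed, tolerance = 1e-10)
  expect_equal(mi$expected, ref$expected, tolerance = 1e-12)
})

test_that("null moments and directions of the autocorrelation tests are right", {
  d <- generate_design(seed = 1)
  w <- build_weight_matrix(d$spots, "binary", 1.0)
  x <- withr::with_seed(5, rnorm(480))
  mi <- morans_i(x, w)
  expect_equal(mi$expected, -1 / 479)
  expect_equal(mi$Z, (mi$observed - mi$expected) / mi$sd)
  gc <- gearys_c(x, w)
  expect_equal(gc$expected, 1)
  # perfect checkerboard on a 4x4 rook lattice: I = -1
  cb <- expand.grid(x = 1:4, y = 1:4)
  wcb <- build_weight_matrix(cb, "binary", 1)
  z <- (-1)^(cb$x + cb$y)
  expect_equal(morans_i(z, wcb)$observed, moran_brute(z, as.matrix(wcb$W)),
               tolerance = 1e-12)
  expect_equal(morans_i(z, wcb)$observed, -1, tolerance = 1e-12)
  # iid calibration of Geary's c
  cbar <- mean(vapply(1:200, function(s) {
    gearys_c(withr::with_seed(300 + s, rnorm(480)), w)$observed
  }, numeric(1)))
  expect_gt(cbar, 0.97)
  expect_lt(cbar, 1.03)
  # smooth gradient: positive association, c < 1, negative Z
  grad <- d$spots$x + d$spots$y
  gg <- gearys_c(grad, w)
  expect_lt(gg$observed, 1)
  expect_lt(gg$Z, 0)
  expect_error(morans_i(rep(2, 480), w), "constant")
})

test_that("structured fields push Moran and Geary in opposite directions", {
  d <- generate_design(seed = 2)
  w <- build_weight_matrix(d$spots, "binary", 1.0)
  m <- variogram_model("spherical", nugget = 0.376, psill = 0.053,
                       range = 6.41)
  f <- simulate_spatial_field(d$spots, m, seed = 77, n = 40)
  dir_ok <- vapply(1:40, function(r) {
    morans_i(f[, r], w)$Z > 0 && gearys_c(f[, r], w)$Z < 0
  }, logical(1))
  expect_gte(mean(dir_ok), 0.9)
})
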