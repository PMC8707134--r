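# shared fixtures and brute-force oracles

# a small single-block design (10 plots, 120 spots) for fast LMM tests
small_design <- function(seed = 1) generate_design(n_blocks = 1, seed = seed)

# a reduced two-block design (20 plots, 120 spots at 6 spots/plot) for
# calibration loops
reduced_design <- function(seed = 1) {
  generate_design(n_blocks = 2, spots_per_plot = 6, seed = seed)
}

# spectrum set with arbitrary reflectance rows on the full 1-nm grid
full_grid_set <- function(rows) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  meta <- data.frame(spot = seq_len(n), plot = 1L, block = 1L,
                     main = "NO", sub = "TRI", x = seq_len(n), y = 0)
  spectrum_set(350:2500, rows, meta)
}

# O(n^2) double-sum oracles for the spatial statistics
moran_brute <- function(x, W) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

geary_brute <- function(x, W) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(W))) * num / sum((x - mean(x))^2)
}

# all-pairs empirical semivariogram oracle
variogram_brute <- function(values, xy, lag_width, max_dist) {
  n <- length(values)
  lag_id <- num <- cnt <- c()
  acc <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (h <= 0 || h > max_dist) next
    k <- ceiling(h / lag_width - 1e-12)
    key <- as.character(k)
    if (is.null(acc[[key]])) acc[[key]] <- c(0, 0, 0)
    acc[[key]] <- acc[[key]] + c((values[i] - values[j])^2, 1, h)
  }
  ks <- sort(as.numeric(names(acc)))
  data.frame(lag = vapply(as.character(ks), function(k) acc[[k]][3] / acc[[k]][2], 0),
             gamma = vapply(as.character(ks), function(k) acc[[k]][1] / (2 * acc[[k]][2]), 0),
             n_pairs = vapply(as.character(ks), function(k) acc[[k]][2], 0),
             row.names = NULL)
}

# left-skewed iid sample with skewness about -1.2 (reflected lognormal)
skewed_sample <- function(n, seed) {
  withr::with_seed(seed, {
    e <- rnorm(n)
    y <- -(exp(sqrt(0.1302) * e) - exp(0.1302 / 2))
    as.vector(scale(y))
  })
}
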