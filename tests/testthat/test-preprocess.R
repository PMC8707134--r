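wl_full <- 350:2500

test_that("spectra CSV round-trips and validates its header", {
  tr <- simulate_trial(seed = 2, n_blocks = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(tr$spectra, path)
  s <- read_spectra_csv(path)
  expect_equal(s$wavelengths, tr$spectra$wavelengths)
  expect_equal(s$reflectance, tr$spectra$reflectance, tolerance = 1e-12)
  expect_equal(s$meta$plot, tr$spectra$meta$plot)

  # single-spot file is valid
  one <- spectrum_set(wl_full, tr$spectra$reflectance[1, , drop = FALSE],
                      tr$spectra$meta[1, ])
  path1 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(one, path1)
  expect_equal(nrow(read_spectra_csv(path1)$reflectance), 1)

  # shuffled wavelength header is rejected
  lines <- readLines(path1)
  hdr <- strsplit(lines[1], ",")[[1]]
  hdr[c(8, 9)] <- hdr[c(9, 8)]
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(hdr, collapse = ","), lines[-1]), path2)
  expect_error(read_spectra_csv(path2), "increasing")
})

test_that("splice correction removes constructed detector steps", {
  base <- 0.2 + (wl_full - 350) * 1e-4 # linear spectrum
  stepped <- base + 0.05 * (wl_full >= 1000) - 0.02 * (wl_full >= 1800)
  s <- full_grid_set(rbind(base, stepped))
  out <- splice_correct(s)
  # already-continuous row unchanged; stepped row restored to the line
  expect_lt(max(abs(out$reflectance[1, ] - base)), 1e-9)
  expect_lt(max(abs(out$reflectance[2, ] - base)), 1e-9)
})

test_that("splice correction is local to the segments beyond each boundary", {
  base <- 0.2 + (wl_full - 350) * 1e-4
  stepped <- base + 0.05 * (wl_full >= 1800)
  out <- splice_correct(full_grid_set(rbind(stepped)))
  seg12 <- wl_full < 1800
  expect_equal(out$reflectance[1, seg12], stepped[seg12])
  expect_error(splice_correct(full_grid_set(rbind(base)), boundaries = 1000.5),
               "not on the wavelength grid")
})

test_that("10-nm binning has exactly 215 bins with closed-form means", {
  s <- full_grid_set(rbind(rep(0.3, 2151), wl_full / 10000))
  b <- bin_to_10nm(s)
  expect_length(b$wavelengths, 215)
  expect_equal(b$reflectance[1, ], rep(0.3, 215))
  # reflectance == wavelength/10000 -> bin value = mean member wavelength/1e4
  expect_equal(b$reflectance[2, ], b$wavelengths / 10000, tolerance = 1e-12)
  # last bin folds 2500 nm in: mean(2490..2500) = 2495
  expect_equal(b$wavelengths[215], 2495)
  expect_equal(b$wavelengths[1:214], 354.5 + 10 * (0:213))
  # grand-mean conservation over the full bins
  expect_equal(mean(b$reflectance[2, 1:214]), mean((350:2489) / 10000))
  # non-1-nm grids are rejected
  sub <- spectrum_set(seq(350, 2500, 2), s$reflectance[, seq(1, 2151, 2)],
                      s$meta)
  expect_error(bin_to_10nm(sub), "1-nm grid")
})

test_that("MSC inverts additive/multiplicative distortion and is idempotent", {
  tr <- simulate_trial(seed = 3, n_blocks = 1)
  s <- bin_to_10nm(tr$spectra)
  ref <- colMeans(s$reflectance)
  distorted <- s
  distorted$reflectance[1, ] <- ref               # row equal to the reference
  distorted$reflectance[2, ] <- 0.1 + 2 * ref     # known (a, b)
  out <- msc_correct(distorted, reference = ref)
  expect_equal(out$reflectance[1, ], ref, tolerance = 1e-10)
  expect_equal(out$reflectance[2, ], ref, tolerance = 1e-10)
  # idempotence under a fixed reference
  once <- msc_correct(s, reference = ref)
  twice <- msc_correct(once, reference = ref)
  expect_equal(once$reflectance, twice$reflectance, tolerance = 1e-8)
  # degenerate slope rejected
  flat <- s
  flat$reflectance[3, ] <- 0.5
  expect_error(msc_correct(flat, reference = ref), "degenerate")
})

test_that("Savitzky-Golay reproduces polynomials exactly, edges included", {
  tr <- simulate_trial(seed = 5, n_blocks = 1)
  s <- bin_to_10nm(tr$spectra)
  # polynomial in band index (the smoother's abscissa)
  wlc <- (seq_along(s$wavelengths) - 107) / 100
  s$reflectance[1, ] <- 0.4 + 0.1 * wlc - 0.2 * wlc^2
  s$reflectance[2, ] <- 0.25
  out <- savitzky_golay(s, w = 11, order = 2)
  expect_equal(out$reflectance[1, ], s$reflectance[1, ], tolerance = 1e-10)
  expect_equal(out$reflectance[2, ], s$reflectance[2, ], tolerance = 1e-12)
  expect_error(savitzky_golay(s, w = 10), "odd")
})

test_that("Savitzky-Golay shrinks white-noise variance by the kernel factor", {
  # interior smoothing factor = sum of squared kernel weights
  half <- 5
  A <- outer(-half:half, 0:2, `^`)
  kernel <- (A %*% solve(crossprod(A)))[, 1]
  shrink <- sum(kernel^2)
  meta1 <- data.frame(spot = 1, plot = 1, block = 1, main = "NO", sub = "T",
                      x = 0, y = 0)
  ratios <- vapply(1:50, function(sd_seed) {
    x <- withr::with_seed(sd_seed, 0.5 + 0.05 * rnorm(215))
    s <- spectrum_set(1:215 * 10, rbind(x), meta1)
    sm <- savitzky_golay(s, 11, 2)$reflectance[1, 11:205]
    var(sm) / var(x[11:205])
  }, numeric(1))
  expect_equal(mean(ratios), shrink, tolerance = 0.1)
})

test_that("preprocessing operators are row-independent", {
  tr <- simulate_trial(seed = 6, n_blocks = 1)
  s <- tr$spectra
  perm <- withr::with_seed(1, sample(nrow(s$reflectance)))
  sp <- s
  sp$reflectance <- s$reflectance[perm, ]
  sp$meta <- s$meta[perm, ]
  rownames(sp$meta) <- NULL
  for (op in list(function(z) splice_correct(z),
                  function(z) bin_to_10nm(z),
                  function(z) savitzky_golay(bin_to_10nm(z)))) {
    a <- op(s)$reflectance[perm, ]
    b <- op(sp)$reflectance
    expect_equal(a, b, tolerance = 1e-12)
  }
})
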