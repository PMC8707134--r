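#' Simulate a zero-mean Gaussian random field with a given variogram model
#'
#' Draws exact realizations of a stationary Gaussian field at arbitrary
#' locations by Cholesky factorization of the full n x n covariance matrix
#' implied by the model (no approximation). The nugget contributes to the
#' covariance only at exactly zero distance, so coincident locations are
#' required to be absent.
#'
#' @param locations Data frame or matrix with columns/metres `x`, `y`.
#' @param model A [variogram_model()].
#' @param seed Integer seed for the draw (applied locally; the global RNG
#'   state is untouched).
#' @param n Number of independent replicate draws.
#' @return A numeric vector (if `n = 1`) or a `nrow(locations) x n` matrix.
#' @export
simulate_spatial_field <- function(locations, model, seed = 1L, n = 1L) {
  xy <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  stopifnot(inherits(model, "variogram_model"), n >= 1)
  nl <- nrow(xy)
  sill <- model$nugget + model$psill
  z <- withr::with_seed(seed, matrix(rnorm(nl * n), nl, n))
  if (sill == 0) {
    out <- matrix(0, nl, n)
  } else if (model$family == "nugget" || model$psill == 0) {
    out <- sqrt(model$nugget) * z
  } else {
    C <- .cov_matrix(model, as.matrix(dist(xy)))
    R <- tryCatch(chol(C), error = function(e) {
      stop("covariance matrix is not positive definite for this model (",
           conditionMessage(e), ")", call. = FALSE)
    })
    out <- crossprod(R, z)
  }
  if (n == 1L) drop(out) else out
}

#' Fixed-effect specification for synthetic trial responses
#'
#' Describes the true mean structure and residual spatial model used by
#' [compose_response()]: a grand mean plus sum-to-zero adjustments for the
#' main-plot factor, the sub-plot factor and their interaction, and a
#' residual [variogram_model()] (optionally one per main-plot level, giving
#' group-wise heteroscedastic residuals).
#'
#' @param grand_mean Overall mean.
#' @param main Named numeric vector of main-level adjustments, summing to 0.
#' @param sub Named numeric vector of sub-level adjustments, summing to 0.
#' @param interaction Optional main x sub matrix (dimnames matching the
#'   levels) of interaction adjustments; every row and column must sum to 0.
#' @param residual A `variogram_model`, or a named list of one model per main
#'   level.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(grand_mean = 0, main, sub, interaction = NULL,
                        residual) {
  stopifnot(!is.null(names(main)), !is.null(names(sub)))
  check_sum0 <- function(v, what) {
    if (abs(sum(v)) > 1e-8)
      stop(what, " adjustments must sum to zero (got sum = ", sum(v), ")")
  }
  check_sum0(main, "main-effect")
  check_sum0(sub, "sub-effect")
  if (is.null(interaction)) {
    interaction <- matrix(0, length(main), length(sub),
                          dimnames = list(names(main), names(sub)))
  } else {
    stopifnot(is.matrix(interaction),
              identical(rownames(interaction), names(main)),
              identical(colnames(interaction), names(sub)))
    for (i in seq_len(nrow(interaction))) check_sum0(interaction[i, ], "interaction row")
    for (j in seq_len(ncol(interaction))) check_sum0(interaction[, j], "interaction column")
  }
  if (inherits(residual, "variogram_model")) {
    residual <- list(residual)
  } else {
    stopifnot(is.list(residual), !is.null(names(residual)),
              all(names(residual) %in% names(main)),
              all(vapply(residual, inherits, TRUE, "variogram_model")))
  }
  structure(list(grand_mean = grand_mean, main = main, sub = sub,
                 interaction = interaction, residual = residual),
            class = "effect_spec")
}

#' Compose a per-spot response from a design, an effect spec and a field draw
#'
#' Builds the response `z = grand mean + main + sub + interaction + field`
#' for every spot of a trial design, drawing the residual field from the
#' spec's variogram model (per main-plot group when the spec carries one
#' model per level; group fields are independent). The true coefficients and
#' residual models are attached as the `"truth"` attribute for recovery
#' tests.
#'
#' @param design A [generate_design()] result.
#' @param spec An [effect_spec()].
#' @param seed Integer seed for the field draw.
#' @param residual_transform Optional function applied to each group's
#'   residual field draw before it is added to the mean (e.g. a skewing
#'   transform); it must preserve zero mean.
#' @return A data frame (the design's spots plus a `z` column) with
#'   attribute `truth`.
#' @export
compose_response <- function(design, spec, seed = 1L,
                             residual_transform = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "effect_spec"))
  sp <- design$spots
  if (!all(design$main_levels %in% names(spec$main)))
    stop("effect spec is missing main levels: ",
         paste(setdiff(design$main_levels, names(spec$main)), collapse = ", "))
  if (!all(design$sub_levels %in% names(spec$sub)))
    stop("effect spec is missing sub levels: ",
         paste(setdiff(design$sub_levels, names(spec$sub)), collapse = ", "))

  mu <- spec$grand_mean + spec$main[sp$main] + spec$sub[sp$sub] +
    spec$interaction[cbind(sp$main, sp$sub)]

  res <- spec$residual
  eps <- numeric(nrow(sp))
  if (is.null(names(res))) {
    eps <- simulate_spatial_field(sp[, c("x", "y")], res[[1]], seed = seed)
  } else {
    for (g in seq_along(res)) {
      idx <- sp$main == names(res)[g]
      eps[idx] <- simulate_spatial_field(sp[idx, c("x", "y")], res[[g]],
                                         seed = seed + g - 1L)
    }
  }
  if (!is.null(residual_transform)) eps <- residual_transform(eps)
  sp$z <- as.numeric(mu + eps)
  attr(sp, "truth") <- spec
  sp
}

# smooth windows and bumps used by the spectral synthesizer
.gauss <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)
.window <- function(wl, lo, hi, edge) plogis((wl - lo) / edge) * plogis((hi - wl) / edge)

#' Latent loading shapes of the spectral synthesizer
#'
#' Three smooth, unit-peak loading shapes on the 1-nm wavelength grid, each
#' covering one spectral region so that together they span 350-2500 nm:
#' a SWIR shape with water-absorption bumps near 1450, 1885 and 1940 nm and
#' secondary bumps near 2080 and 2365 nm; a NIR plateau over 715-1375 nm;
#' and a VIS shape with pigment-related bumps at 495 and 650 nm. Each shape
#' keeps a floor amplitude across its region so every band carries latent
#' signal.
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @return Matrix with columns `swir`, `nir`, `vis`.
#' @export
latent_shapes <- function(wavelengths = 350:2500) {
  wl <- wavelengths
  swir_bumps <- .gauss(wl, 1450, 35) + 0.9 * .gauss(wl, 1885, 30) +
    0.9 * .gauss(wl, 1940, 30) + 0.6 * .gauss(wl, 2080, 40) +
    0.5 * .gauss(wl, 2365, 35)
  swir <- .window(wl, 1375, 2520, 30) * (0.35 + 0.65 * swir_bumps / max(swir_bumps))
  nir <- .window(wl, 705, 1385, 25)
  vis_bumps <- .gauss(wl, 495, 45) + .gauss(wl, 650, 45)
  vis <- .window(wl, 330, 715, 20) * (0.35 + 0.65 * vis_bumps / max(vis_bumps))
  cbind(swir = swir, nir = nir, vis = vis)
}

#' Baseline leaf reflectance spectrum
#'
#' A smooth vegetation-like reflectance curve on \[0, 1\]: low visible
#' reflectance with a green bump at 550 nm, a sharp red-edge rise near
#' 715 nm, a NIR plateau, and SWIR decline with water absorption dips near
#' 1450 and 1940 nm.
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @return Numeric vector of reflectances.
#' @export
base_spectrum <- function(wavelengths = 350:2500) {
  wl <- wavelengths
  0.05 + 0.04 * .gauss(wl, 550, 30) +
    0.40 * plogis((wl - 715) / 18) -
    0.18 * plogis((wl - 1400) / 150) -
    0.10 * .gauss(wl, 1450, 40) -
    0.13 * .gauss(wl, 1940, 60) -
    0.05 * .gauss(wl, 2450, 150)
}

#' Synthesize full-resolution reflectance spectra from latent scores
#'
#' Builds one reflectance spectrum per spot on the 350-2500 nm 1-nm grid
#' (2151 bands) as `base spectrum + swir_score * a_swir * swir shape +
#' nir_score * a_nir * nir shape + vis_score * a_vis * vis shape + white
#' noise`, clipped to (0, 1). The three latent score vectors are typically
#' spatially correlated fields from [compose_response()]; amplitudes convert
#' unit-variance-scale scores into reflectance units.
#'
#' @param design A [generate_design()] result (provides spot metadata).
#' @param latents Matrix/data frame with columns `swir`, `nir`, `vis`, one
#'   row per spot.
#' @param amplitudes Named numeric vector of reflectance amplitudes per unit
#'   latent score.
#' @param noise_sd Standard deviation of the additive white measurement
#'   noise (reflectance units).
#' @param seed Integer seed for the noise draw.
#' @return A [spectrum_set()].
#' @export
synthesize_spectra <- function(design, latents,
                               amplitudes = c(swir = 0.040, nir = 0.045, vis = 0.035),
                               noise_sd = 0.0015, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  latents <- as.matrix(as.data.frame(latents)[, c("swir", "nir", "vis")])
  stopifnot(nrow(latents) == nrow(design$spots))
  wl <- 350:2500
  shapes <- latent_shapes(wl)
  amp <- amplitudes[c("swir", "nir", "vis")]
  refl <- matrix(base_spectrum(wl), nrow(latents), length(wl), byrow = TRUE) +
    (latents %*% (t(shapes) * amp))
  if (noise_sd > 0) {
    refl <- refl + withr::with_seed(
      seed, matrix(rnorm(length(refl), sd = noise_sd), nrow(refl)))
  }
  refl <- pmin(pmax(refl, 1e-6), 1 - 1e-6)
  spectrum_set(wl, refl, design$spots[, c("spot", "plot", "block", "main",
                                          "sub", "x", "y")])
}
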