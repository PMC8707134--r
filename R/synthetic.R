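#' Default ground-truth specifications of the three latent components
#'
#' The canonical study conditions of the synthetic generator: three latent
#' spectral components at realistic plot-trial scales. The SWIR (water
#' absorption) latent has heteroscedastic residuals — a pure nugget in one
#' main-plot group, a short-range spherical model in the other — plus main,
#' sub and interaction effects of roughly 0.2-0.6 magnitude. The NIR
#' (canopy structure) latent has pure-nugget residuals and a sub-plot
#' effect only. The VIS (pigment / stress) latent has a long-range, weakly
#' structured spherical residual and both effects. Nuggets sit near
#' 0.26-0.92, partial sills near 0.02-0.11 and ranges near 2.8-11.2 m.
#'
#' @return Named list of [effect_spec()] objects (`swir`, `nir`, `vis`).
#' @export
default_latent_specs <- function() {
  m2 <- c(NO = 0, YES = 0)
  s5 <- c(TRI = 0, LAM = 0, CER = 0, CHE = 0, CTR = 0)
  center <- function(v) v - mean(v)
  rank1 <- function(amp, u, v) amp * outer(u, v)
  u <- c(NO = -1, YES = 1)

  swir <- effect_spec(
    grand_mean = 0,
    main = c(NO = 0.1525, YES = -0.1525),
    sub = center(c(TRI = 0.298, LAM = 0.150, CER = 0.221, CHE = 0.376,
                   CTR = 0)),
    interaction = rank1(0.1, u, c(TRI = -0.25, LAM = -0.25, CER = -0.25,
                                  CHE = 1, CTR = -0.25)),
    residual = list(
      NO = variogram_model("nugget", nugget = 0.259),
      YES = variogram_model("spherical", nugget = 0.256, psill = 0.100,
                            range = 2.77)))

  nir <- effect_spec(
    grand_mean = 0,
    main = m2,
    sub = c(TRI = -0.05, LAM = -0.05, CER = -0.10, CHE = 0.30, CTR = -0.10),
    residual = variogram_model("nugget", nugget = 0.917))

  vis <- effect_spec(
    grand_mean = 0,
    main = c(NO = -0.1295, YES = 0.1295),
    sub = center(c(TRI = -0.500, LAM = -0.351, CER = -0.367, CHE = 0,
                   CTR = -0.600)),
    interaction = rank1(0.1, u, c(TRI = -0.25, LAM = -0.25, CER = -0.25,
                                  CHE = 1, CTR = -0.25)),
    residual = variogram_model("spherical", nugget = 0.557, psill = 0.062,
                               range = 11.18))

  list(swir = swir, nir = nir, vis = vis)
}

#' Left-skewing transform for a residual field
#'
#' Maps a zero-mean Gaussian residual vector through a reflected exponential
#' transform, producing a zero-mean, left-skewed (skewness about -1.2)
#' vector with the same standard deviation. Applied pointwise, so an iid
#' (pure nugget) field stays iid. Used to emulate a latent component whose
#' distribution fails the normality screen and triggers the rank-normal
#' branch of the pipeline.
#'
#' @param eps Zero-mean residual vector.
#' @return Transformed vector.
#' @export
skew_left <- function(eps) {
  s <- sd(eps)
  if (s == 0) return(eps)
  # lambda tuned so the lognormal skewness is ~1.18 before reflection
  lam <- sqrt(0.1302) / s
  y <- -(exp(lam * eps) - exp(0.1302 / 2))
  y * s / sd(y) - mean(y * s / sd(y))
}

#' Simulate a complete synthetic trial: design, latent fields and spectra
#'
#' The top-level synthetic generator. Builds the split-plot design, draws
#' the three latent component fields from their effect specifications
#' (optionally skewing the NIR latent's residuals so the normality screen
#' fails for that component, as real structural-component scores often do),
#' and synthesizes full-resolution reflectance spectra from them.
#'
#' @param seed Integer master seed; design, fields and spectral noise use
#'   deterministic sub-streams derived from it.
#' @param n_blocks Number of blocks.
#' @param specs Latent effect specifications (see [default_latent_specs()]).
#' @param skew_nir Skew the NIR latent's residuals (default `TRUE`).
#' @param amplitudes,noise_sd Passed to [synthesize_spectra()].
#' @return List with `design`, `latents` (data frame of spot metadata plus
#'   `swir`, `nir`, `vis`), `spectra` (a [spectrum_set()]) and `specs`.
#' @export
simulate_trial <- function(seed = 1L, n_blocks = 4,
                           specs = default_latent_specs(),
                           skew_nir = TRUE,
                           amplitudes = c(swir = 0.040, nir = 0.045,
                                          vis = 0.035),
                           noise_sd = 0.0015) {
  design <- generate_design(n_blocks = n_blocks, seed = seed)
  offs <- c(swir = 11L, nir = 23L, vis = 37L)
  latents <- design$spots
  for (nm in names(offs)) {
    tr <- if (nm == "nir" && skew_nir) skew_left else NULL
    resp <- compose_response(design, specs[[nm]], seed = seed + offs[[nm]],
                             residual_transform = tr)
    latents[[nm]] <- resp$z
  }
  spectra <- synthesize_spectra(design, latents, amplitudes = amplitudes,
                                noise_sd = noise_sd, seed = seed + 53L)
  list(design = design, latents = latents, spectra = spectra, specs = specs)
}
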