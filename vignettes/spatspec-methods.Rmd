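---
title: "Spatially aware mixed-model analysis of plot-trial reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware mixed-model analysis of plot-trial reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small agronomic trials — a handful of blocks under a greenhouse, plots a few
metres across, measurements centimetres apart — routinely violate the
independence assumption behind classical ANOVA. Residual variation in a
crop–soil system is spatially autocorrelated at exactly the scales at which
treatments are laid out, so ordinary least squares (OLS) F tests overstate
the evidence for treatment effects: part of the spatial trend is
misattributed to the factors. `spatspec` implements a complete pipeline for
detecting treatment effects on leaf hyperspectral reflectance in this
setting, replacing the iid residual assumption with a spatially correlated
residual field estimated by restricted maximum likelihood (REML).

The pipeline is: spectral preprocessing → correlation-matrix PCA with
VARIMAX rotation → per-component distributional and spatial diagnostics →
variogram estimation on OLS residuals → a REML-fitted linear mixed model
with spherical residual covariance, generalized least-squares (GLS) fixed
effects, Wald F tests and pairwise least-squares-mean contrasts — with an
OLS fit alongside for comparison.

## The model

For each retained spectral component, the per-spot scores $z$ follow

$$ z = M\beta + \varepsilon, \qquad
   \varepsilon \sim N(0, \Sigma), $$

where $M$ is the fixed-effects indicator design (intercept, main-plot
factor, sub-plot factor, interaction; reference-level constraint on the
last level of each factor so the reduced design has full rank) and the
residual covariance is stationary and isotropic,

$$ \operatorname{Cov}[e_i, e_j] = c(h) =
   \begin{cases} \sigma_0 + \sigma & h = 0 \\
   \sigma\left(1 - 1.5\,\tfrac{h}{\rho} + 0.5\,(\tfrac{h}{\rho})^3\right) &
   0 < h < \rho \\ 0 & h \ge \rho, \end{cases} $$

the spherical model with nugget variance $\sigma_0$, partial sill $\sigma$
and range $\rho$ (metres); equivalently $\gamma(h) = \sigma_0 + \sigma -
c(h)$ for $h>0$ with $\gamma(0)=0$. A pure-nugget model ($\sigma = 0$) is
the iid special case. Note that some descriptions print the spherical
covariance with $\sigma_0$ retained at all $h < \rho$; that contradicts
$\gamma(0) = 0$ and the standard convention, so this package keeps the
nugget at exactly $h = 0$ only.

Covariance parameters maximize the restricted log-likelihood

$$ \ell_R(\theta) = -\tfrac12\left[\log|\Sigma| + \log|X'\Sigma^{-1}X| +
   z'Pz + (n-p)\log 2\pi\right], \qquad
   P = \Sigma^{-1} - \Sigma^{-1}X(X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}, $$

by bounded quasi-Newton iteration on log-transformed parameters, started
deterministically from the least-squares variogram fit of the OLS residuals
plus two perturbations of it (×1/4, ×4). Fixed effects are the GLS
estimates at the optimum; with a single pure-nugget group the fit is
closed-form and reproduces OLS exactly (this identity is asserted to 1e-8
in the test suite, and is the primary oracle for the REML code path).

When Levene's test (one-way ANOVA of absolute deviations from group means)
rejects homogeneity across the two main-plot levels, each level gets its
own covariance parameters — possibly different families — with zero
cross-group covariance (block-diagonal $\Sigma$), while $\beta$ remains
jointly estimated. The five-level sub-plot factor is never used for
grouping: five separate variograms from under a hundred spots each are not
estimable with useful precision, so the rule restricts grouping to the
two-level factor.

### Inference

F tests are Wald quadratic forms in the GLS coefficient covariance: main
and sub-plot effects through contrasts of their least-squares means
(averaging the cell-mean rows of the reduced design over the other factor),
the interaction through its reduced-design coefficients. Denominator
degrees of freedom are the residual df, $n - \operatorname{rank}(X)$.
Fancier small-sample df corrections (Kenward–Roger, Satterthwaite) are
deliberately out of scope; the simulation studies below quantify what the
simple choice costs at this design's size. Pairwise LS-mean differences
report estimate, $\mathrm{SE} = \sqrt{L'\,\widehat{\operatorname{Cov}}
(\hat\beta)\,L}$, t and two-sided p, flagged at $\alpha = 0.05$.

Variance-parameter uncertainty (the REML table's z tests) comes from a
central-finite-difference Hessian of $-\ell_R$ on the natural parameter
scale; p-values are one-sided, the usual convention for variance
components.

## The pipeline stages and their parameters

**Preprocessing.** Spectra arrive as one row per measurement spot on the
1-nm 350–2500 nm grid (2151 bands). Splice correction removes detector-
transition steps (default boundaries 1000 and 1800 nm) by additively
offsetting each longer-wavelength segment so its first point matches the
linear extrapolation of the previous segment's last two points — the
simplest correction consistent with "minimize the inconsistency", since the
instrument vendors do not document their exact algorithm. Binning then
averages 10-nm intervals down to 215 bands; 2151 points do not divide
evenly, so the last bin absorbs 2500 nm as an 11th member and output labels
are bin-mean wavelengths. Multiplicative scatter correction (per-row
regression on the mean spectrum) and Savitzky–Golay smoothing (window
$w = 2n+1 = 11$, polynomial order 2, truncated asymmetric windows at the
edges) are implemented and tested but **off by default**: the default
analysis runs on splice-corrected, binned raw spectra, which for
contact-probe measurements typically retain more explainable variance at
the same number of components.

**PCA.** Eigen-decomposition of the 215×215 correlation matrix; Kaiser
candidates are eigenvalues > 1 (the strict inequality; with 215 variables
equality has probability zero), and the retained set is the shortest
candidate prefix exceeding 97% cumulative variance (all candidates, with a
warning, if none does). Retained loadings are VARIMAX-rotated (Kaiser
normalization, tolerance 1e-8) with each component's sign fixed so its
largest-magnitude loading is positive — eigen-solvers do not fix signs, so
reproducibility requires a convention. Scores are regression-method
(Thomson) scores from standardized data, centered to mean exactly 0 and not
rescaled; the original study's software does not document its estimator,
and its reported score SDs (≈0.7–0.8) are consistent with regression
scores. Salient wavelengths per component are maximal runs of contiguous
bands with |loading|×100 ≥ 80; an empty set is legitimate and is reported
as such.

**Diagnostics.** Normality of each component's scores is screened with the
three composite-null tests (Lilliefors/Kolmogorov–Smirnov, Cramér–von
Mises, Anderson–Darling, via the standard Stephens-type approximations in
`nortest`). The rank-normal (Blom) transform
$y_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, with average ranks for
ties, is applied when **at least 2 of the 3** tests reject at $\alpha$:
the screening rule is not fully specified by a single test, and the 2-of-3
majority reproduces both the clear-failure case (all three tests reject
for a skewness ≈ −1.2 component) and the clear-pass cases without being
triggered by one marginal p-value.

Moran's I and Geary's c are computed on OLS residuals under the
normality-assumption null moments (expectations $-1/(n-1)$ and 1), with
two-sided Z tests. The spatial weights are binary with a 1.0 m cutoff —
two within-plot neighbor rings at the 0.5 m spot spacing — symmetric,
zero-diagonal, unstandardized, and configurable; published analyses of
this design do not state their weights, and the printed null standard
deviations are weight-dependent, so the package documents its choice
rather than reverse-engineering one.

**Variogram.** The empirical semivariogram of OLS residuals uses
0.5 m lags (the spot spacing) up to half the maximum pairwise distance,
standard geostatistical practice; lags with fewer than 30 pairs are
flagged and excluded from fitting. Weighted least squares with pair-count
weights $N_k$ fits the spherical model (bounded, 5 deterministic range
starts); Gauss–Newton covariance gives approximate SEs and t tests. The
spherical model is **selected** over the pure nugget only when its partial
sill is significant at 0.05 and the fitted range is interior to its
bounds; the decision and its triggering statistic are logged. These LSE
fits initialize REML; they are not the final estimates.

## The synthetic-data generator

No field data accompany the study this design emulates, so the generator
is a first-class, tested module that defines the study conditions:

- **Design**: 4 blocks (beds 1.3 m deep, 0.5 m alleys), each split into
  two halves separated by a 2 m tunnel gap, randomized main-plot levels
  (NO/YES) per half and sub-plot levels (TRI/LAM/CER/CHE/CTR) within
  halves: 40 plots of 3.0 × 1.3 m. Spots sit on a 6 × 2 grid at 0.5 m
  spacing centered in the plot (the spot layout within a plot is not
  published; this grid spans 2.5 × 0.5 m and respects the 0.5 m minimum
  spacing). One seed drives design randomization, field draws and
  spectral noise through fixed sub-stream offsets.
- **Fields**: exact Gaussian-field draws via Cholesky factorization of the
  full covariance matrix — no approximation — from spherical/nugget models
  at the published parameter scales (nuggets 0.26–0.92, partial sills
  0.02–0.11, ranges 2.8–11.2 m), per-group heteroscedastic for the SWIR
  component (pure nugget in one compost level, short-range spherical in
  the other).
- **Effects**: sum-to-zero adjustments at the published contrast scales
  (main-effect differences ≈ 0.26–0.31, sub-effect differences ≈ 0.2–0.6,
  rank-one ±0.1 interaction). Differences not published (e.g. the LAM
  level on the SWIR component) were fixed once at mid-scale values.
- **Skewness**: the NIR component's residuals pass through a reflected
  lognormal transform calibrated to skewness ≈ −1.2, matching the scale at
  which real structural-component scores fail normality screens; the
  transform is pointwise, so the iid (nugget) spatial structure is
  preserved.
- **Spectra**: reflectance = smooth leaf-like base spectrum + three
  latent scores × smooth loading shapes (SWIR water bumps at
  1450/1885/1940 nm plus 2080/2365 nm; a NIR plateau over 715–1375 nm;
  VIS pigment bumps at 495/650 nm) + white noise (SD 0.0015), clipped to
  (0, 1). Shapes keep a floor amplitude of 0.35 of their peak across
  their region: with 215 standardized bands from 480 rows, bands carrying
  only noise would contribute spurious eigenvalues above 1
  (Marchenko–Pastur upper edge ≈ 2.2 at this aspect ratio) and corrupt
  Kaiser counting. Amplitudes (0.040/0.045/0.035 reflectance units per
  unit score) order the components' variance shares as SWIR > NIR > VIS.

What the generator does **not** emulate: radiative transfer or any leaf
biophysics, disease or treatment biology, instrument drift, anisotropy,
non-stationary trends. Passing tests therefore demonstrate that the
statistical machinery recovers known structure of exactly this kind — they
do not validate the biological interpretation of components on real
spectra.

## Numerical choices

- Optimizer: `optim(L-BFGS-B)` on $(\log\sigma_0, \log\sigma, \log\rho)$,
  $\rho$ bounded by the group's diameter; infeasible proposals (Cholesky
  failure, non-finite pieces) are internally rejected by returning a large
  objective value. Convergence tolerance 1e-8 on the restricted
  log-likelihood, 200 iteration cap, non-convergence flagged.
- The restricted log-likelihood at the optimum is checked against the
  initialization value (never lower) and, in tests, against `nlme::gls`,
  whose own optimum our fit must match or beat (on the test fixture `gls`
  stalls in a local optimum with a range an order of magnitude short, which
  is why the comparison is on likelihoods, not coefficients).
- Ties in ranks: average ranks throughout.
- Degenerate inputs are rejected with informative errors: constant vectors
  for autocorrelation/normality tests, groups of size < 2 for Levene,
  isolated locations for weight matrices, singular reduced designs,
  boundaries off the wavelength grid, non-monotone wavelength headers.
- Determinism: every stochastic function takes a `seed` and uses it
  locally (`withr::with_seed`), leaving the session RNG untouched;
  re-running the pipeline with the same config is byte-identical, and the
  run log records a hash of the configuration.

## Simulation study sizes

The packaged simulation studies (test suite and acceptance script) use:
20 seeds for PCA retention; 200 seeds for variogram-LSE recovery at the
weak-structure regime (13% structured share), with median-estimate
tolerances of 25%/50%/40% for nugget/partial sill/range — wide because a
13% structured share at n = 480 is genuinely weakly identified; 100 seeds
for grouped REML recovery at the heteroscedastic scales; and 500 seeds for
the type-I calibration study. Calibration uses the 40-plot layout with 6
spots per plot (n = 240): it preserves the design's spatial scales while
halving the covariance dimension, and residual-df F approximations are
already accurate there, whereas much smaller layouts (n ≈ 120) make any
method without small-sample df corrections visibly liberal. Under strongly
structured nulls (50% structured share, range 4 m) the OLS F tests reject
at 25–47% per effect while the spatial model's overall rejection rate
stays at the nominal level — the quantitative form of the warning that
ignoring spatial correlation risks type-I errors.

## Known limitations

- Isotropic spherical/nugget families only; no exponential/Gaussian
  variograms, no anisotropy, no kriging prediction.
- No random whole-plot error term: all non-fixed variation is carried by
  the spatial residual, mirroring the modelling tradition this pipeline
  follows; a textbook split-plot analysis would add one.
- Residual-df F tests are mildly liberal for small n with estimated
  covariance; at the design's scale the effect is within the calibration
  band reported above.
- Heteroscedastic grouping is restricted to the two-level main factor.
- The Blom transform is applied to scores before model fitting; effects
  estimated for a transformed component live on the rank-normal scale.
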