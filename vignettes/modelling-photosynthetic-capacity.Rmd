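---
title: "Estimating photosynthetic capacity from leaf spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating photosynthetic capacity from leaf spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

photospec links two measurement streams that plant ecophysiologists collect
on the same leaves: CO2-response (A/Ci) curves from gas exchange, which
yield the biochemical capacity parameters V~cmax~ (maximum RuBP
carboxylation rate) and J~max~ (maximum electron transport rate), and
full-range leaf reflectance spectra (350–2500 nm), which carry optical
signatures of the pigments, water and structure that covary with those
parameters. The package implements the complete analysis chain — curve
fitting, spectral preprocessing, partial least squares regression (PLSR)
with wavelength importance, a vegetation-index comparison, and validation
designs of increasing rigor — together with a synthetic study generator
that makes every stage testable without field data.

## The gas-exchange side: FvCB model and A/Ci fitting

Net assimilation in a C3 leaf is modelled as the minimum of two gross
rates minus day respiration:

$$A = \min(A_c, A_j) - R_d,$$

with the Rubisco-limited rate
$A_c = V_{cmax}\,(C_i - \Gamma^*)/(C_i + K_m)$ and the
RuBP-regeneration-limited rate
$A_j = J\,(C_i - \Gamma^*)/(4 C_i + 8 \Gamma^*)$. The realised electron
transport rate $J$ follows a non-rectangular hyperbola in irradiance with
curvature $\theta = 0.85$ and quantum yield $\alpha = 0.24$; at the
saturating PPFD of 1800 µmol m⁻² s⁻¹ used throughout, $J$ is within a few
percent of J~max~, so the estimates are insensitive to $\alpha$ and
$\theta$. All measurements are taken at 25 °C, so the kinetic constants
are fixed at their 25 °C values ($\Gamma^* = 42.75$ ppm, $K_c = 404.9$
ppm, $K_o = 278.4$ mbar, O₂ = 210 mbar, giving
$K_m = K_c(1 + \mathrm{O_2}/K_o) \approx 710$ ppm) and no temperature
response is implemented. Triose-phosphate-utilisation limitation is not
modelled; the highest-C~i~ points are retained as regeneration-limited.

`fit_aci()` estimates (V~cmax~, J~max~, R~d~) by bounded
Levenberg–Marquardt least squares from a small multi-start grid
(V~cmax~ ∈ {25, 50, 100, 200}, J~max~ = 2 V~cmax~, R~d~ = 1), keeping the
start with the lowest residual sum of squares. R~d~ is a free parameter
bounded [0, 10] µmol m⁻² s⁻¹. Standard errors come from the Jacobian at
the optimum. Each point is labelled Rubisco- or RuBP-limited by which
gross rate is minimal (ties to Rubisco); a fit with fewer than two points
in either regime, or that ends on a parameter bound, is flagged rather
than silently returned — with only one (or zero) Rubisco-limited points
the carboxylation capacity is essentially unidentified, a situation that
arises for strongly stressed leaves whose whole curve is
regeneration-limited, and such curves can harbour spurious low-residual
optima with wildly wrong V~cmax~. Downstream dataset assembly excludes
flagged fits, as a field campaign excludes unreliable curves.

Pre-fit quality control (`qc_aci()`) applies declared, switchable rules:
assimilation at the first ambient point must reach 10 µmol m⁻² s⁻¹ (the
conventional screen for photosynthetically active leaves), at least five
finite points, and A must track C~i~ over the initial descending limb
(Spearman ρ ≥ 0.5). All triggered rules are reported.

## The spectral side: preprocessing chain

Replicate spectra are quality-checked by masking negative reflectance
values, averaged per leaf, and assembled into a samples × wavelengths
matrix; a wavelength masked in *all* replicates of a leaf is linearly
interpolated from its neighbours, with a warning. Models use the
450–2500 nm window, subset before any transform.

The preprocessing chain applies, in order: standard normal variate (per
spectrum), a Savitzky–Golay second derivative (per spectrum), autoscaling
(per wavelength, dividing by the calibration-set standard deviation) and
mean centering (per wavelength). Scaling before centering as listed
composes to ordinary autoscaling; the literal order is kept so the stored
chain replays transform by transform. Two points matter in practice:

* **Calibration statistics never leak.** The per-wavelength sd and mean
  are estimated on the training rows only and replayed on any test rows
  (`preprocess_fit()` / `preprocess_apply()`); inside cross-validation the
  statistics are re-estimated within every training fold. The row-wise
  transforms (SNV, derivative) involve no cross-sample statistics and may
  safely be computed once for a dataset.
* **Derivative window.** The second derivative uses a 35-point window with
  a quadratic polynomial by default. At 1-nm sampling the leaf absorption
  features of interest are 30–80 nm wide, and a much narrower window turns
  the derivative into an amplifier of uncorrelated band noise: in our
  simulations a 15-point window left the latent chlorophyll signal at the
  noise floor and made cross-validated skill erratic from seed to seed,
  while windows of 25–35 points recover it stably. Both window and
  polynomial order are user-settable, and the filter is exact for
  polynomials up to the fitted degree (a quadratic input returns exactly
  2a everywhere, including the edge windows, which are handled by
  evaluating the edge-window polynomial fit off-centre).

The standard-deviation convention is n−1 everywhere. Wavelengths with zero
variance at the autoscaling step are dropped with a warning. A fitted
chain serialises to JSON at full double precision and restores
bit-identically.

## PLSR, component selection and Selectivity Ratio

With ~10² samples and ~2×10³ collinear predictors, ordinary regression is
hopeless; PLSR extracts a few latent components that maximise covariance
with the trait. For a single response the classical NIPALS algorithm needs
no inner iteration: each component's weight vector is the normalised
covariance of the current X residual with the current y residual, followed
by score/loading extraction and deflation. The implementation accumulates
regression coefficients for every component count from one fit, so
cross-validation evaluates all model sizes cheaply, and it verifies
against a pseudoinverse least-squares oracle at full rank.

The component count is chosen as the global minimiser of the root mean
squared error of prediction (RMSEP) under 10-fold cross-validation with a
fixed fold seed, ties broken toward fewer components. The upper bound
defaults to 10 components.

Wavelength importance uses the Selectivity Ratio: samples are projected
onto the normalised regression vector (target projection) and, per
wavelength, the variance explained by that single predictive component is
divided by the residual variance, with the denominator floored at 1e-12 to
keep uninformative wavelengths finite. SR is preferred over VIP scores as
the more reliable screen for which spectral regions a model actually
uses.

## Vegetation indices

The package ships a versioned JSON registry of 19 published narrow-band
indices (simple ratios such as SR1 = ρ750/ρ700, normalised differences
such as NDVI and PRI, and water-band indices such as NDWI) plus a
broad-band "MODIS-like" NDVI that averages raw reflectance over the MODIS
red (620–670 nm) and NIR (841–876 nm) band ranges before applying the
NDVI formula. An alternative "fwhm" mode restricts each band to the
wavelengths above the half-range height of the band-limited curve before
averaging; the procedure that mode emulates is under-specified for
non-peaked band segments, which is why the plain band mean is the
default. Two registry entries are transcribed exactly as published in the
comparison table they come from even though their printed forms differ
from the original index publications (noted in the registry); the
conventional full SIPI form is available separately as `SIPI_full`.
Indices are always evaluated on raw reflectance at exact 1-nm grid
points — never on preprocessed spectra — and `index_trait_report()`
regresses traits on each index, ranking by R².

## Validation designs

Three designs of increasing rigor, mirroring how such models are stressed
in practice:

1. **Leave-one-out** (`loo_cv()`): train on all but one leaf, predict it;
   fully deterministic.
2. **Repeated random splits** (`repeated_split()`): 100 random 80/20
   train/test splits by default; reports the mean, sd and median of
   per-split R².
3. **Stress holdout** (`stress_holdout()`): among all pairs of consecutive
   sampling dates ("consecutive" = adjacent in the sorted date list), hold
   out the pair with the largest pooled variance in predawn water
   potential, train on the rest, test on the held-out pair. This probes
   whether a model trained under mild, homogeneous conditions transfers to
   a period of strong within-population stress variation. Ties go to the
   earlier pair.

The headline R² is the squared Pearson correlation between observed and
predicted values, the convention consistent with observed-vs-predicted
validation panels; the alternative $1 - SSE/SST$ prediction R² is
reported alongside, since the two differ under bias. Component selection
and preprocessing statistics are recomputed inside every training fold of
every design; a canary test verifies that corrupting held-out spectra
cannot change any training-fold quantity. An option to fix the component
count across folds (`ncomp =`) exists for replicating analyses that
selected it once on the full data, at the cost of leak-freedom.

## The synthetic study generator

`simulate_study()` emulates the structure of a small mid-summer dry-down
campaign: 12 trees sampled on 7 weekly dates, population-mean V~cmax~
declining two-fold (110 → 55 µmol m⁻² s⁻¹) along a logistic trajectory
whose endpoints hit the configured means exactly, J~max~ coupled to
V~cmax~ with ratio 1.98 and 5% multiplicative noise, and a water-stress
episode: predawn water potential Ψ~pd~ dips from a −0.3 MPa baseline by up
to 0.9 MPa along a Gaussian-in-time profile (σ = 1 date, truncated at 2σ
so distant dates carry exactly zero stress) centred on date 4, with
per-tree noise that grows near the peak so the population variance of
Ψ~pd~ is largest on the stress dates. Stress also depresses V~cmax~ itself
(15 µmol m⁻² s⁻¹ per MPa below baseline) and J~max~ more strongly (a
multiplicative 0.3/MPa term centred on the study-mean stress level, so the
population J~max~/V~cmax~ ratio is unbiased) — electron transport is the
more drought-sensitive of the two capacities, and this asymmetry is what
makes the stress-holdout design genuinely harder for J~max~.

Each leaf gets a forward-simulated 13-point A/Ci curve at the standard
setpoint sequence (400, 300, 200, 100, 50, 0, 400, 400, 600, 800, 1200,
1600, 2000 ppm) with additive Gaussian noise (sd 0.5 µmol m⁻² s⁻¹), and
nine replicate reflectance spectra built from a smooth analytic green-leaf
template: a visible baseline, a red-edge rise, a gentle SWIR decline,
chlorophyll absorption wells at 470 and 665 nm whose depth grows linearly
with V~cmax~ (the blue well at only ~30% of the red well's sensitivity,
mimicking the saturation of blue absorption at moderate chlorophyll
contents), a red-edge midpoint that moves to longer wavelengths with
V~cmax~ (the relationship red-edge chlorophyll indices exploit), and water
wells at 1450 and 1940 nm that deepen as Ψ~pd~ becomes less negative.
When the water confound is enabled (the default study condition), the
red-edge midpoint additionally blue-shifts 1.5 nm per MPa of water
potential below baseline, entangling the chlorophyll region with stress.
Replicate noise is iid Gaussian (sd 0.005 reflectance units per band) and
spectra are clipped to [0, 1].

What this generator deliberately does **not** emulate: radiative-transfer
realism (no PROSPECT-style leaf model), smooth wavelength-correlated
instrument noise, detector-junction artefacts, weather, or leaf ontogeny.
Passing tests on synthetic data therefore demonstrate that the statistical
machinery recovers known structure under the declared noise model — not
that any particular field dataset will yield the same numbers. With all
noise terms set to zero the spectra→trait mapping is injective over the
simulated trait range, so near-perfect held-out prediction is attainable
and is asserted in the tests.

## Numerical and design choices worth knowing

* Kinetic constants are the 25 °C values above, config-overridable.
* The curve-fit multi-start grid avoids local minima without user tuning;
  non-convergence from every start returns an explicit failure object.
* The limitation transition is the discrete minimum of the two rates, ties
  labelled Rubisco-limited; no smoothing.
* RMSEP fold assignment, repeated-split draws and the study generator all
  take explicit seeds; two runs with the same seeds are bit-identical.
* Degenerate inputs fail loudly: constant spectra at SNV, constant traits
  at PLSR, all-negative spectra at QC, all-zero regression vectors at SR.
* Zero denominators in index formulas yield non-finite values, not errors.
* Problem sizes in the shipped tests and acceptance script are the default
  study (84 leaves × 2051 bands), 200 Monte-Carlo curve fits, 100 random
  splits and 50 PLSR oracle instances — sizes chosen so the full suite
  exercises every claim at desk scale.

## Known limitations

* The analytic spectral template has two latent degrees of freedom
  (capacity, water status); real leaf spectra are higher-dimensional, so
  absolute R² values on synthetic data are not forecasts for field data.
* No temperature or mesophyll-conductance corrections; estimates are
  "apparent" parameters at 25 °C.
* The FWHM band mode reproduces a published band-construction procedure
  only up to its ambiguities.
* PLSR here is single-response NIPALS; multi-trait and sparse variants are
  out of scope.

## A short end-to-end example

```{r}
library(photospec)

study <- simulate_study(synth_config(seed = 1))
data <- study_dataset(study, trait_source = "fitted")

loo <- loo_cv(data, "vcmax")
loo

st <- stress_holdout(data, "vcmax")
st$held_out_dates

model <- train_plsr(data$spectra, data$traits$vcmax, "vcmax")
selectivity_ratio(model,
                  preprocess_apply(model$prep_state,
                                   crop_wavelengths(data$spectra)))
```
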