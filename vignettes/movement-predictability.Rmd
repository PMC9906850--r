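---
title: "Quantifying movement predictability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement predictability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

High-frequency tracking of a population (here emulating a nocturnal
central-place forager such as the barn owl, localized every few seconds by a
regional reverse-GPS array) yields many repeated "assays" of each
individual's nightly movement. Two distinct axes of individuality can be
read from such data:

* the **behavioral type**: the individual's mean level of a movement index,
  e.g. its average nightly max-displacement (the beeline distance from the
  night's first fix to the farthest fix of the night); and
* the **predictability**: how tightly the individual's nights cluster around
  its own expectation, quantified as the residual intra-individual variation
  (rIIV). A low rIIV means a predictable individual.

`predmove` implements the full chain from raw localization fixes to these
two quantities and their ecological correlates (home-range size, survival),
plus a generative simulator with known ground truth so that every inference
stage can be validated by parameter recovery.

# The double-hierarchical model

The core statistical object is a Gaussian double-hierarchical model for
nightly max-displacement $y_{ij}$ of individual $i$ on night $j$:

$$y_{ij} = x_{ij}'\beta + u_i + e_{ij}, \qquad e_{ij} \sim N(0,
\sigma_{ij}^2),$$
$$\log \sigma_{ij} = w_{ij}'\lambda + v_i, \qquad
(u_i, v_i) \sim N_2\!\left(0, \begin{pmatrix} \tau_u^2 & \rho\tau_u\tau_v \\
\rho\tau_u\tau_v & \tau_v^2 \end{pmatrix}\right).$$

$u_i$ is the behavioral-type intercept; $v_i$ shifts the individual's log
residual SD, so the back-transformed residual SD
$\mathrm{rIIV}_i = E\!\left[\exp(\bar w_i'\lambda + v_i)\right]$ (posterior
mean, km) is the predictability index. $\rho$ captures the mean-variance
syndrome: whether individuals that fly farther are also less predictable.

**Response scale.** The response is modeled in km on the natural scale with
a log-linear model for the residual SD. The exponent back-transform to km
applies to the dispersion linear predictor, not to the response; a
log-response mode (`log_response = TRUE` in `dhglm_spec()`) exists for
sensitivity analysis and is not asserted to be "the" reference model.

**Fixed effects.** Defaults are age class + sex + period in the mean part
and age class in the dispersion part. These are configurable; the package
logs the design actually used in the fit object. An optional night-level
slope covariate can be added to the mean formula by the user (a minimal
reaction-norm gradient); no specific gradient is built in because none is
canonical.

**Priors.** Weakly informative: $N(0, 10^2)$ for mean fixed effects (km
scale), $N(0, 5^2)$ for dispersion fixed effects (log-km scale),
half-normal(2) for $\tau_u, \tau_v$, uniform$(-1, 1)$ for $\rho$.

## Sampler

The joint posterior is sampled by a blocked MCMC scheme written for this
model:

* $(\beta, u)$ — drawn jointly by composition: $\beta$ from its Gaussian
  conditional with $u$ marginalized out analytically (Woodbury identities on
  the per-individual compound-symmetry blocks), then $u \mid \beta$
  conjugately. Marginalizing matters: updating $\beta$ and $u$ separately
  mixes extremely slowly along the ridge created by individual-constant
  covariates (sex, mostly age).
* $\lambda$ — random-walk Metropolis (dimension is small).
* $v$ — element-wise random-walk Metropolis, vectorized across individuals
  (conditionally independent given the hyperparameters).
* ridge translation moves — a shift $d$ of one dispersion fixed effect
  compensated by $v_i \leftarrow v_i - d\,\bar w_{i}$; for
  individual-constant covariates the likelihood is invariant and the move is
  accepted on the prior ratio, decoupling $\lambda$ from the dispersion
  intercepts. A full Metropolis correction keeps the move exact when a
  covariate varies within individuals (age transitions).
* $(\tau_u, \tau_v, \rho)$ — joint random-walk Metropolis on
  $(\log\tau_u, \log\tau_v, \operatorname{atanh}\rho)$ with Jacobian terms.

Proposal scales adapt toward standard acceptance targets during warmup only.
Defaults are 4 chains of 4000 iterations (half warmup); convergence is
declared when split-$\widehat R < 1.05$ on all hyperparameters, and a
non-converged fit is returned with a failure flag and a warning, never
silently. All draws are reproducible from the spec seed.

Degenerate regimes are handled explicitly: $\tau_u \to 0$ pins $u_i = 0$,
$\tau_v \to 0$ pins $v_i$ at its conditional mean, and both are exercised by
the null-heterogeneity tests.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every inference stage is validated.

**Defaults** follow the printed summary statistics of the emulated study
system: 74 individuals; cohort-mean nightly max-displacement $\mu = 2.45$
km; among-individual SD $\tau_u = 0.887$ km (so that
$\mathrm{CV_i} = \tau_u/\mu = 0.362$); adult residual SD
$\exp(\lambda_0) = 1.23$ km and juvenile $2.25$ km
($\lambda_{age} = \log(2.25/1.23)$); $\tau_v = 0.4$, $\rho = 0.3$ (log-scale
spread of the reported group rIIVs and the reported positive mean-rIIV
association); 8-s fixes in 17:00–06:00 nights; 5-m localization noise;
nightly total distance $\approx 4.82 \times$ max-displacement (the ratio of
the two printed cohort means). Mean-part covariate effects are applied
centered so that $\mu$ remains the cohort mean.

**Free parameters the study does not state** were fixed once at values a
field ecologist would call realistic and are not revisited: flight speed 8
m/s; three 300-s perching bouts of 5-m radius along the outbound leg;
tagging dates spread over ~10 months; 60% juveniles; baseline hazard
1/1000 per day with log-hazard $-0.5$ per km of true rIIV (protective
unpredictability, the study's headline direction) and $+0.3$ for juveniles;
administrative censoring at 570 days.

**Truncation floor.** Nightly displacement draws below 0.05 km are resampled
rather than clipped, preserving the Gaussian bulk without a point mass at
zero. This has a real consequence: when $\sigma_{ij}$ is large relative to
$\mu$ (e.g. juveniles at the preset 2.25 km), resampling inflates the
realized mean and deflates the realized SD of the least predictable
individuals, and thereby genuinely raises the realized mean–dispersion
correlation above the nominal $\rho$. The parameter-recovery experiments are
therefore run at a dispersion scale where the floor is inactive
($\lambda_0 = \log 0.5$, no dispersion age effect, < 1% resampled); at the
full preset scale the generator is still exactly as specified, but the
recovery oracle for $\rho$ no longer applies to the *nominal* value. The
truncated fraction is always reported by the generator.

**What the generator does not emulate:** habitat-dependent movement,
foraging decisions, multi-night dispersal, heteroscedastic localization
error along the night, or missing fixes. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every feature of field data.

# Preprocessing and movement indices

* Fixes with accuracy estimate (STD) above 50 m are dropped; then a forward
  sweep per tag drops fixes implying a speed above 15 m/s relative to the
  *last retained* fix. Removing the later member of an over-speed pair and
  re-checking against the last retained fix is standard telemetry practice
  and deterministic; the filter is idempotent and never imputes.
* Nights run from 17:00 (closed) to 06:00 (open) local time, labeled by the
  evening's date; local time is UTC plus a fixed configurable offset, with
  no daylight-saving logic (reproducibility over calendar correctness).
* Seasonal periods: P1 Feb–May, P2 Jun–Sep, P3 Oct–Jan, with P3 keyed to the
  year of its October so a January night joins the preceding autumn.
* Inclusion: a night needs strictly more than 1000 fixes; an
  individual-period needs at least 25 nights; exclusion windows (e.g.
  incubation) are applied first and all counts are reconciled in the QC
  report.
* Stop detection uses a running-centroid rule (radius 20 m, minimum
  duration 60 s): the radius is well above the ~5-m localization accuracy
  and the duration well above the 8-s fix interval. Both are tunable, and
  sensitivity of rIIV to them should be examined rather than assumed. Total
  distance sums steps whose two endpoints are both in move segments;
  bridging steps are excluded (conservative).

# Home range

The home-range estimator is a deliberately simplified
autocorrelation-adjusted kernel density: stop-mode fixes thinned to 10-min
spacing, an exponential-decay timescale $\tau_{pos}$ fitted to the position
autocorrelation by least squares, an effective sample size
$N_{\mathrm{eff}} = \min(n, 1 + T/(2\tau_{pos}))$, per-axis reference
bandwidth $\hat\sigma N_{\mathrm{eff}}^{-1/6}$, and the isopleth area taken
as the smallest set of cells of a fixed $512 \times 512$ grid (padded by 3
bandwidths) containing 95% of the probability mass. This captures the core
correction of full autocorrelated kernel estimation — serially correlated
points carry less information than their count suggests — without variogram
model selection or optimal weighting; every output records
`estimator = "neff-adjusted-kde"`. The 95% level is the conventional choice
and is configurable. Reference-bandwidth smoothing inflates the area of a
Gaussian cloud by roughly $(1 + h^2/\sigma^2)$, about 5–7% at these sizes,
which is inside the tolerance used for validation.

# Survival and multimodel inference

Cox proportional-hazards regression is fitted by Newton–Raphson on the
partial likelihood with step-halving, Breslow tie handling by default
(Efron behind a flag), convergence at a relative log-likelihood change of
$10^{-9}$, and SEs from the observed information. Individuals crossing the
juvenile–adult boundary mid-study contribute two independent records
(juvenile span censored at the first birthday, adult span thereafter); a
mixed-effects variant is out of scope. On synthetic cohorts the per-record
tracking duration equals the outcome time by construction (exponential
events with administrative censoring), which makes it a degenerate,
monotone-likelihood covariate; it is therefore kept in the survival table
but omitted from default synthetic-data fits.

Candidate linear mixed models for log home-range area and for rIIV use a
random intercept per individual and are fitted by maximum likelihood (not
REML) so AICc is comparable across fixed-effect sets; the parameter count
includes the two variances. Collinearity-flagged pairs (|r| > 0.7) never
co-occur; stage 2 augments the stage-1 top set (ΔAICc ≤ 4.3 by default)
with geographic/density terms and re-ranks; full model averaging substitutes
0 where a predictor is absent and reports unconditional SEs per
Burnham–Anderson. Both the stage-wise and pooled rankings are emitted, since
it is ambiguous which set should carry the weights.

Repeatability uses a one-random-intercept REML fit profiled over the
variance ratio (written here so that balanced designs match closed-form
ANOVA estimators to numerical precision; `lme4` serves as an independent
cross-check in the test suite), with
$R_p = \tau^2_{among}/(\tau^2_{among} + \sigma^2)$ and
$\mathrm{CV_i} = \tau_{among}/\bar y$. Confidence intervals are parametric
bootstrap percentiles (the interval method is not canonical; posterior
intervals would be an alternative). Consistency of predictability across
periods applies the same machinery to log-rIIV — the log because an SD is a
ratio-scale quantity.

# Problem sizes and numerical choices

Validation experiments are sized for a desk machine: hyperparameter
recovery at 60 individuals × 120 nights (2 chains × 2000 iterations),
null-heterogeneity at 30 × 60, the survival headline at 500 individuals,
coefficient presets at n = 128, the Gaussian home-range closed form at 5000
points, and full-trajectory pipeline checks at 8 individuals × 30 nights of
5850 fixes each. Bootstrap intervals default to 1000 resamples (smaller in
pipeline smoke runs). Ties in AICc ranking break by parameter count, then
formula text; all stochastic stages derive their streams from one seed.

# Known limitations

* The DHGLM assumes Gaussian nightly displacement; the emulated system's
  fat-tailed nights (occasional very long excursions) would be captured as
  high rIIV, not as a separate behavioral mode.
* The home-range estimator is not a full autocorrelated kernel machinery;
  absolute areas carry a few percent of smoothing bias and its isopleths are
  grid-quantized.
* The speed filter's choice of which member of an over-speed pair to remove
  is a convention; the original pipeline's choice is unknown.
* Period-wise DHGLM refits treat periods independently; information is not
  pooled across periods.
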