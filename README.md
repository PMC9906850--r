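# predmove

Individual predictability in animal movement from high-frequency tracking
data.

## The problem this package addresses

Modern biologging systems localize many animals every few seconds for
months, turning each tracked night into one more repeated "assay" of an
individual's movement. Two axes of individuality can then be separated:

* **Spatial behavioral type** — the individual's mean level of a movement
  index. The index used throughout is the nightly *max-displacement*: the
  beeline distance from the night's first fix (typically the roost) to the
  farthest fix of that night.
* **Predictability** — the *residual intra-individual variation* (rIIV):
  how widely an individual's nights scatter around its own expectation once
  mean and covariate effects are removed. Low rIIV = a predictable
  individual.

`predmove` implements the full analysis chain for nocturnal central-place
foragers tracked by regional reverse-GPS arrays, and a ground-truth
simulator so that every stage is verifiable by parameter recovery: raw-fix
quality filtering and night segmentation, move/stop trajectory
segmentation, nightly movement indices, a double-hierarchical Gaussian
model for behavioral types and rIIV, repeatability (Rp) and CVi variance
partitioning, an autocorrelation-adjusted kernel home range, Cox
proportional-hazards survival, and AICc multimodel inference with full
model averaging.

## The model at the core

For nightly max-displacement `y_ij` (individual `i`, night `j`):

    y_ij = x_ij' beta + u_i + e_ij,        e_ij ~ N(0, sigma_ij^2)
    log sigma_ij = w_ij' lambda + v_i
    (u_i, v_i) ~ BVN(0; tau_u, tau_v, rho)

`u_i` is the behavioral-type intercept, `exp(w_i' lambda + v_i)` the
individual residual SD in km, whose posterior mean is the rIIV.
`rho` measures the mean–variance syndrome (do far-ranging individuals vary
more?). The joint posterior is sampled by a blocked Gibbs/Metropolis scheme
with collapsed fixed-effect updates, ridge-translation and
scale-interweaving moves (see the methods vignette,
`vignettes/movement-predictability.Rmd`). Downstream, Rp =
var_among/(var_among + var_within) partitions trait variance, rIIV enters
Cox hazard regression and AICc-averaged mixed models for log home-range
size.

## A worked example

Simulate a 30-owl cohort under the package's generative model (defaults
emulate a barn-owl-like study population), fit the DHGLM and extract
predictability:

```r
library(predmove)
cfg <- sim_config(n_individuals = 30, nights_per_individual = 80, seed = 42)
cohort <- simulate_cohort(cfg)
nights <- simulate_night_indices(cfg, cohort$truth)
fit <- fit_dhglm(nights, dhglm_spec(seed = 1))   # 4 chains x 4000 draws
print(fit)
#> DHGLM fit: 30 individuals, 2400 nights
#>   tau_u = 0.996  tau_v = 0.348  rho = 0.596
#>   max split-Rhat = 1.020  converged = TRUE

riiv <- extract_riiv(fit)
head(riiv, 3)   # most predictable individuals
#>   individual   scope riiv_km ci_low ci_high n_nights
#> 1     owl005 overall   0.590  0.507   0.688       80
#> 2     owl020 overall   0.698  0.602   0.818       80
#> 3     owl015 overall   0.721  0.615   0.843       80
tail(riiv, 2)   # least predictable
#>    individual   scope riiv_km ci_low ci_high n_nights
#> 29     owl003 overall    3.01   2.60    3.52       80
#> 30     owl023 overall    3.14   2.72    3.65       80

estimate_repeatability(nights, value_col = "max_disp_km",
                       n_boot = 500, seed = 1)
#> Rp = 0.320 [0.200, 0.433]  CVi = 0.385 [0.272, 0.510]  (30 ind, 2400 obs)
```

`riiv_km` is each individual's residual SD of nightly max-displacement in
km with its 95% credible interval: owl005 deviates from its own nightly
expectation by ~0.6 km, owl023 by ~3.1 km. The Spearman correlation between
these estimates and the simulator's true per-individual rIIV is 0.95 in
this run. Rp says 32% of the variance in nightly max-displacement is
among-individual; CVi scales the among-individual SD by the trait mean.

`run_all(run_config(...))` chains every stage (simulation, preprocessing,
indices, DHGLM, repeatability, home range, survival, model comparison) into
an artifact directory with a config-stamped JSON report.

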