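# starscale

Spatiotemporal scaling analysis of microbial biodiversity: how
taxonomic richness and Faith's phylogenetic diversity accumulate
jointly over nested sampled areas and observation time, and how land
use changes that accumulation.

## Who this is for

Microbial ecologists with nested spatiotemporal survey data — a plot
sampled at a fixed set of points grouped into nested areas, on a
repeated (e.g. monthly) schedule, typically with a treatment contrast
replicated across sites — who want scaling-rate estimates with honest
uncertainty, rather than one-off regressions.

## The model

Richness grows with sampled area (species-area relationship, slope
*z*) and with time observed (species-time relationship, slope *w*),
and the two dimensions interact. The species-time-area relationship
(STAR) fits both at once:

```
ln S = z ln A + w ln T + u ln A ln T + b
```

with area *A* in m², time *T* in months, and *u* the time-space
interaction (negative when each scaling rate decays with the other
dimension). Substituting Faith's phylogenetic diversity for *S* gives
the phylogenetic analog (PTAR). From a fitted model the time-space
equivalence ratio `exp((z − w)/u)` is the area whose spatial scaling
rate matches the temporal scaling rate over one time unit; because of
*u* the exponents are scale-dependent, and `rescale_units()` carries
fits between unit systems with the exact substitution algebra.

Around this core the package provides: nested / complete-nested /
island accumulation constructions; depth standardization
(passive-sampling control) with closed-form rarefaction; restricted
block-permutation significance tests; moving-window model families
with mixed-model, ln-response-ratio and Cohen's-d treatment
contrasts; rrn copy-number trait matching and community-weighted
means; spatial and detrended-temporal coefficients of variation;
temporal stability; and the Sloan neutral community model. A
mechanistic synthetic-data generator (log-normal pool,
distance-decaying spatial field, Markov turnover, multinomial read
sampling) makes the whole pipeline testable without sequencing data.

## Worked example

```r
library(starscale)

design <- make_design(n_sites = 1, n_treatments = 2, n_points = 9,
                      n_times = 12, n_area_levels = 4)
params <- simulation_params(pool_size = 200, depth_mean = 1000,
                            homogenization = 0.4, seed = 11)
comm <- simulate_communities(design, params)
tree <- simulate_tree(200, seed = 12)

surface <- build_accumulation_surface(subset_plot(comm, "site1", "fallow"),
                                      design, tree)
head(surface, 3)
#>    site treatment area_level area_m2 time_months richness       pd total_sequences
#> 1 site1    fallow          1       1           1       81 223.9558            1052
#> 2 site1    fallow          1       1           2      103 272.5303            2051
#> 3 site1    fallow          1       1           3      113 291.3805            3069

fit <- fit_star(surface, response = "richness")
fit
#> STAR fit (m2, month): z = 0.0605, w = 0.2479, u = -0.02034, b = 4.4906, R^2 = 0.9575 (n = 48)

equivalence_ratio(fit)
#> Time-space equivalence ratio (richness): 1.003e+04 m2/month

fam <- fit_window_family(comm, design, sizes = 5:9)
lmm_effect_size(fam, exponent = "w", fixed = "treatment", control = "fallow")
#> Effect size (lmm, random intercepts + AR(1)): -0.0488 (se 0.0023), p = 3.093e-05 [cropping vs fallow (richness w)]
```

Reading the output: one month of extra sampling in this fallow plot
adds new taxa about four times faster (*w* = 0.25) than a four-fold
area increase (*z* = 0.06 per ln-unit of area), the negative *u* says
each rate slows as the other dimension grows, and the homogenized
"cropping" arm has a significantly lower temporal scaling rate than
fallow (β = −0.049), the qualitative signature of a homogenizing land
use.

The full pipeline — surfaces, fits, permutations, windows, effect
sizes, soil heterogeneity, rrn traits, neutral models — runs from one
config:

```r
res <- run_pipeline(analysis_config(seed = 1))
write_report(res, "out/")
```

or from the shell via `inst/scripts/starscale.R` with a YAML config.

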