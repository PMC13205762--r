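---
title: "Spatiotemporal scaling of microbial diversity with starscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal scaling of microbial diversity with starscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starscale)
```

## The scientific problem

Species richness grows with the area sampled (the species-area
relationship, SAR) and with the length of time a site is observed (the
species-time relationship, STR); in log-log space both are
approximately linear, and their slopes — the *scaling rates* — measure
how fast new taxa are encountered as sampling extends along either
dimension. The two dimensions are not independent: the spatial scaling
rate measured over a long time window is smaller than over one month,
and vice versa. The species-time-area relationship (STAR) captures
both dimensions and their coupling in one generalized power law,

$$\ln S = z \ln A + w \ln T + u \,\ln A \ln T + b,$$

where $S$ is cumulative richness, $A$ the sampled area (m²), $T$ the
time length (months), $z$ the spatial scaling rate over one time unit,
$w$ the temporal scaling rate at one area unit, and $u$ the time-space
interaction (negative when each rate decays with the other dimension).
Replacing $S$ with Faith's phylogenetic diversity (PD, the summed
branch lengths of the subtree spanning the observed taxa) gives the
phylogenetic analog, PTAR. `starscale` implements this analysis for
nested soil-microbiome surveys: a plot sampled at a fixed set of
points, grouped into nested areas, on a monthly time series, with
treatments (e.g. bioenergy cropping vs fallow) replicated across sites.

## Nested accumulation surfaces

The response surface is built by *nested* accumulation
(`build_accumulation_surface()`): the taxa of the smallest area are
augmented by the new taxa of each successively larger area, and
likewise along time from the initial survey onward, so the cell
$(j, k)$ holds the union richness over area levels $1..j$ and months
$1..k$. Richness and PD are therefore monotone non-decreasing along
both axes by construction. Two alternative temporal constructions are
provided: the *complete-nested* curve (`complete_nested_curve()`),
which averages cumulative diversity over every consecutive window of
each length and coincides with the nested value at the full series
length, and *temporal islands* (`island_curve()`), one point per
independent survey. A taxon counts as present at any count above zero;
no minimum-count threshold is applied.

Faith's PD is computed root-inclusively by default (the branch path
from each tip to the tree root, matching common `picante` usage), so
the PD of all tips equals the total branch length; a rootless
convention (spanning subtree below the set's MRCA) is available via
`include_root = FALSE`. Missing (point, time) cells are a hard error
by default — nested unions silently built over incomplete cells would
not be comparable across scales — with an explicit `on_missing =
"skip"` escape hatch.

To separate genuine accumulation from the Passive Sampling Hypothesis
(more reads trivially yield more taxa), `standardize_depth()` rarefies
each scale's pooled counts to a common depth, reporting both the
Monte-Carlo mean over subsamples drawn without replacement (default
100 repetitions) and the closed-form hypergeometric expectation from
`vegan::rarefy`.

## Model fitting and unit algebra

`fit_power_law()` and `fit_star()` are ordinary least squares on
natural-log axes; the interaction design must contain at least two
distinct areas and two distinct times, and degenerate designs raise
errors rather than returning silent `NA`s (permutation machinery
discards and counts degenerate refits). On any noise-free surface
generated from the model the exponents are recovered to numerical
precision, which the test suite exploits as an exact oracle.

The time-space equivalence ratio $A/T = \exp((z - w)/u)$ is the area
whose spatial scaling rate equals the temporal scaling rate over one
time unit. It is undefined at $u = 0$ and numerically unstable for
$|u|$ near zero (flagged with a warning). Because the interaction term
makes all exponents scale-dependent, reporting in different units is
*not* relabelling: with $a$ old area units per new unit and $t$
likewise for time, `rescale_units()` applies the exact substitution
algebra ($z' = z + u\ln t$, $w' = w + u \ln a$, $u' = u$,
$b' = b + z\ln a + w\ln t + u \ln a \ln t$), under which the
equivalence ratio transforms as $\mathrm{ratio} \cdot t/a$. Fits are
always performed in base units (m², months) and converted afterwards;
refitting a rescaled surface and converting a fit agree to $10^{-8}$,
which is tested.

## Permutation inference

Nested construction induces strong serial dependence between adjacent
scales, so model significance is assessed by *restricted block
permutation* (`block_permutation_test()`): time points and area-level
increments are grouped into blocks of three consecutive scales
(trailing remainders of one or two scales stay intact as their own
block), the block orders are shuffled independently on each axis, the
surface is rebuilt from the permuted construction order, and the model
refit. Model significance is the upper tail of the null $R^2$; each
exponent is tested two-sided on its absolute refitted value. P-values
use the add-one estimator $(1 + m)/(1 + R)$, which can never be zero.

Two interpretations of "permuting the temporal and spatial order" are
possible: permuting the *labels* of the accumulation scales against a
fixed surface, or permuting the *construction order* of the raw scales
and rebuilding. We implement the second. The first is not a valid
test here: an accumulation surface is monotone by construction even
for structureless data, so the observed (sorted) labelling virtually
always fits best and the type-I error approaches one. Under the
rebuild null the test holds its size — across 300 simulated
structureless data sets (i.i.d. multinomial samples, $5\times 17$
scales, 199 permutations) the empirical rejection rate at
$\alpha = 0.05$ is 0.02–0.05 — at the cost of limited power against
smooth, time-homogeneous accumulation dynamics, for which permuted
construction orders produce nearly as regular a surface. The test
should be read as asking whether the *ordering* of scales carries
information beyond set size.

The STAR-vs-PTAR exponent contrast
(`star_ptar_difference_test()`) swaps the richness/PD response labels
block-wise along the time axis and records the refitted exponent
difference. This contrast is conservative by construction: the null
spread is generated by reshuffling the signal itself, so the ratio of
observed difference to null spread depends on the swap-unit geometry
far more than on the size of the gap. Finer swap units
(`block_size = 1`, one time scale per unit) give it materially more
sensitivity and are recommended when the surface cells are not
strongly dependent; the default stays at three for consistency with
the other permutation machinery.

## Moving windows and effect sizes

`fit_window_family()` refits the interaction model inside every time
window of sizes 5–14 months (step 1), re-anchored at the window start,
per plot and response — a 17-month series gives $13 + 12 + \dots + 4
= 85$ windows per plot per response. Treatment and soil-texture
contrasts on the resulting exponent families use a linear mixed model
(`lmm_effect_size()`, via `nlme::lme`) with nested random intercepts
(window size / site / plot) and an AR(1) residual correlation indexed
by the window start, to absorb the overlap between windows. AR(1) with
nested grouping is not estimable for every data layout (duplicated
start indices within the innermost grouping, or non-convergence); the
model then falls back to nested random intercepts only, then to OLS,
and the structure actually fitted is recorded in the result. Random
factors without replication in the data are dropped from the nesting
automatically. Complementary distribution-free effect sizes are
provided: the log response ratio with its delta-method variance
(`ln_response_ratio()`) and Cohen's d with pooled sample SD
(`cohens_d()`). Rank correlations between scaling rates and
environmental heterogeneity across taxa or plots use Spearman's rho
with Benjamini-Hochberg adjustment over the whole family of tests
(`spearman_fdr()`).

## Traits, heterogeneity, stability, neutral model

rrn copy numbers (16S rRNA operon copies per genome, a growth-potential
trait) are matched from an rrnDB-style reference starting at each
taxon's lowest named rank: all reference records carrying that name in
their lineage contribute their mean (child-mean); failing that the
search ascends the lineage (parent-mean); taxa unmatched at every rank
are flagged and excluded from downstream weighting, renormalizing the
abundance weights (`match_rrn()`). The community-level trait is the
abundance-weighted mean $\sum S_i n_i / \sum S_i$ (`community_rrn()`),
bounded by the trait extremes and invariant to rescaling all counts.

Environmental heterogeneity uses the coefficient of variation: spatial
CV is SD/mean across points at one time point; temporal CV is
*detrended* — the SD of residuals from an ordinary linear regression
on the time index, over the series mean — so a purely linear drift
contributes no heterogeneity. Sample (n−1) standard deviations are
used throughout. Temporal stability of richness is the inverse CV
(mean/SD), flagged infinite for a constant series.

The Sloan neutral community model (`fit_ncm()`) relates each taxon's
occurrence frequency across local communities to its mean relative
abundance through the Beta tail $1 - B(d;\,Nmp,\;Nm(1-p))$, with
community size $N$ defaulting to the mean read depth and detection
limit $d = 1/N$ (both overridable). The migration rate $m$ is
estimated by bounded scalar least squares on $(10^{-6}, 1]$. On data
generated from the model's own sampling mechanism
(`simulate_ncm_data()`: Beta-distributed local abundances truncated at
the detection limit) the median relative error of $\hat m$ is under
10% at $m = 0.1$, $N = 1000$, 50 samples, and estimates are ordered
across an $m$ grid. Applied to the package's synthetic communities
the estimate sits at the upper bound $m \approx 1$ — correctly so:
the generator draws every point from a common monthly pool, i.e. it is
mass-effects dominated, with no dispersal limitation to detect.
`ncm_treatment_effect()` contrasts per-time-point $m$ between
treatments with a random intercept per time point.

## The synthetic generator

`simulate_communities()` is a first-class, tested module that stands
in for the field study's sequencing data. Its mechanism is the
simplest one that exhibits SAR/STR behaviour: a log-normal regional
abundance pool (shape `abundance_sigma`, default 1.5, of which a
fraction `active_fraction` = 0.6 is locally active at any time); a
taxon-wise Gaussian spatial field over the point coordinates with
correlation $\exp(-\text{decay}\cdot d)$ between points
(`spatial_decay` = 0.15 per metre, amplitude `spatial_sigma` = 1);
Markov taxon replacement over months (`temporal_turnover` = 0.08 per
month, swapping active taxa against the inactive reservoir) plus
month-level log-abundance fluctuations (`temporal_sigma` = 0.4); and
multinomial read sampling at Poisson depth (`depth_mean` = 2000). The
default design mirrors a nested cross layout: 2 sites × 2 treatments ×
21 points × 17 months (1,428 samples), five nested area levels with
cumulative point counts `round(seq(1, 21, length.out = 5))` and
nominal areas 1, 4, 16, 64, 256 m². The physical area of each nested
level is not a measured quantity here; the geometric series is a
declared default, configurable per design.

`homogenization` emulates the loss of environmental heterogeneity
under intensive monoculture. Because reduced heterogeneity in the
motivating system is both spatial *and* temporal, the parameter damps
the spatial field, the monthly fluctuations and the turnover rate in
the designated (cropping) treatment by the factor $1 - h$; at $h = 1$
every point of a treated plot shares one composition per time point.
A moderate $h$ depresses the fitted $z$ and $w$ of the treated arm,
reproducing the qualitative direction of a homogenizing land-use
treatment. `simulate_soil_table()` applies the same idea to soil
properties through `treatment_variance_factor`, shrinking spatial and
temporal deviations of the treated plots.

What the generator does *not* emulate: read-level error and chimera
structure, phylogenetically conserved habitat preferences (the tree is
independent of the abundance mechanism), seasonality, and true
dispersal kernels. Passing tests therefore demonstrate correctness of
the estimators and constructions on data with the assumed statistical
structure, not robustness to every feature of real amplicon data.
One root seed drives every generator through documented sub-stream
offsets, so all stages are independently byte-reproducible.

## Numerical choices and degenerate inputs

Natural logarithms throughout; presence threshold is count > 0;
power-law fits demand strictly positive responses and predictors, and
zero-variance predictors raise a degenerate-design error while
constant responses return slope 0 with an explicit degenerate flag.
Permutation refits that hit an empty diversity cell are discarded and
counted rather than patched. The mixed models run with
convergence-tolerant control (`opt = "optim"`, `returnObject = TRUE`)
and a documented fallback chain. Rarefaction draws without
replacement; ties in the NCM objective resolve to the smaller $m$
through the bounded golden-section search.

## Problem sizes used by the test suite

The suite validates the nested construction against an exhaustive
set-union oracle on 200 random toy matrices (≤ 6 taxa, ≤ 3 levels,
≤ 3 times); permutation size on 300 structureless data sets (5 points,
17 months, 199 permutations); noisy exponent recovery on 200 surfaces
(5 × 17 grid, log-scale noise SD 0.05); homogenization direction on 50
replicate two-treatment studies (9 points, 17 months, window sizes
5–14); and neutral-model recovery on 20 replicates (50 samples, 200
taxa). These sizes were chosen to give stable Monte-Carlo estimates at
interactive runtimes.

## Limitations

The package fits the log-linear STAR family only (no Michaelis-Menten
or Lomolino saturation variants) and ordinary least squares rather
than mixed-effects surface fits; permutation inference is conservative
for smooth accumulation dynamics as discussed above; the rrn matcher
requires lineage-annotated references and does not query any live
database; and the equivalence-ratio extrapolation inherits all the
usual dangers of extrapolating a fitted power law beyond the sampled
scale range.
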