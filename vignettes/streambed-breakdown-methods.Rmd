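---
title: "Methods: litter breakdown and its biotic mediators across streambed compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: litter breakdown and its biotic mediators across streambed compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamlitter)
```

## The scientific problem

Plant litter entering streams is processed both in the benthic zone (BZ, the
upper few centimetres of the streambed in contact with surface flow) and in
the hyporheic zone (HZ, the sediment volume beneath it where surface water
and groundwater mix). Standardized bioassays — cotton strips, whose loss of
tensile strength tracks cellulose breakdown, and paired green/rooibos tea
bags (the Tea Bag Index) — make breakdown comparable across many streams.
The analytical question this package addresses is not merely *whether*
breakdown differs between compartments, but *through whom*: how much of the
compartment effect is mediated by the biological structure of the streambed
assemblage (biomass and diversity of Prokaryota, Protozoa and Eumetazoa
invertebrates, and prokaryote metabolic activity), and how much is a direct
effect of the abiotic environment.

The package implements the full chain: decay kinetics normalized to thermal
sums, community metrics, ordination of community structure, and a causal
three-step mediation analysis over nested linear mixed models — together
with a forward simulator of the whole survey so that every stage can be
tested against a known ground truth.

## Decay kinetics and the Tea Bag Index

Breakdown follows the single-pool exponential model
$X_t / X_0 = e^{-k t}$, where $X$ is tea dry mass or cotton tensile
strength and $t$ is measured in degree-days, so
$k = \ln(X_0 / X_t) / t_{dd}$. Using thermal sums as biological time
removes differences in deployment length and temperature between streams.

Degree-days are accumulated as daily mean temperature above a 0 °C base
(`thermal_sum()`). The base temperature is exposed as configuration; base-0
on daily means is the standard ecological convention, and nothing in the
method depends delicately on it at the temperatures of temperate streams.
The HZ is logged every 10 minutes; the BZ is only spot-sampled, so a linear
regression of BZ spot temperatures on time-matched HZ readings
(`infer_benthic_temperature()`, nearest reading within ±5 min) predicts the
full BZ series. With three or more well-spread spot pairs this is an
ordinary least-squares problem; fewer pairs, or a constant HZ series, are
degenerate and raise errors.

The Tea Bag Index splits each tea into a hydrolysable (labile) fraction and
a recalcitrant remainder, with published hydrolysable fractions
$H_g = 0.842$ (green) and $H_r = 0.552$ (rooibos) as configurable defaults.
From the observed decomposed green fraction $a_g$:

$$S = 1 - a_g / H_g, \qquad a_r = H_r (1 - S), \qquad
  W_t / W_0 = a_r e^{-K t_{dd}} + (1 - a_r),$$

solved for the stabilization factor $S$ (the share of the labile pool that
escapes decomposition) and the global decay coefficient $K$. Two degenerate
regions are flagged rather than thrown: $S < 0$ (green tea decomposed past
its nominal labile pool) and a rooibos remaining fraction at or below its
recalcitrant floor $1 - a_r$, where $K$ has no finite solution and is
reported missing. Assays whose final value exceeds the initial one
(measurement noise) are clamped to $k = 0$ with a warning; dropping them is
left to the caller.

Decay coefficients are reported in raw per-degree-day units; summaries and
plots use the conventional $10^{-3}$ per degree-day scale.

## Community metrics

Organism counts and body dimensions become carbon biomass through an
ellipsoid biovolume model $V = (\pi/6) L W^2$ and per-group allometries
$C = c_v V^{b}$ (`carbon_coefficients()`). The defaults follow widely used
literature conventions — a protist power law with exponent 0.939 and a
linear wet-volume conversion for invertebrates — and are deliberately
configuration, not claims about any particular dataset: published
supplementary conversion equations differ between studies, so the
coefficients must be adjustable without touching code. Prokaryote biomass
applies a fixed carbon density (default 200 fg C per cubic micrometre,
mid-range among published values) to spherical cell volumes.

Alpha-diversity is Shannon diversity standardized to a common base sample
size by rarefaction/extrapolation of the order-1 Hill number. For a
subsample of size $m \le n$ the package computes the *exact* expected
entropy under without-replacement subsampling from species-wise
hypergeometric expectations; for $m > n$ it extrapolates as a size-weighted
mixture of the plug-in entropy and the asymptotic low-bias entropy
estimator, which is continuous at $m = n$ and approaches the asymptotic
estimate as $m$ grows. The base size follows the usual convention
(`base_sample_size()`): the largest sample total, capped at twice the
smallest, so no sample is extrapolated beyond double its size. Flagellates
are counted as a single taxon in diversity but contribute to Protozoa
biomass; diversity is computed separately for Protozoa and Eumetazoa, which
are distinct mediators in the analysis.

EcoPlate readings (31 carbon sources × 3 replicates + 3 water controls) are
blanked against the mean control, floored at zero, and summarised as plate
and substrate AWCD, metabolic richness (substrates above an OD threshold,
default 0.25, the common EcoPlate convention) and metabolic diversity
($H'$ of the relative substrate AWCDs). A plate with no colour development
has undefined $H'$, reported as 0 with a flag. Mean-control blanking (rather
than per-replicate blanking) is the implemented variant.

## Ordination

Replicate bioassays are pooled per stream × compartment (summed densities,
ind/L) before ordination. Bray–Curtis dissimilarities feed a 2-D non-metric
multidimensional scaling (Kruskal stress-1, monotone regression via
`vegan::monoMDS`), run from a metric-scaling start plus random restarts
(default 50) with tight convergence thresholds so that exactly embeddable
geometries reach numerically zero stress. Tie treatment is weak by default;
a strong-tie option exists for degenerate symmetric configurations whose
shape is pinned down only by the tie structure. Goodness of fit is reported
as the non-metric $R^2 = 1 - S^2$ and the linear $R^2$ (squared correlation
of monotone-fitted values with ordination distances).

Covariates are related to the ordination by least-squares vector fitting
(continuous variables: projection direction and $R^2$; factors:
between-centroid share of the coordinate sum of squares) with significance
from row-label permutation: $p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) /
(1 + n_{perm})$, so $p$ can never be exactly zero and the smallest
attainable value with 1,000 permutations is 1/1001. Plain row permutation is
the null model; the permutation distribution is computed in-package (and
cross-checked against `vegan::envfit` in the tests).

## Mediation over nested mixed models

Each bioassay is the sampling unit; streams (30) nested in catchments (10)
enter every model as random intercepts, fitted by REML through
`lmerTest::lmer` with Satterthwaite degrees of freedom (an approximation
choice, documented as such). Compartment is coded BZ = 1, HZ = 0, so
positive coefficients mean faster benthic breakdown. Mediators are
standardized (mean 0, SD 1) so coefficients are comparable; zero-variance
mediators are dropped with a warning.

The causal three-step decomposition for each breakdown response:

1. response ~ compartment → total effect $c$;
2. each mediator ~ compartment → paths $a_j$;
3. response ~ compartment + mediators (+ selected compartment×mediator
   interactions) → direct effect $c'$ and paths $b_j$.

Step 3 may be preceded by backward elimination on maximum-likelihood fits:
interactions are considered before main effects, a main effect is frozen
while its interaction is retained, and a term is dropped unless its removal
worsens AIC by more than 2 — i.e. only terms carrying at least 2 AIC units
stay. The final specification is refitted by REML. The elimination path is
logged in the result.

The proportion mediated is the difference-in-coefficients estimator
$(c - c')/c$, the standard choice within the three-step framework, reported
only when the total effect is significant (default $\alpha = 0.05$); when
$c$ and $c'$ have opposite signs the result carries an "inconsistent
mediation" flag. Classification: *full* mediation when $c$ is significant,
$c'$ is not, and at least one retained mediator has significant $a_j$ and
$b_j$; *partial* when $c'$ stays significant; *none* otherwise.

The confidence interval for the proportion uses a delta-method standard
error. For nested linear models $\mathrm{Cov}(\hat c, \hat c') =
\sigma^2_{full} / (z'z)$, i.e. $\mathrm{Var}(\hat c)$ scaled by the ratio of
full- to reduced-model error variance; the package estimates that ratio from
the total error variances (residual plus random-intercept components) of the
step-1 and step-3 fits. In simulation at the survey design this interval is
mildly conservative (empirical coverage near 98% for nominal 95%), which we
prefer to an anti-conservative alternative. Bootstrap and quasi-Bayesian
intervals are deliberately out of scope.

## The forward simulator

`simulate_study()` generates the whole survey from configuration, so every
downstream stage has a test bed with known truth. The default design is 10
catchments × 3 streams × 2 compartments × 3 replicate bioassays deployed
29–61 days from late-October leaf fall.

The causal structure is linear on standardized scales: each mediator is its
compartment shift $a_j$ plus stream and catchment random intercepts plus
noise; each substrate's decay coefficient is an intercept plus a direct
compartment effect plus $\sum_j b_j m_j$ plus its own random intercepts and
noise, floored at $10^{-6}$ per degree-day (the decay model is undefined at
$k \le 0$). Configurations whose expected rate minus three random-intercept
SDs is non-positive are rejected as unusable. Substrate masses and strengths
are then obtained by *inverting* the decay model over degree-days computed
with the same `thermal_sum()`/`infer_benthic_temperature()` path the
analysis uses — so running the decay module on a simulated bundle recovers
the recorded true $k$ to machine precision, and the recorded true TBI
$(S, K)$ is the exact closed-form image of the generated tea masses. (A
design note: one cannot simultaneously impose a single-exponential $k$ for
rooibos *and* an independent two-pool $(S, K)$ on the same mass series; the
simulator treats the exponential model as primary and derives the TBI truth
from it, which keeps both round trips exact.)

Default effect sizes are chosen to emulate the gradient structure such
regional surveys report, fixed once and not revisited: mean decay coefficients near 4.0,
3.0 and 0.7 ×10⁻³ per degree-day for cotton, green and rooibos tea; a
roughly five-fold benthic excess for cotton and 1.5-fold for the teas;
strong benthic excess in all mediators except prokaryote biomass (shift 0);
and generating proportions mediated of 0.64 (green), 0.80 (rooibos, with a
near-zero direct effect, i.e. full mediation) and 0.69 (cotton). The large
compartment effect for cotton together with realistic within-zone spread
implies that a noticeable fraction of hyporheic cotton rates hit the
positivity floor — mirroring real surveys, where hyporheic cotton strips
often show no measurable strength loss; this truncation slightly attenuates
estimated effects for cotton.

Temperatures are a per-stream baseline (7–12 °C) with a 1.2 °C diel
sinusoid and reading noise; benthic spots follow a linear map
(slope 1.15, intercept 0.5 °C) of the hyporheic series plus spot noise, so
the regression inference has a recoverable truth.

Community tables are *renderings* of the latent mediators: multinomial
counts over fixed taxa pools with geometric-series abundances, a body-size
bias that over-represents large taxa in the BZ and small taxa in the HZ
(this is what lets the ordination separate compartments), evenness tied to
the diversity mediators, and total counts tied to the biomass mediators
through the same carbon allometries the analysis uses. EcoPlate profiles are
geometric substrate-utilisation spectra whose Shannon diversity matches the
metabolic-diversity mediator. The rendering is intentionally imperfect —
recomputed biomasses and diversities correlate strongly but not perfectly
with the latent values — so the end-to-end pipeline faces realistic
attenuation, while estimator-level tests use the latent analysis table
directly. What passing tests therefore show is that the *estimators* recover
the truth they are pointed at; they do not show that real communities follow
geometric abundance spectra, Gaussian mediators, or a linear structural
model, and temporal dynamics (colonisation, succession, spates) are not
simulated at all.

## Numerical choices and problem sizes

- NMDS: 50 starts, maximum 500 iterations, stress threshold 1e-12 and
  stress-ratio ceiling 1−1e-9, so exactly embeddable inputs reach stress
  below 1e-6; the run is reproducible under a seed.
- Permutation tests add one to numerator and denominator; p-values cannot
  be zero.
- Rarefaction uses log-space binomial coefficients throughout; no
  factorials overflow.
- Mixed models: singular fits (variance component at zero) are retained and
  flagged, not refitted; non-convergence raises an error.
- The test suite runs the mediation-recovery simulation at 200 seeds of the
  full 10 × 3 × 2 × 3 design with a single mediator, the variance-component
  recovery at 200 simulated surveys, the permutation calibration at 500
  seeds × 1,000 permutations, and the end-to-end reproducibility check on a
  packaged 2 × 2 fixture; these sizes were chosen so the whole suite
  completes comfortably on one CPU while keeping Monte-Carlo error well
  below the tested tolerances.

## Known limitations

- Single-retrieval design: no time-series decay fitting, and physical
  abrasion is not modelled separately from biological processing.
- The mediation decomposition is causal only under the usual mediation
  assumptions (no unmeasured mediator–outcome confounding); the package
  quantifies, it does not identify.
- The delta-method CI for the proportion mediated is approximate and
  mildly conservative; with multiple correlated mediators the nested-model
  covariance identity is itself an approximation under REML.
- Fungal assemblages, taxonomic identification and raw flow-cytometry
  processing are out of scope; the pipeline ingests counts, sizes and
  absorbances as data.

## A worked run

```{r run, eval = FALSE}
run <- run_pipeline(list(seed = 1))
run$mediation_summary
autoplot(run$ordination,
         groups = sub("^.*:", "", run$ordination$points$row),
         vectors = run$vectors)
```
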