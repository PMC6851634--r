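# streamlitter

Litter breakdown in streambeds, and the organisms that mediate it.

`streamlitter` is an R package for analysing standardized litter-breakdown
bioassays — cotton strips and paired green/rooibos tea bags (the Tea Bag
Index) — deployed in the two vertical compartments of the streambed: the
benthic zone (BZ, in contact with surface flow) and the hyporheic zone (HZ,
the sediment below it). It is aimed at freshwater ecologists who want to go
beyond "breakdown is slower at depth" and quantify *how much of the
compartment effect runs through the biology* — the biomass and diversity of
Prokaryota, Protozoa and Eumetazoa invertebrates colonising the assays.

## The model at the package's core

Breakdown is the single-pool exponential decay

> X_t / X_0 = exp(−k · t),  k = ln(X_0 / X_t) / t_dd,

with biological time t_dd in degree-days (daily mean temperature above
0 °C, accumulated over the deployment; hyporheic loggers record
continuously and the benthic series is inferred by regression on paired
spot measurements). The Tea Bag Index adds a two-pool model: from the
decomposed green-tea fraction a_g, the stabilization factor is
S = 1 − a_g/H_g, the decomposable rooibos fraction a_r = H_r(1 − S), and
the global decay coefficient K solves
W_t/W_0 = a_r·exp(−K·t_dd) + (1 − a_r) (hydrolysable fractions
H_g = 0.842, H_r = 0.552 by default).

Community structure enters through carbon biomass (ellipsoid biovolume ×
allometric carbon conversion), Shannon α-diversity rarefied/extrapolated
via order-1 Hill numbers to a common base sample size, and EcoPlate
metabolic activity (AWCD) and metabolic diversity (H′). Compartments are
compared by Bray–Curtis NMDS with permutation-tested vector fitting, and
each breakdown response is decomposed by the causal three-step mediation
method over linear mixed models with stream-within-catchment random
intercepts:

1. response ~ compartment → total effect c
2. mediator_j ~ compartment → paths a_j
3. response ~ compartment + mediators → direct effect c′ and paths b_j

with proportion mediated (c − c′)/c and a full/partial/none
classification. A forward simulator (`simulate_study()`) generates entire
surveys with known ground truth — the package's tests recover decay
coefficients to machine precision and the generating mediation structure
across hundreds of simulated surveys.

## A worked example

```r
library(streamlitter)

run <- run_pipeline(list(seed = 1))   # simulate the full 10x3x2x3 survey
                                      # and run every analysis stage
run$mediation_summary[, c("response", "c", "c_prime",
                          "proportion_mediated", "classification")]
#> # A tibble: 5 x 5
#>   response         c     c_prime proportion_mediated classification
#>   <chr>        <dbl>       <dbl>               <dbl> <chr>
#> 1 k_cotton  0.00540   0.00276                  0.489 partial
#> 2 k_green   0.00137   0.000392                 0.714 partial
#> 3 k_red     0.000307 -0.00000173               1.01  full
#> 4 K         0.000272  0.0000958                0.647 full
#> 5 S        -0.262    -0.100                    0.617 partial
```

Reading the rows: the compartment effect on cotton breakdown (total
c ≈ 5.4 ×10⁻³ per degree-day) drops by about half once the biological
mediators enter (partial mediation), while for rooibos tea the direct
effect becomes indistinguishable from zero — full mediation, essentially
the whole compartment difference runs through the biology. The
stabilization factor S moves the other way (negative c: more labile carbon
is sequestered at depth). Decay summaries, the biological summary table,
compartment ANOVA
contrasts, NMDS coordinates and fitted vectors are in `run$decay`,
`run$biology`, `run$zone_contrasts`, `run$ordination` and `run$vectors`;
`autoplot(run$ordination, vectors = run$vectors)` draws the ordination,
and `tidy()`/`glance()` work on the NMDS and mediation objects.

Each stage is also available on its own (`decay_table()`,
`biological_summary()`, `rarefied_shannon()`, `ecoplate_summary()`,
`bray_curtis()` + `run_nmds()` + `fit_vectors()`,
`anova_zone_contrast()`, `mediate_three_step()`), all taking and returning
plain data frames, so they chain with the pipe on your own CSV tables.
`write_study()`/`read_study()` round-trip a dataset bundle as CSV, and
`inst/scripts/streamlitter-cli.R` wraps `simulate` and `run-all` for shell
use.

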