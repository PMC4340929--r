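# arborant

Diversity and spatial null models for arboreal ant communities censused on
mapped forest stems.

## The problem

Whole-plot canopy censuses record, for every tree, which ant species **nest**
in it and which merely **forage** there. Holding the two layers side by side
answers two questions that single-layer surveys cannot:

1. How much of the diversity found on a tree is contributed by visitors —
   species foraging but not nesting there (**F-N records**)?
2. Do those visitors come from nearby? If foraging range is spatially
   limited, the nearest conspecific nest of an F-N record should be closer
   than expected when nests are shuffled over trees at random.

`arborant` is for community ecologists who have (or want to simulate) a stem
map plus two binary trees × species incidence matrices per plot, and who
want per-tree and whole-plot diversity summaries and a defensible spatial
test, reproducibly from a single seed.

## What it computes

* **Diversity.** Per-tree richness for the union, nest, forage and F-N
  layers; sample-based rarefaction via the Mao Tau expectation
  τ(h) = Σᵢ [1 − C(H−Yᵢ, h)/C(H, h)]; Chao2 richness estimates
  (classic S_obs + ((H−1)/H) q₁²/(2q₂) and bias-corrected variant, with
  Chao's 1987 incidence variances); shared species between plots; occupancy
  and invasive-fraction summaries.
* **Spatial null model.** Nearest-nest distances for F-N records, their
  cumulative distance curve, and a density-adjusted nesting-probability
  profile over radii 5–30 m, each compared against permutations of the nest
  matrix with **all row and column sums held fixed**. The randomization
  engine uses independent-restart curveball trades (C++), which sample the
  fixed-margin matrix class uniformly — verified against exhaustive
  enumeration in the test suite. Inference comes as nearest-rank 2.5–97.5%
  envelopes, min–max bands, an empirical rank p, and a rank-sum comparison.
* **Synthetic forests.** A stem-map simulator (uniform or Thomas-clustered
  stems, log-series species occupancies, exponential distance-decay
  foraging kernel, uniform "tourist" records) with two presets that rehearse
  a primary-versus-secondary forest census (389 + 295 stems, 126 species,
  26 shared). The generator is the known-truth harness behind the
  calibration and power tests.
* **Pipeline.** A YAML-configured runner (`run_pipeline()` /
  `run_diversity()` / `run_nullmodel()` / `run_simulate()`) writing
  long-format CSVs with config-hash sidecars, plus a thin CLI at
  `exec/arborant` (`simulate | diversity | nullmodel | all`).

## Worked example

```r
library(arborant)

sim <- simulate_community(preset_config("primary_like", seed = 42))
x <- sim$community
x
#> ant_community: 389 trees, 102 species, 1 plot(s)
#>   primary: 389 trees, 102 nesting / 102 foraging species

richness_summary(per_tree_richness(x, "primary"))
#>      plot  layer mean     se max
#> 1 primary    all 3.55 0.0840   8
#> 2 primary   nest 1.43 0.0590   5
#> 3 primary forage 3.55 0.0840   8
#> 4 primary     fn 2.12 0.0687   8

null_test(x, "primary", "nearest_distance", n_perm = 100, seed = 43)
#> Fixed-marginal null-model test (quasiswap, 100 permutations, seed 43)
#>   plot 'primary': 824 F-N records
#>   observed mean nearest-nest distance: 9.29 m (null mean 13.86 m)
#>   envelope for the mean: [13.12, 14.65] m -> below envelope (nests nearer than expected)
#>   rank p = 0.0198; rank-sum W = 0, p = 0.0895
```

Reading the output: trees hold on average 3.55 ant species, of which only
1.43 nest there — the rest are foragers, 2.12 of them F-N records. The mean
distance from an F-N record to the nearest conspecific nest is 9.29 m, while
the 100 fixed-margin permutations of the nest matrix put that mean at
13.1–14.7 m; the observed value sits below the whole null range
(rank p = 2/101 ≈ 0.02), i.e. species foraging in a tree nest significantly
closer in surrounding trees than chance placement predicts — exactly the
spatial signal the simulation preset embeds (a 5 m foraging kernel).

The per-radius probability profile makes the same point density-adjusted:

```r
null_test(x, "primary", "probability_profile", n_perm = 100, seed = 43)
#>   per-radius mean nesting probability of F-N species:
#>     d <=  5 m: observed 0.055, null 0.032 [0.026, 0.036]  *outside*
#>     d <= 10 m: observed 0.047, null 0.032 [0.030, 0.034]  *outside*
#>     ...
```

Within 5 m of a tree, 5.5% of neighbouring trees hold a nest of the focal
tree's F-N species, versus 3.2% expected under the null — aggregation that
fades with distance.

## Layout

```
R/                 data model, diversity, spatial null model, simulator, pipeline
src/curveball.cpp  fixed-margin randomization engine
exec/arborant      command-line wrapper
scripts/acceptance.R
tests/testthat/    unit, property and acceptance suites (oracles in helper-oracles.R)
vignettes/         methods vignette: model, assumptions, calibration design
```
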