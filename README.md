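# midecay

Mutual-information decay analysis of ethogram-coded action sequences.

Sequences of animal actions — here, wild chimpanzee stone-tool nut cracking
coded as `manipulation OBJECT` symbols such as `grasp NUT` or
`strike HAMMER` — can be generated by qualitatively different processes:
Markovian chaining of adjacent actions, hierarchical nesting under
higher-order goals, or a composite in which short *subroutines* are chained
locally and arranged hierarchically. These mechanisms leave distinct
fingerprints in how the mutual information (MI) between two sequence
elements decays as the distance between them grows:

- **exponential decay** `a·e^(−bx)` — Markovian, adjacent dependencies;
- **power-law decay** `a·x^b` (b ≤ 0) — hierarchical, fully nested
  structure;
- **composite decay** `a·e^(−bx) + c·x^d` — Markov subroutines under a
  hierarchical arrangement, with a transition point that predicts
  subroutine length.

`midecay` implements the full chain of analysis:

1. **MI estimation** (`estimate_decay_curve`) at inter-element distances
   0–100 with the Grassberger bias-corrected entropy estimator
   `Ŝ = [ln N − (1/N) Σ Nᵢ ψ(Nᵢ)] / ln 2`, a permutation chance floor
   `MI_sh` (observed marginals + shuffled joint entropy, 1,000 replicates
   at study scale) and the adjusted score `MI_Adj = MI − mean(MI_sh)`.
2. **Dependency range** (`max_dependency_distance`): the last distance
   before observed MI first drops below the upper 95% permutation limit,
   censored at the distance cap.
3. **Decay-model selection** (`fit_decay_model`, `compare_models`,
   `select_decay_model`): Levenberg–Marquardt least squares without
   additive constants, multi-start over a deterministic grid, and AICc
   comparison with Akaike weights (K counts the error variance: 3, 3, 5).
4. **Transition points** (`transition_point`): the minimand of the second
   derivative of the composite curve in log₁₀–log₁₀ space, floored to an
   integer distance, plus a 2-SE comparison against mean per-nut sequence
   length.
5. **Markov nulls** (`fit_markov`, `null_max_distance`,
   `community_experiment`): bigram-MLE chains with computed
   irreducibility/period flags, simulated null distributions of the
   dependency range with Garwood exact Poisson CIs, and a pooled community
   experiment measuring how often chain-generated sequences *falsely*
   prefer power-law or composite decay.
6. **Synthetic generators** (`gen_markov`, `gen_hierarchical`,
   `gen_composite`, `gen_nutcracking_corpus`) with known ground truth, used
   throughout the tests.

The raw video-coded chimpanzee corpus is not public; the published
per-individual summary tables ship in `inst/extdata/` and the package
reproduces the cross-individual arithmetic from them
(`published_aggregates()`).

## Worked example

Analyse a synthetic composite stream (subroutines of exactly 5 actions,
hierarchically arranged) end to end:

```r
library(midecay)

st    <- gen_composite(L_min = 5, L_max = 5, seed = 7, length = 2000)$stream
curve <- estimate_decay_curve(st, d_max = 100, n_perm = 200, seed = 8)
sel   <- select_decay_model(curve)
sel$max_distance
#> $distance
#> [1] 31
#> $censored
#> [1] FALSE
sel$comparison
#> <model_comparison>
#>        family K   AICc dAICc weight cum_weight   LL
#> 1   composite 5 -122.8   0.0      1          1 67.6
#> 2 exponential 3  -73.7  49.1      0          1 40.3
#> 3   power_law 3  -54.7  68.1      0          1 30.8
#> sole best: composite
transition_point(sel$fits$composite, sel$max_distance$distance)
#> <transition_point> 3 (continuous 3.386 )
```

Dependencies are significant out to 31 elements; the composite model wins
decisively (ΔAICc ≥ 49 over both alternatives), and the estimated
transition at distance 3 sits within ±2 of the true subroutine length 5 —
the decay curve switches from within-subroutine (exponential) to
between-subroutine (power-law) comparisons at about the scale the generator
actually used.

A shell wrapper for whole-corpus runs is installed at
`system.file("scripts", "midecay-study.R", package = "midecay")`:

```sh
Rscript inst/scripts/midecay-study.R --synthetic 8 --seed 7 --out results/ --desk
```

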