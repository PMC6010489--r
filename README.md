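# cuewalk

Step-length distributions of cue-driven search walks.

## The problem

Searching insects produce paths that look random, and movement ecology
usually models them as correlated random walks with exponentially
distributed step lengths. `cuewalk` implements and tests a mechanistic
alternative: the searcher is an automaton that travels in straight lines
and reorients only when it contacts a substrate micro-cue. The spatial
statistics of the cues then *dictate* the step-length law. If the cue
count within distance *r* scales as *n(r) = (r/δ)^D* — a fractal pattern
of dimension *D* with inner scale δ and cue radius ρ — the free-path
density for *r ≥ δ* is

```
p(r) = (ρD/πδ²) · exp[ −(ρD/πδ^D)·(r^{D−1} − δ^{D−1})/(D−1) ] · (r/δ)^{D−2}
```

a **generalized stretched exponential** with shape tied to one number:
γ = D − 1, μ = D − 2 in the kernel `exp(−(λl)^γ)·l^μ`. Uniform random
cues (D = 2) give the familiar simple exponential; D = 1 gives a pure
power law. Distinguishing these practically similar distributions — and
estimating D from paths — is what the package is for.

It is aimed at movement ecologists analysing digitized search
trajectories (e.g. ants searching after displacement) and at theorists
who want a tested simulation of the underlying encounter process.

## What is inside

* **Distribution families** on a truncated support — exponential,
  bi-exponential, stretched exponential, constrained and free generalized
  stretched exponentials, power law — with log-domain normalization,
  CDF/quantile/sampling, and the encounter-theory functions
  (`encounter_rate()`, `free_path_pdf()`, `mean_free_path()`).
* **Maximum-likelihood fitting** (`fit_steplaw()`) with multi-start
  bounded optimization, AICc, pairwise and multi-model Akaike weights,
  pooling, the exact two-tailed binomial sign test, and rank-frequency
  curves.
* **Trajectory segmentation** (`segment_path()`) by the field's standard
  criteria: a turn must exceed 45° and be sustained for at least 4 cm,
  within a 4 m analysis radius; per-segment metrics and first-k summaries.
* **A synthetic-data engine**: uniform Poisson cue fields, the 3-of-4
  quadrant-retention fractal (similarity dimension log3/log2 ≈ 1.585) and
  its tunable-dimension generalization, box-counting dimension
  estimation, an exact ray–circle automaton walker, and dimension-recovery
  experiments.
* **A pipeline** (`run_study()`) that simulates or reads data, segments,
  fits, compares and writes report tables, plus a thin CLI at
  `inst/scripts/cuewalk.R`. The package also bundles the published
  per-individual fit table for *Melophorus bagoti* channel searches
  (`bagoti_channel_fits()`) and recomputes its Akaike weights from the
  printed log-likelihoods.

## Worked example

Simulate a walker on a deep quadrant fractal and ask which step-length
family the data support:

```r
library(cuewalk)

qf    <- quadrant_fractal(levels = 8, domain = 8, seed = 1)
run   <- simulate_walker(qf, walker_config(max_steps = 800, seed = 2))
steps <- walker_step_sample(run, qf)   # drops steps below the cutoff
fit   <- fit_steplaw(steps, "GSE_CONSTRAINED", D_range = c(1, 3))
print(fit)

multi_model_weights(list(
  fit,
  fit_steplaw(steps, "EXP"),
  fit_steplaw(steps, "BIEXP"),
  fit_steplaw(steps, "POWER")))
```

```
steplaw fit [GSE_CONSTRAINED]: n = 750, logL = -894.6976, AICc = 1793.4112
lambda      D
1.3943 1.4920
           family k  logL aicc delta   weight
1 GSE_CONSTRAINED 2  -895 1793   0.0 1.00e+00
2             EXP 1 -1075 2153 359.6 8.33e-79
3           BIEXP 3  -906 1818  24.7 4.44e-06
4           POWER 1  -946 1893  99.8 2.12e-22
```

The fitted dimension (D̂ = 1.49) sits near the substrate's similarity
dimension 1.585, and the constrained stretched exponential takes
essentially all of the Akaike weight: the walker's steps carry a readable
imprint of the substrate's fractal dimension. On a uniform field the same
pipeline hands the weight to the simple exponential instead.

Auditing the published per-ant table works the same way:

```r
sign_test(18, 22)
#> p-value = 0.004344
```

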