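---
title: "Methods: step-length distributions of cue-driven search walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-length distributions of cue-driven search walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuewalk)
```

## The model

`cuewalk` analyses animal search paths under one generative hypothesis: the
searcher travels in straight lines and reorients only on contact with small
substrate features ("micro-cues"). The spatial statistics of the cues then
dictate the step-length distribution.

If the number of cues within distance $r$ of the walker scales as
$n(r) = (r/\delta)^D$ — the mass–radius definition of a fractal pattern
with dimension $D$ and inner scale $\delta$ — then the chance of an
encounter while crossing the annulus $[r, r+\mathrm{d}r]$ is the fraction
of its circumference covered by cue cross-sections of radius $\rho$:

$$q(r)\,\mathrm{d}r = \frac{\rho D}{\pi \delta^2}
  \left(\frac{r}{\delta}\right)^{D-2} \mathrm{d}r .$$

Accumulating the hazard gives the free-path density for $r \ge \delta$,

$$p(r) = \frac{\rho D}{\pi \delta^2}
  \exp\!\left[-\frac{\rho D}{\pi \delta^D}
  \frac{r^{D-1} - \delta^{D-1}}{D-1}\right]
  \left(\frac{r}{\delta}\right)^{D-2},$$

a *generalized stretched exponential* (GSE): the kernel
$\exp(-(\lambda l)^\gamma)\, l^\mu$ with shape tied to a single dimension,
$\gamma = D - 1$ and $\mu = D - 2$. Uniform random cues ($D = 2$) give a
simple exponential — the step-length law assumed by correlated random
walks — and $D = 1$ gives a pure power law. The package implements this
family (`GSE_CONSTRAINED`) alongside its rivals: the exponential, the
bi-exponential mixture (multiphasic walks), the bare stretched exponential,
the unconstrained GSE and the power law (Lévy-type), all on a truncated
support, with AICc model selection and Akaike weights.

## Truncated families and numerics

All densities are defined on $[a, b]$ with $0 < a < b$; evaluations outside
are zero. When fitting data the default bounds are the observed range; for
simulations they are $[\delta_{\text{cutoff}}, \text{domain diagonal}]$.

* **Normalization** uses closed forms where exact (exponential, power) and
  adaptive quadrature otherwise, with the kernel evaluated in the log
  domain so large $\lambda l$ never under/overflows; the absolute
  tolerance is $10^{-9}$ and every family is property-tested to integrate
  to one within $10^{-6}$.
* **Sampling** inverts the numerically integrated CDF on a 4096-node
  log-spaced grid with monotone interpolation — one mechanism for all six
  families; at $n = 10^5$ the empirical CDF agrees with the integrated CDF
  within $3\times10^{-3}$ sup-norm.
* The $\gamma = 0$ limit of the GSE kernel is handled explicitly (the
  stretch factor degenerates to a constant, leaving a pure power of $l$).
* The bi-exponential is a mixture of two *individually normalized*
  truncated exponentials, so its mixing weight `w` keeps its probability
  interpretation on the truncated support; identifiability is fixed by
  reporting $\lambda_1 < \lambda_2$.

## Fitting and model selection

`fit_steplaw()` maximizes the truncated log-likelihood by bounded
multi-start local optimization (`L-BFGS-B`; $\lambda$ on the log scale).
The bi-exponential likelihood is multi-modal, hence eight start points
spanning rate ratios; nested families are additionally seeded from the
fitted simpler family, which guarantees (and the suite verifies) that the
maximized log-likelihood is monotone non-decreasing along
EXP $\subset$ STRETCHED $\subset$ GSE\_FREE,
EXP $\subset$ GSE\_CONSTRAINED $\subset$ GSE\_FREE and
EXP $\subset$ BIEXP. A small-sample fit is verified against an exhaustive
$400 \times 400$ grid search to within $10^{-3}$ log-likelihood units.

Default parameter boxes: $\lambda \in [10^{-4}, 10^4]\,\mathrm{m}^{-1}$,
$D \in (0.5, 3]$, $\gamma \in (0.05, 3]$, $\mu \in [-3, 3]$,
$w \in [0.01, 0.99]$, power exponent $\mu < 0$. $D$ deliberately extends
above 2: data-driven estimates may exceed the geometric ceiling that
applies to a physical cue pattern.

Model comparison uses the finite-sample AICc,
$2k - 2\log L + 2k(k+1)/(n-k-1)$, with Akaike weights
$w_i \propto \exp(-\Delta_i / 2)$. Fits are refused for $n < k + 2$ and
the refusal is reported, not silently dropped. Across individuals the
package offers the exact two-tailed binomial sign test (doubled smaller
tail, capped at one) and pooling that concatenates samples and refits on
the pooled range. Rank-frequency curves (the complement of the empirical
CDF) mirror the field's standard visualization.

### A bimodality at low D

For data generated with $D \approx 1.3$ on realistic supports, the
constrained-GSE likelihood is bimodal: a branch with $D < 1$ — where
$\gamma = D - 1 < 0$ turns the stretch factor into a *rising* term played
off against a steeper power — fits samples of $n \approx 500$ marginally
better (about two log-likelihood units) in roughly a quarter of
realizations. Estimates then collapse toward the box edge rather than
scattering near the truth; published per-individual estimates that sit at
exactly 1.00 are the signature of the same effect. The generative theory
is only defined for $D > 1$ (below it a walker has finite escape
probability), so wherever the package estimates the dimension *of a
substrate* — `recovery_experiment()` and the `run_study()` pipeline — the
constrained fit is restricted to $D \in [1, 3]$ (`D_range`). Direct
`fit_steplaw()` calls keep the wide box, and the recovery suite documents
the bimodality instead of hiding it: at $D \in \{1.6, 1.9\}$, $n = 500$,
the estimate lands within $\pm 0.3$ of the truth in $\ge 90\%$ of seeds;
at $D = 1.3$ part of the mass sits in the $D < 1$ branch.

## Trajectory segmentation

`segment_path()` converts a digitized polyline into straight runs using
two criteria applied at each vertex, both relative to the direction of the
*current run* (run start to current vertex), not the previous tiny
digitization edge: the turn must be strictly sharper than the threshold
(default 45°) on the outgoing edge, **and** it must be sustained over the
next `min_run` (default 4 cm) of path. The first condition stops lookahead
from anticipating a corner; the second discards on-the-spot turns that
revert within 4 cm, and hand-digitization jitter far below 45° never
fragments a run. Paths are clipped at the analysis radius (default 4 m)
by linear interpolation before segmentation. Segment length is the
polyline arc length of the run — sub-threshold wiggle is part of the
traveled step — with a `"chord"` option; both the vertex-only convention
(`turn_convention = "vertex"`) and the chord length are exposed as flags
since the original procedures do not pin these details down. The suite
verifies scale equivariance, rotation invariance and idempotence
(re-segmenting the segment chords reproduces the breakpoints).

`first_k_summary()` reproduces the per-segment-index descriptive summary:
individuals with fewer than $k = 20$ segments are excluded (count
reported) and normal-theory $t$ confidence intervals are computed across
individuals for the absolute turn angle, segment length and distance of
the segment end from the release point. The repeated-measures inferential
analysis around those means is out of scope.

## The synthetic-data engine

The simulator is the package's test bed for the theory; it emulates the
study conditions — an 8 m × 8 m arena with the release point at the
center — and two substrate classes:

* `uniform_field()`: a homogeneous Poisson scatter ($D = 2$) with
  $\delta = 1/\sqrt{\pi \cdot \text{density}}$, so $n(r) = (r/\delta)^2$.
* `quadrant_fractal()`: the recursive 3-of-4 quadrant retention — each
  retained cell keeps a random three of its four sub-quadrants — whose
  infinite-depth similarity dimension is $\log 3 / \log 2 \approx 1.585$;
  the experimental surface class corresponds to three recursion levels,
  and level 8 is used when a deep scaling range is wanted. The retained
  area fraction is exactly $(3/4)^{\text{levels}}$.
  `retention_fractal()` generalizes the rule (drop one quadrant with
  probability $p$), interpolating dimensions $\log(4-p)/\log 2 \in
  [1.585, 2]$ for recovery experiments.

Two calibration choices matter and are deliberate:

* **$\delta$ is measured, not assumed.** The theory's $\delta$ is defined
  by the mass–radius relation, and for the quadrant fractal it is *not*
  the deepest cell size: retained cells touch, so the average cue count
  around a cue is about twice the naive cell-size scaling. The generator
  therefore calibrates $\delta$ by regressing the measured counts on the
  fixed slope $D$ over dyadic radii (boundary-aware, seeded), storing the
  cell size separately as the scaling cutoff below which steps are
  excluded from fits. With the naive cell-size $\delta$ the
  walker-vs-theory survival comparison is off by ~0.2 sup-norm; with the
  measured $\delta$ it agrees within ~0.03.
* **Cues are sparse: $\rho = \text{cell}/10$ by default.** The
  product-to-exponential step in the hazard derivation assumes
  $q(r)\,\mathrm{d}r \ll 1$ and no correlated re-collisions. At
  $\rho = \delta/4$ a Poisson field puts a second cue within $2\rho$ of
  roughly half of all turn points, generating excess short steps that a
  three-parameter rival will detect in a few thousand steps. The hard
  geometric bound remains $\rho \le \delta/2$ (non-overlap), enforced
  everywhere.

`simulate_walker()` advances the walker along its heading, finds the first
entry into any cue disc by exact ray–circle intersection, records the
straight distance since the last turn, and draws a fresh heading uniformly
on the circle — the minimal isotropic reading of "random reorientation".
The cue that triggered a turn is refractory until left behind, preventing
zero-length step cascades the theory does not model. Cue discs persist by
default (the predictions hold equally for long-lasting and ephemeral cues;
an ephemeral toggle would remove them on contact, and persistence is the
conservative choice for reproducibility). At the arena wall the default
rule mirrors the heading and lets the current run keep accumulating
length: a reflected Poisson field is statistically the field itself, so
unfolding preserves the free-path law; `"stop"` ends the run instead.
Everything is byte-for-byte reproducible from the seed.

Detection is disc intersection (matching the cross-section argument of the
hazard) rather than grid-cell entry; that choice is the only one
consistent with $q(r)$.

## What the simulator does and does not establish

Passing tests show that the implemented walker on the implemented fields
realizes the predicted free-path laws: the mean free path on uniform
terrain matches $\pi\delta^2/(2\rho)$ within 5% at $10^4$ steps, the
fractal-terrain survival matches the closed form within 5% sup-norm over
$[\delta_{\text{cutoff}}, 20\,\delta_{\text{cutoff}}]$, and the fitted
dimension recovers $\log 3/\log 2$ within $\pm 0.3$ in $\ge 90\%$ of
20 seeds at $n = 500$ (with a modest downward bias, mean $\hat D \approx
1.47$, from boundary reflections and lattice discreteness — the quadrant
fractal's cues sit on a dyadic lattice, which is self-similar only down to
the cell size). Real substrates differ in ways the engine does not
emulate: cue strengths and detection are probabilistic, headings after
real turns are not uniform, arenas contain non-cue obstacles, and
digitization noise enters upstream of segmentation. The segmentation and
fitting layers are therefore tested separately on constructed geometries
and on draws from the exact distributions.

Two statistical facts shape the acceptance checks. First, model-selection
consistency cuts both ways: with a nested three-parameter rival, a *true*
exponential sample loses the AICc race with probability $\approx e^{-2}$
by chance, and at very large $n$ the selection will eventually resolve the
simulator's finite-arena corrections; the exponential-wins prediction is
therefore evaluated at the scale of the study's pooled samples
($n = 2000$) and as a majority outcome over five replicate walks. Second,
the per-individual published table is audited arithmetically: recomputing
pairwise AICc weights from the printed log-likelihoods reproduces most
rows to the printed precision, while a minority of rows (1, 16, 23) are
internally inconsistent under any standard AIC/AICc convention and one of
them reverses the favored model; the package reports recomputed values and
leaves the printed ones in the bundled table.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
sizes quoted above — $10^4$-step walks for distributional comparisons,
$20 \times 500$ steps for recovery, $10^5$ draws for sampler validation,
$400^2$ grids for the optimizer oracle — sizes chosen so each check is
decisively more precise than the tolerance it guards.
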