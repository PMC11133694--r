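---
title: "Energy-landscape analysis of multi-network brain activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energyscape)
```

## The model

The pipeline treats the joint activity of $N$ brain networks at one time
point as a binary pattern $\sigma \in \{-1,+1\}^N$ ($+1$ active, $-1$
inactive). The pairwise maximum-entropy model (MEM) is the least-structured
distribution that reproduces the empirical mean activity
$\langle\sigma_i\rangle$ and mean co-activation
$\langle\sigma_i\sigma_j\rangle$. It is the Ising model of statistical
physics: each pattern has statistical energy

$$E(\sigma) = -\sum_i h_i \sigma_i
  - \tfrac12 \sum_{i \neq j} J_{ij}\sigma_i\sigma_j ,$$

with baseline activities $h_i$ and symmetric couplings $J_{ij}$
(zero diagonal), and occurs with Boltzmann probability
$P(\sigma) \propto e^{-E(\sigma)}$. Energy here is a statistical quantity
— a log-probability up to sign and constant — not metabolic cost. Lower
energy means more frequent.

Everything downstream is enumeration over the $2^N$ patterns. With the
study-scale $N = 9$ that is 512 patterns, so exact computation (no
mean-field or pseudo-likelihood approximations) is used throughout; the
implementation caps $N$ at 20 and is comfortable to about 14.

### Assumptions

* Time points are exchangeable for **fitting** (the MEM is a stationary
  model; temporal order matters only for the dynamics measures).
* Binarization at the group-mean threshold preserves the signal of
  interest. Values exactly at the threshold map to inactive; thresholds
  are computed once per group on the concatenated matrix, not per subject,
  because one model is fitted per group.
* One model per group on concatenated data. A per-subject fitting mode is
  deliberately not offered; 140 time points cannot constrain 45 coupling
  parameters.

## Fitting

`fit_pairwise_mem()` runs maximum-likelihood gradient ascent: at each
iteration the model moments are recomputed exactly by enumeration and the
parameters move along the moment mismatch,
$h_i \mathrel{+}= \varepsilon(\langle\sigma_i\rangle -
\langle\sigma_i\rangle_m)$ and likewise for $J_{ij}$. The fixed point is
exact moment matching, and because the pairwise MEM is identifiable from
its first two moments, fitting on the enumerated moments of a known model
recovers that model — the package's core self-consistency property, held
to $10^{-4}$ at tolerance $10^{-8}$ in the test suite.

Numerical choices:

* **Initialization** at the independent closed form $h_i =
  \operatorname{atanh}\langle\sigma_i\rangle$, $J = 0$ — the $R = 0$
  reference model, so the accuracy measure starts at 0 and climbs.
* **Step size** defaults to 0.1 and is halved whenever the gap grows
  (plain overshoot damping, `adapt_lr = TRUE`). With damping off, a gap
  that grows tenfold between 100-iteration checkpoints aborts with an
  error naming the learning rate.
* **Convergence** at a maximum absolute moment gap below `tol` (default
  $10^{-5}$), `max_iter` default $5\times10^4$. At $N = 9$ on study-sized
  data a fit typically converges in a few hundred to a few thousand
  iterations (about a second).
* Means at exactly $\pm 1$ are clamped to magnitude $1 - 10^{-9}$ with a
  warning before the `atanh`.

Goodness of fit follows the two-divergence construction:
$D_1$ is the Kullback–Leibler divergence (base-2, bits) from the empirical
pattern distribution to the independent model, $D_2$ the divergence to the
pairwise model, and $R = (D_1 - D_2)/D_1$ is the fraction of the
independent model's shortfall that the couplings remove: 1 when the
pairwise model reproduces the data exactly, 0 when couplings add nothing.
Zero-frequency patterns contribute nothing ($0\log 0 = 0$). A Pearson
correlation between model probabilities and empirical frequencies over all
$2^N$ patterns is reported alongside.

## The landscape

Patterns form the vertices of an $N$-hypercube; edges join patterns one
flip apart. Local minima are patterns strictly below all $N$ neighbors.
Basins are found by steepest descent — repeatedly move to the
lowest-energy neighbor while one is strictly lower — and the basin size is
the fraction of the $2^N$ patterns draining to each minimum.

**Tie-breaking.** For generic parameters exact energy ties have measure
zero, but toy landscapes (and tests) hit them. When several equally lowest
strictly-lower neighbors exist, the descent flips the **highest-index
network**. This rule is deterministic and equivariant under a global
activity flip, so a perfectly symmetric double well splits its basins
exactly 0.5/0.5 — which symmetry demands, and which an index-ordered rule
(e.g. "smallest pattern index") would violate by funnelling both mixed
patterns into the all-inactive well.

The disconnectivity tree sweeps an energy threshold downward through the
sorted unique energies, removing patterns at or above the threshold; two
minima separate at the highest threshold at which no surviving path joins
them. That branch energy equals the minimax over connecting paths of the
maximum energy en route — verified in the tests against an exhaustive
path-search oracle. The implementation processes patterns in ascending
energy order with union–find, recording each merge of two minima-bearing
components; the result is stored in `hclust`-compatible `merge`/`height`
form and exports to Newick with branch lengths
(parent threshold − child energy).

A degenerate, perfectly flat landscape has no strict minimum; this is
reported as an explicit warning/error rather than a guess.

**States.** Minima are grouped into brain states either by an explicit
mapping (the default when reproducing a published grouping — e.g. six
minima into states {1,2,4}, {3,5}, {6}) or by cutting the tree below its
$k-1$ highest branch points (`k = 3` by default). States are renumbered by
their deepest minimum so state 1 always contains minimum 1. The automatic
cut exists because a grouping "according to the hierarchical structure" is
otherwise irreproducible from a verbal description.

## Dynamics measures

Each time point maps pattern → basin → state; runs never cross subject
boundaries. Seven per-subject measures are computed:

* **appearance frequency** — time points in the state / $T$;
* **mean duration** — average maximal-run length, in time points
  (multiply by the repetition time, default 3 s, for seconds);
* **mean energy** — the average energy of the *visited patterns* over the
  state's time points, not the state's minimum energy ("across all time
  points" is read at time-point resolution);
* **total / direct / indirect transition frequency** per unordered state
  pair, and **in/out frequency** per state, all as fractions of the total
  transition count.

**Indirect transitions.** A transition is indirect when it is routed
through a brief excursion into a third state: scanning the
run-length-compressed sequence left to right, a triple $(A, C, B)$ with
$A \neq B$, $C \notin \{A,B\}$ and dwell$(C) \le$ `d_max` (default 1 time
point) counts as one indirect $A \to B$ and replaces its two constituent
direct steps; remaining adjacent run pairs are direct. This is the minimal
reading under which direct + indirect = total holds exactly; overlapping
triples resolve greedily left to right. The dwell cap is configurable and
is a modelling choice, not a claim about any particular prior
implementation.

## Simulation

`metropolis_walk()` runs the standard Metropolis chain: from a uniformly
drawn start, propose one of the $N$ neighbors with probability $1/N$ and
accept with $\min(1, e^{E_\text{cur} - E_\text{prop}})$. A rejected
proposal keeps the pattern and **consumes a time step** — dwell-time
measures need a defined clock, and the standard chain provides one.
Detailed balance with the enumerated Boltzmann distribution is asserted
exactly on the explicit $2^N \times 2^N$ kernel in the tests, and
$10^6$-step walks on study-size landscapes stay within total-variation
0.015 of the enumerated law (bound 0.03 in the acceptance suite). The
default walk length is $10^5$ steps. Group comparison of simulated
dynamics uses count tables (time points per state, transition counts per
pair) in chi-square tests with post-hoc adjusted residuals, since relative
frequencies are not themselves chi-square testable.

## Group statistics

Two-sample comparisons use the pooled-variance Student $t$
($df = n_1 + n_2 - 2$); Welch's form is available by flag. The
equal-variance form is the one under which a published demographic table
(means ± SD at $n = 30/30$) reproduces its printed $t$ values within 1%:

```{r table-t}
t_from_summary(28.7, 1.3, 30, 22.5, 2.5, 30)   # printed: 12.01
t_from_summary(43.03, 10.3, 30, 21.53, 6.6, 30) # printed: 9.58
```

Multiple comparisons use Bonferroni within **declared families** — one
family per measure type (3 states for occupancy measures, 3 pairs for
transition measures), declared explicitly because no published family
sizes exist to follow. Chi-square post-hoc uses the adjusted standardized
residual $(O-E)/\sqrt{E(1-\text{row}/n)(1-\text{col}/n)}$ against a
standard normal, Bonferroni-corrected across cells. Behavior correlations
are plain Pearson $r$ per group, restricted to measures that survived the
group comparison.

## The synthetic-data generator

Real cohort data for this analysis are access-restricted, so the package
ships a generator whose output has the statistical structure the analysis
assumes, with known ground truth:

* **Models**: random MEMs with $h_i \sim \mathcal N(0, 0.3^2)$ and
  $J_{ij} \sim \mathcal N(0, 0.3^2)$ by default. At $N=9$ these scales
  produce 3–9 local minima with energy barriers of 1–3 units — landscapes
  qualitatively like the fitted ones.
* **Dynamics**: `markov` mode runs the same Metropolis kernel mixed with a
  self-repeat probability (`persistence`, default 0.7). The lazy chain
  keeps the Boltzmann stationary law exactly while producing dwell times
  of a few volumes at TR = 3 s. Real time-series autocorrelation is not
  characterized anywhere to copy, so the default is a judgment call, fixed
  once.
* **Observation model**: continuous signal = pattern value × `snr` + unit
  Gaussian noise, zero baseline (default `snr = 2`, about 98% of values
  recovered by mean-thresholding; `snr = 10` recovers over 99%). This
  makes the group-mean binarization the correct decoder with a known
  answer — the property the binarize tests exploit.
* **Behavior**: score = intercept + slope × (subject's value of a named
  dynamics measure, computed from the noise-free generating sequence) +
  Gaussian noise. RAVLT-like defaults (intercept 20, slope 40, noise SD 5).
* **Group differences** can be planted two ways. `perturb_couplings()`
  shifts chosen $J$ entries — the mechanism mirroring altered network
  interactions; its footprint is spread across occupancy, duration and
  energy measures, because a coupling change moves the whole stationary
  law. For experiments that need a difference confined to one state
  pair's *transition rate*, `ground_truth(planted_transition = ...)`
  intervenes on the chain directly: with probability `reroute` a natural
  exit from a paired state toward the third state is redirected into the
  other paired state's deepest minimum, plus a small per-step `jump`
  probability between the paired states. Rerouting changes transition
  destinations but not exit times, so dwell structure is nearly untouched
  and the planted effect loads on exactly one pair. Design-time scans
  showed that no $J$-perturbation at study scale (30 subjects × 140
  volumes, where a subject shows only ~5–10 state transitions) can make a
  pair's transition share the dominant finding — the transition shares
  simply carry the largest sampling variance of all seven measures — which
  is why the direct mechanism exists.

What the generator does **not** emulate: hemodynamics, ICA unmixing
artifacts, spatially correlated noise, scanner drift, inter-subject
variability in the generating model, or non-stationarity. Passing tests
therefore demonstrate the pipeline's internal correctness and statistical
calibration under its own assumptions, not robustness to fMRI
preprocessing choices.

## Validation design and problem sizes

The test suite checks every stage against an independent oracle: hand
evaluation for energies and toy sequences; closed forms for single-network
models; exhaustive minimax path search for branch energies (50 random
landscapes at $N \le 4$); exact detailed balance for the sampler;
parameter recovery from exact moments (20 models, $N \in 3..6$, error
$< 10^{-4}$); and long-run frequencies against the enumerated law
($10^6$ steps, TV < 0.03). The statistical stage is validated on 500 null
cohorts (identical ground truth; family-wise false positives within the
binomial envelope of the nominal 5% per family) and 100 planted cohorts
(the planted pair's transition comparison is the most significant result
in ≥ 80% of runs, observed ≈ 95%). Null and planted runs are generated at
full study scale and evaluated at the pattern level with states fixed to
the ground-truth landscape, isolating the testing stage from refit
variability; the fit–landscape–measure–compare path is exercised
end-to-end separately.

## Known limitations

* Exact enumeration only: no support for $N$ much beyond 14.
* Binarization discards amplitude; only the mean-threshold scheme is
  implemented (no median or quantile variants).
* The indirect-transition rule and Bonferroni family layout are explicit
  conventions; alternative conventions would change the per-measure
  numbers (not the pipeline's calibration).
* Cross-group state matching relies on the groups sharing a minima
  structure (as when both landscapes derive from similar data); when
  fitted landscapes differ qualitatively, state labels are aligned only by
  deepest-minimum order and comparisons should be read with care.
* Mean durations are in time points; seconds require the repetition time,
  carried in the config (`tr_seconds`, default 3).
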