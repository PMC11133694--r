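# energyscape

Energy-landscape analysis of multi-network brain activity in R.

Resting-state fMRI studies often summarize brain dynamics as movement over
an *energy landscape*: the joint on/off activity of N large-scale networks
(DMN, salience, executive-control, sensorimotor, visual, auditory,
basal-ganglia, ...) at each time point is a binary pattern
σ ∈ {−1,+1}^N, and the pairwise maximum-entropy (Ising) model

    E(σ) = −Σᵢ hᵢσᵢ − ½ Σᵢ≠ⱼ Jᵢⱼσᵢσⱼ ,   P(σ) ∝ e^(−E(σ))

assigns each pattern a statistical energy from baseline activities `h` and
pairwise couplings `J` fitted to the data's first and second moments.
Local minima of `E` act as attractors; groups of minima define brain
states; the geometry (basins, saddle energies, disconnectivity tree) and
the state dynamics (occupancy, dwell time, transition rates) can then be
compared between clinical groups and correlated with behavior scores.

`energyscape` implements that pipeline end to end for cohorts of
network-by-time series:

* group-level binarization at network means and pattern-index encoding;
* exact (enumeration-based) MEM fitting by gradient ascent, with the
  R = (D₁−D₂)/D₁ accuracy measure;
* local minima, steepest-descent basins, disconnectivity tree (Newick
  export, base-graphics plot), and minima-to-state grouping;
* seven per-subject dynamics measures (appearance frequency, mean
  duration, mean energy, total/direct/indirect transition frequency,
  in/out frequency);
* Metropolis–Hastings simulation on the fitted landscape with the same
  measures and count-based chi-square group comparison;
* group statistics: pooled-variance t tests with Bonferroni families,
  chi-square with post-hoc adjusted residuals, behavior correlations;
* a synthetic-cohort generator with known ground truth (Boltzmann models,
  temporally persistent sampling, a linear behavior model, and optional
  planted group differences), so every stage is testable without any
  restricted data.

## Worked example

Generate a two-group synthetic cohort (30 subjects per group, 9 networks,
140 volumes — the scale of a typical resting-state study) with a planted
transition-rate difference between two brain states in the "AD" group,
then run the full per-group analysis:

```r
library(energyscape)

base  <- make_ground_truth_mem(9, field_scale = 0.3, coupling_scale = 0.3,
                               seed = 30)
truth <- ground_truth(
  list(HC = base, AD = base), persistence = 0.7,
  planted_transition = list(group = "AD", pair = c(1, 3),
                            reroute = 0.8, jump = 0.01),
  seed = 42)
cohort <- make_cohort(truth, n_subjects_per_group = 30,
                      t_per_subject = 140, snr = 2)

res <- run_group_analysis(cohort, default_run_config(mcmc_steps = 1e5))
#> group HC: MEM fit converged after 922 iterations (max moment gap 9.92e-06)
#> group HC: accuracy R = 0.902, Pearson r = 0.965
#> group HC: 6 local minima grouped into 3 states
#> group AD: MEM fit converged after 1098 iterations (max moment gap 9.95e-06)
#> group AD: accuracy R = 0.930, Pearson r = 0.984
#> group AD: 4 local minima grouped into 3 states
#> group comparison: 6 of 21 measures significant at corrected 0.05
```

R ≈ 0.9 means the pairwise couplings remove ~90% of the
independent-model's divergence from the empirical pattern distribution —
the model fits. The fitted HC landscape has six attractors:

```r
res$per_group$HC$basins
#> Basin map: 6 local minima
#>  label pattern    energy basin_size
#>      1     434 -4.796430 0.22460938
#>      2     275 -4.722391 0.27148438
#>      3     236 -4.561902 0.14648438
#>      4      12 -4.294688 0.24414062
#>      5     188 -4.101964 0.07617188
#>      6     244 -3.930933 0.03710938
```

and the most significant group difference is a state-pair transition
frequency, as planted (state labels refer to each group's own fitted
landscape):

```r
head(res$comparisons[order(res$comparisons$p),
                     c("measure", "mean1", "mean2", "t", "p_bonferroni")], 3)
#>                           measure      mean1      mean2         t p_bonferroni
#> 19        transition_frequency_1_2  0.1369777  0.5005195 -3.853480 0.0008812733
#> 17                   mean_energy_2 -2.5990878 -3.7085573  3.846813 0.0011475310
#> 4  direct_transition_frequency_1_2  0.1347554  0.4938528 -3.764656 0.0011740828
```

`write_newick(res$per_group$HC$tree)` exports the disconnectivity tree;
`plot(res$per_group$HC$tree)` draws it. Setting
`default_run_config(output_dir = "out")` persists every artifact
(fitted `h`/`J`, the 512-row landscape table with basin and state columns,
trees, measures, comparisons, a JSON summary and a log) as plain text.

Published summary tables can be checked without raw data:

```r
t_from_summary(28.7, 1.3, 30, 22.5, 2.5, 30)
#> [1] 12.05153
```

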