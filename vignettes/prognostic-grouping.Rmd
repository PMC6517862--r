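---
title: "Building prognostic systems by ensemble clustering of survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building prognostic systems by ensemble clustering of survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaccd)
```

## The problem

Cancer staging systems such as the AJCC TNM scheme stratify patients into a
small number of ordered groups with distinct prognosis. This package builds
such stratifications directly from registry-style survival data. The working
unit is not the patient but the **combination**: the cell of patients sharing
one level of each selected prognostic factor (e.g. `T1N0M0A1` — a small
tumor, no nodal disease, no metastasis, under 55 at diagnosis). Combinations
with fewer than 25 patients are discarded before analysis, because cell-level
survival estimates below that size are too unstable to stratify on.

The pipeline has four stages:

1. **Initial dissimilarities.** For every pair of combinations the survival
   difference is scored by the Gehan-Wilcoxon two-sample statistic, the
   censored-data generalization of the Wilcoxon test. Each cross-pair of
   patients scores +1/-1 when censoring leaves no doubt who survived
   longer, 0 otherwise; the statistic `w` is the sum, its permutation
   variance comes from the pooled per-subject scores
   (`Var(W) = n1 n2 sum(U^2) / (N(N-1))`), and the dissimilarity is the
   Cohen-type effect size `d = |w/sqrt(Var W)| / sqrt(n1 + n2)`. This
   effect size is scale-free, symmetric, and exactly zero for identical
   cohorts — the three properties the later stages rely on. The formula is
   pluggable (`initial_dissimilarities(effect_fn = )`) should a different
   standardization be preferred.

2. **Ensemble-learned dissimilarities.** The initial matrix is refined by
   evidence accumulation: for each of `runs` (default 1000) ensemble runs a
   cluster count `k` is drawn uniformly from `[k_min, k_max]` (defaults 2
   and `n - 1`) and the combinations are partitioned around medoids; the
   learned dissimilarity of a pair is the fraction of runs separating them.
   Our PAM is the classical two-phase algorithm — greedy BUILD, then
   best-improvement SWAP until no single exchange lowers the objective —
   with all ties broken by lowest index, so it is fully deterministic given
   the matrix and `k`. Determinism has a useful consequence: one partition
   per distinct `k` suffices, and the ensemble is memoized accordingly.
   We also evaluated randomized-initialization PAM and per-run item
   subsampling as ensemble perturbations; neither improved latent-group
   recovery on the synthetic benchmark (the SWAP phase largely erases the
   initialization), so the simpler declared scheme stands.

3. **Hierarchical clustering.** Complete linkage (via `stats::hclust`) on
   the learned matrix produces the dendrogram. Because co-association
   values are multiples of `1/runs`, learned matrices contain many exact
   ties; `fit_prognostic_system()` adds `eps * d0` (initial
   dissimilarities, `eps` below half the co-association grid step) purely
   as a tie-break. The perturbation provably cannot reorder distinct
   learned values, so it only replaces `hclust`'s arbitrary row-order
   tie-breaking with a data-driven one.

4. **Cutting by the concordance index.** Every cut of the dendrogram into
   `g` groups yields a candidate stratification; patients are assigned
   their group number (groups renumbered so that pooled 5-year
   Kaplan-Meier survival strictly decreases) as an ordinal risk score, and
   Harrell's C-index over all patients measures how well that score orders
   survival. The C-index is invariant to monotone transforms, so the
   ordinal encoding is the minimal choice consistent with "higher group =
   shorter predicted survival". The C-index curve rises steeply while real
   risk structure is being resolved and then plateaus; the selected number
   of groups `n*` is the largest *knee* of the curve whose cut is
   *admissible*.

## Selection rules and numerical choices

**Knee detection.** A knee is an interior point whose discrete second
difference falls below `-0.25` times the mean absolute first difference of
the curve. The threshold is exposed (`drop`); the curve itself is always
part of the fitted object so the choice can be reviewed visually, which is
how such knees are read in practice.

**Admissibility.** A cut qualifies only if (i) no two of its pooled group
Kaplan-Meier curves *cross* — a sign change of `S_A(t) - S_B(t)` beyond
`tol` (default 0) on the union of step times within the common follow-up —
and (ii) the group 5-year rates are strictly decreasing. Touching without
crossing is deliberately not a crossing; the published practice judges
overlap visually and we chose the sharper, reproducible reading. Rule (ii)
means that groups indistinguishable at five years are not counted as
separate strata; it is what collapses a cohort with no survival signal to a
single group instead of letting the no-knee fallback return the trivial
finest admissible cut. `n*` is the largest knee at or below the largest
admissible cut, falling back (with a warning) to that cut itself when no
knee qualifies.

**Tie conventions.** Registry follow-up is reported in whole months, so
ties are everywhere and the tie rules matter. In the Gehan scoring a pair
is indeterminate unless one subject's *event* strictly precedes the other's
observation. In the C-index, comparable pairs are those whose earlier
observed time belongs to an event, including equal-time pairs where exactly
one subject died; prediction ties count 0.5; equal-time pairs of two deaths
with *different* predictions count as comparable-tied (0.5), and with equal
predictions are excluded (`tied_events = FALSE` disables the tied-death
convention entirely).

**Comparing two systems.** `compare_c()` tests the difference of two
C-indices on the same patients. The variance of the paired difference is
estimated by the jackknife over subjects, computed in closed form from each
subject's pair contributions (removing a subject only subtracts its
concordant/discordant/tied counts), which makes the leave-one-out deltas
exact rather than approximated by refits. The AJCC comparison
(`compare_with_ajcc()`) scores the ordinal stages I < II < III < IVA < IVB
as the competing risk score; the combination-level association uses
Spearman's rank correlation with midranks and the t approximation — over
combinations, unweighted, which is the convention under which the bundled
39-combination table reproduces its published correlation.

## The synthetic benchmark

Real registry extracts of the kind this pipeline targets sit behind
data-use agreements, so validation runs on a synthetic cohort generator
with known latent structure. `default_benchmark()` emulates the *shape* of
a well-differentiated thyroid cancer extract: 40 combinations of
T × N × M × A, heavily unbalanced log-uniform cell sizes (floor 25, upper
bound 2300, making the expected cohort 20,000 patients), five latent risk
groups with 5-year disease-specific survivals of about 0.995, 0.96, 0.90,
0.75 and 0.45 (monthly exponential hazards solved from
`exp(-60 * lambda)`), uniform accrual over 84 months with an
administrative horizon of 143 months (so censored follow-up has its median
near 90 months), and observation floored to whole months to reproduce
registry tie structure. Latent groups follow a crude T/N/M/A severity
ranking so the truth is clinically coherent.

What the generator does *not* emulate: death-certificate misclassification,
registry coding quirks, non-exponential hazard shapes in the default (a
Weibull shape parameter is available), and covariate-dependent censoring.
Passing recovery tests therefore demonstrates that the pipeline extracts
the structure its model family describes, not that it is robust to those
real-data pathologies.

One feasibility property of this design is worth stating plainly, because
it bounds what any method can achieve on it. A combination at the
25-patient floor in a low-risk group is often *statistically ambiguous*:
with ~100 months of follow-up, a 25-patient cell expects about 0.2 deaths
under the 0.995 group and 1.7 under the 0.96 group, so even an oracle that
knows the true group hazards and assigns each cell by maximum likelihood
misassigns one or more floor-sized cells in most replicates. Two
misassigned cells out of 40 already push the adjusted Rand index against
the truth below 0.9. Perfect recovery of *every* cell on this benchmark is
therefore not an attainable bar for the clustering; the suite reports the
achieved recovery rate, and the three-group validation design (adjacent
hazard ratios of 4, at least 100 patients per cell) is the setting in which
near-certain recovery is a fair requirement and is met.

## Problem sizes and determinism

The test suite and examples run the full pipeline at the benchmark scale
(40 combinations, ~20,000 patients, 1000 ensemble runs) in a few seconds
per fit: Gehan statistics and the C-index are computed from aggregated
(risk, time, event) count tables rather than patient pairs, pooled group
curves reuse a shared combination-by-time count matrix, and ensemble
partitions are memoized per `k`. All randomness flows from explicit seeds
(`sim_design(seed = )`, `ensemble_learn(seed = )` with counter-based
per-run seeds so extending `runs` never reshuffles earlier draws), and a
fixed seed reproduces every artifact byte-for-byte.

## A worked example

```{r example, eval = FALSE}
sim <- generate_cohort(default_benchmark(seed = 3))
sys <- fit_prognostic_system(sim$cases, runs = 1000, seed = 3)
glance(sys)          # n*, C-index at n*, largest admissible cut
tidy(sys)            # combination -> group assignment with 5-year rates
autoplot(sys, "km")  # group survival curves
compare_with_ajcc(sys)$comparison
```

## Known limitations

- The ensemble perturbation is the declared uniform-`k` scheme; because
  PAM is deterministic, the learned matrix is a weighted average over at
  most `k_max - k_min + 1` distinct partitions, and its resolution is
  limited accordingly.
- BUILD+SWAP PAM is a local search. On a few percent of small random
  matrices it terminates in a swap-optimal but globally suboptimal medoid
  set; this is a property of the algorithm (the reference implementation
  in the `cluster` package lands in the same local optima), not of this
  implementation.
- The C-index is computed at patient level with group number as an ordinal
  score; alternative encodings (e.g. size-weighted combination-level
  scores) are not implemented.
- Confidence bands on the group curves and time-dependent concordance are
  out of scope.
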