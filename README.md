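# eaccd

Data-driven prognostic systems for cancer survival data by ensemble
clustering.

## What it does

Cancer staging assigns each patient a small ordered group number that
predicts survival. This package builds such stratifications directly from
patient-level registry data. Patients are first partitioned into
**combinations** — the cells defined by one level of each prognostic factor
(tumor size T, nodal status N, distant metastasis M, dichotomized age A,
optionally histology H), e.g. `T1N0M0A1` — and cells with fewer than 25
patients are dropped. The pipeline then:

1. scores every pair of combinations with a **Gehan–Wilcoxon effect size**
   `d = |W / sqrt(Var W)| / sqrt(n1 + n2)`, where `W` sums the ±1 scores of
   cross-pairs whose survival order is definite under censoring and
   `Var(W) = n1 n2 Σ U_k² / (N(N−1))` is the permutation variance of the
   pooled per-subject scores;
2. refines these dissimilarities by **evidence accumulation**: repeated
   two-phase PAM (greedy BUILD + best-improvement SWAP, deterministic
   tie-breaks) partitions at cluster counts drawn uniformly from
   `[k_min, k_max]`; the learned dissimilarity of a pair is the fraction
   of runs separating them;
3. clusters the combinations by **complete linkage** into a dendrogram;
4. cuts the dendrogram at every size `g`, renumbers groups by decreasing
   pooled 5-year Kaplan–Meier survival, scores each cut with **Harrell's
   C-index** (group number as ordinal risk), and selects `n*` as the
   largest knee of the C-index curve whose cut has non-crossing,
   strictly separated group survival curves.

The result is a prognostic system: the dendrogram, the combination→group
map, the C-index, and per-group survival curves. Companions include the
**AJCC 8th-edition staging rule** for well-differentiated thyroid cancer,
contingency/association analyses between a fitted grouping and AJCC
staging (Spearman rank correlation over combinations), a **jackknife test
for the difference of two C-indices** on the same patients, and a
**synthetic SEER-like cohort generator** with known latent risk groups for
validation. The tables of a published thyroid-cancer stratification are
bundled as fixtures (`thyroid_table2()`, `thyroid_contingency()`).

## Worked example

```r
library(eaccd)

sim <- generate_cohort(default_benchmark(seed = 3))   # 25,080 patients, 40 cells
sys <- fit_prognostic_system(sim$cases, runs = 1000, seed = 3)
glance(sys)
#> # A tibble: 1 × 5
#>   n_groups c_index g_valid n_combinations n_cases
#>      <int>   <dbl>   <int>          <int>   <int>
#> 1        5   0.830       5             40   25080

sys$group_summary
#> # A tibble: 5 × 4
#>   group n_combinations n_cases five_year
#>   <int>          <int>   <dbl>     <dbl>
#> 1     1              8    7452     0.995
#> 2     2              7    3283     0.959
#> 3     3              9    5245     0.898
#> 4     4              8    3442     0.747
#> 5     5              8    5658     0.442
```

The selection found five prognostic groups (`n_groups`) whose pooled
5-year survival rates (0.995 … 0.442) recover the generator's latent
targets (0.995, 0.96, 0.90, 0.75, 0.45); the ordinal grouping orders
patient survival with a C-index of 0.830, and `g_valid` confirms five is
also the largest cut with non-crossing, separated curves. Comparing
against AJCC staging on the same patients:

```r
compare_with_ajcc(sys)$comparison
#> C-index comparison: c1 = 0.83 vs c2 = 0.7249
#>   delta = 0.1052 , z = 42.17 , p = 0
```

`tidy(sys)` returns the combination→group table, `autoplot(sys, "km")`
draws the group survival curves, `autoplot(sys, "cindex")` the C-index
curve with `n*` marked, and `run_pipeline()` drives multi-factor-set /
multi-age-cutoff analyses from a YAML config, writing CSV/JSON/Newick
artifacts and a manifest.

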