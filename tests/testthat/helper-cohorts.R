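# Programmatic fixtures shared across test files.

# minimal valid case table
make_cases <- function(n_cases = 10, seed = 1) {
  set.seed(seed)
  v <- tnm_vocab()
  tibble::tibble(
    id = sprintf("c%03d", seq_len(n_cases)),
    t = sample(setdiff(v$t, "T0"), n_cases, replace = TRUE),
    n = sample(v$n, n_cases, replace = TRUE),
    m = sample(v$m, n_cases, replace = TRUE),
    age = sample(20:85, n_cases, replace = TRUE),
    surv_months = sample(0:120, n_cases, replace = TRUE),
    event = stats::rbinom(n_cases, 1, 0.3)
  )
}

# three-latent-group design: adjacent hazard ratios 4, cells of >= 100
three_group_design <- function(seed, n_per_group = 3, size = 150) {
  v <- tnm_vocab()
  cells <- tidyr::expand_grid(t = c("T1", "T2", "T3"),
                              n = v$n[seq_len(n_per_group)]) |>
    dplyr::mutate(m = "M0", a = "A1", size = size,
                  group = as.integer(match(t, c("T1", "T2", "T3"))))
  sim_design(cells, hazards = c(0.002, 0.008, 0.032), seed = seed)
}

# well-separated cohort as combination tibble + truth
three_group_cohort <- function(seed, size = 150) {
  des <- three_group_design(seed, size = size)
  sim <- generate_cohort(des)
  list(
    combinations = build_combinations(sim$cases),
    truth = sim$truth
  )
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

table2_pairs <- function() {
  thyroid_table2()
}
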