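#' Fit a prognostic system from patient-level cases
#'
#' Chains the whole pipeline for one factor set: build combinations, apply
#' the minimum-size filter, compute Gehan-Wilcoxon initial dissimilarities,
#' ensemble-learn the dissimilarities, cluster with complete linkage and
#' select the optimal number of groups from the C-index curve.
#'
#' @param cases Case tibble (see [read_cases()]).
#' @param factors Factor set, subset of `c("T","N","M","A","H")`.
#' @param age_cutoff Age cutoff in years (default 55).
#' @param min_count Minimum combination size (default 25).
#' @param runs,k_min,k_max Ensemble parameters (see [ensemble_learn()]).
#' @param seed Master seed for the ensemble.
#' @param tol,drop Selection parameters (see [select_system()]).
#' @param tied_events Passed to [harrell_c()].
#' @return A `prognostic_system` with the kept combinations attached as
#'   attribute `combinations` and the discarded ones as `discarded`.
#' @export
fit_prognostic_system <- function(cases, factors = c("T", "N", "M", "A"),
                                  age_cutoff = 55, min_count = 25,
                                  runs = 1000, k_min = 2, k_max = NULL,
                                  seed = 1, tol = 0, drop = 0.25,
                                  tied_events = TRUE) {
  combs <- build_combinations(cases, factors = factors,
                              age_cutoff = age_cutoff)
  flt <- filter_min_count(combs, min_count = min_count)
  if (nrow(flt$kept) < 2) abort("Fewer than two combinations pass the size filter.")
  d0 <- initial_dissimilarities(flt$kept)
  if (is.null(k_max)) k_max <- nrow(d0) - 1
  d1 <- ensemble_learn(d0, runs = runs, k_min = k_min, k_max = k_max,
                       seed = seed)
  # Co-association values are multiples of 1/runs, so learned matrices are
  # heavily tied; break exact ties by the initial dissimilarities with a
  # perturbation smaller than half the learned grid step, which provably
  # never reorders distinct learned values.
  d_link <- d1
  if (max(d0) > 0) {
    d_link <- d1 + (min(1e-4, 1 / (4 * runs)) / max(d0)) * d0
  }
  dend <- complete_linkage(d_link)
  sys <- select_system(dend, flt$kept, tol = tol, drop = drop,
                       tied_events = tied_events)
  attr(sys, "combinations") <- flt$kept
  attr(sys, "discarded") <- flt$discarded
  attr(sys, "factors") <- normalize_factors(factors)
  attr(sys, "age_cutoff") <- age_cutoff
  sys
}

# patient-level vectors for a kept combination set
patient_level <- function(combinations) {
  list(
    label = rep(combinations$label, combinations$size),
    times = unlist(purrr::map(combinations$data, "surv_months"),
                   use.names = FALSE),
    events = unlist(purrr::map(combinations$data, "event"), use.names = FALSE)
  )
}

#' Compare a prognostic system with AJCC 8th-edition staging
#'
#' Stages every kept combination with [ajcc8_stage()], then (i) tests the
#' difference in patient-level C-index between the system's group numbers
#' and the ordinal AJCC stages via [compare_c()], and (ii) computes the
#' combination-level Spearman association between grouping and staging.
#'
#' @param system A `prognostic_system` from [fit_prognostic_system()]
#'   whose factor set contains T, N, M and A.
#' @return List with `comparison` (`cindex_comparison`), `association`
#'   (`cor_result`), `table` (`contingency_table`) and `assignments`
#'   (tibble: label, group, stage, size).
#' @export
compare_with_ajcc <- function(system) {
  combs <- attr(system, "combinations")
  if (is.null(combs)) abort("System lacks attached combinations.")
  if (!all(c("t", "n", "m", "a") %in% names(combs))) {
    abort("AJCC comparison needs factors T, N, M and A.")
  }
  assignments <- tibble::tibble(
    label = combs$label,
    group = unname(system$group_of[combs$label]),
    stage = ajcc8_stage(combs$t, combs$n, combs$m, combs$a),
    size = combs$size
  )
  pl <- patient_level(combs)
  idx <- match(pl$label, assignments$label)
  cmp <- compare_c(assignments$group[idx], as.integer(assignments$stage)[idx],
                   pl$times, pl$events,
                   tied_events = system$params$tied_events)
  list(
    comparison = cmp,
    association = association(assignments),
    table = contingency(assignments),
    assignments = assignments
  )
}

#' Compare two prognostic systems on their common patients
#'
#' Both systems' group numbers are evaluated as risk predictors on the
#' intersection of their member patients (matched by case id) and the
#' paired C-index difference is tested with [compare_c()].
#'
#' @param system1,system2 `prognostic_system` objects fit on overlapping
#'   cohorts.
#' @return A `cindex_comparison`.
#' @export
compare_systems <- function(system1, system2) {
  pat <- function(sys) {
    combs <- attr(sys, "combinations")
    tibble::tibble(
      id = unlist(purrr::map(combs$data, "id"), use.names = FALSE),
      time = unlist(purrr::map(combs$data, "surv_months"), use.names = FALSE),
      event = unlist(purrr::map(combs$data, "event"), use.names = FALSE),
      group = rep(unname(sys$group_of[combs$label]), combs$size)
    )
  }
  p1 <- pat(system1)
  p2 <- pat(system2)
  common <- intersect(p1$id, p2$id)
  if (length(common) < 2) abort("No common patients between the systems.")
  i1 <- match(common, p1$id)
  i2 <- match(common, p2$id)
  compare_c(p1$group[i1], p2$group[i2], p1$time[i1], p1$event[i1],
            tied_events = system1$params$tied_events)
}

default_config <- function() {
  list(
    factor_sets = list(c("T", "N", "M", "A")),
    age_cutoffs = 55,
    min_count = 25,
    ensemble = list(runs = 1000, k_min = 2, k_max = NULL),
    tol = 0,
    knee_drop = 0.25,
    seed = 1
  )
}

#' Run the full analysis pipeline and write artifacts
#'
#' Drives one or more prognostic-system fits from a single configuration:
#' for every requested factor set and age cutoff a system is fit and its
#' artifacts written (groups CSV, C-index curve CSV, long-format group KM
#' curves CSV, merge table, Newick dendrogram when \pkg{ape} is installed,
#' and a JSON report). Systems whose factor set contains T, N, M and A
#' also get an AJCC comparison report. When several analyses are
#' requested, cases are first restricted to those whose combination passes
#' the size filter under every analysis (so the C-index comparisons are
#' paired on identical patients), and all pairwise system comparisons are
#' written. A machine-readable manifest records the configuration and its
#' hash.
#'
#' @param config Named list or path to a YAML file. Recognized keys:
#'   `input` (case CSV path) or `simulate` (list passed to
#'   [default_benchmark()]), `factor_sets` (list of character vectors),
#'   `age_cutoffs`, `min_count`, `ensemble` (`runs`, `k_min`, `k_max`),
#'   `tol`, `knee_drop`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted `systems` and `comparisons`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  cfg$factor_sets <- lapply(cfg$factor_sets, normalize_factors)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$input)) {
    cases <- read_cases(cfg$input)
  } else if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    sim$seed <- sim$seed %||% cfg$seed
    design <- do.call(default_benchmark, sim)
    cases <- generate_cohort(design)$cases
  } else {
    abort("Config must provide `input` or `simulate`.")
  }

  analyses <- tidyr::expand_grid(
    fs = cfg$factor_sets,
    cutoff = cfg$age_cutoffs
  )
  analyses$name <- purrr::map2_chr(analyses$fs, analyses$cutoff, function(f, a) {
    paste0(paste(f, collapse = ""), "_cut", a)
  })
  if (anyDuplicated(analyses$name)) abort("Duplicate analyses in config.")

  # restrict to cases that pass the size filter under every analysis so
  # paired comparisons share identical subjects
  if (nrow(analyses) > 1) {
    keep_ids <- purrr::map(seq_len(nrow(analyses)), function(i) {
      combs <- build_combinations(cases, factors = analyses$fs[[i]],
                                  age_cutoff = analyses$cutoff[i])
      kept <- filter_min_count(combs, cfg$min_count)$kept
      unlist(purrr::map(kept$data, "id"), use.names = FALSE)
    })
    common <- Reduce(intersect, keep_ids)
    cases <- cases[cases$id %in% common, , drop = FALSE]
  }

  systems <- purrr::map(seq_len(nrow(analyses)), function(i) {
    sys <- fit_prognostic_system(
      cases, factors = analyses$fs[[i]], age_cutoff = analyses$cutoff[i],
      min_count = cfg$min_count, runs = cfg$ensemble$runs,
      k_min = cfg$ensemble$k_min, k_max = cfg$ensemble$k_max,
      seed = cfg$seed, tol = cfg$tol, drop = cfg$knee_drop
    )
    write_system_artifacts(sys, file.path(out_dir, analyses$name[i]))
    sys
  })
  names(systems) <- analyses$name

  comparisons <- list()
  if (nrow(analyses) > 1) {
    for (i in seq_len(nrow(analyses) - 1)) {
      for (j in seq(i + 1, nrow(analyses))) {
        key <- paste(analyses$name[i], "vs", analyses$name[j])
        comparisons[[key]] <- compare_systems(systems[[i]], systems[[j]])
      }
    }
    jsonlite::write_json(
      purrr::map(comparisons, function(x) tidy(x)),
      file.path(out_dir, "system_comparisons.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }

  manifest <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    analyses = analyses$name,
    n_cases = nrow(cases)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(systems = systems, comparisons = comparisons))
}

write_system_artifacts <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(system), file.path(dir, "groups.csv"))
  readr::write_csv(system$curve, file.path(dir, "cindex_curve.csv"))
  readr::write_csv(group_curves_tbl(system), file.path(dir, "km_curves.csv"))
  export_merges(system$dendrogram, file.path(dir, "merges.csv"))
  if (requireNamespace("ape", quietly = TRUE)) {
    export_newick(system$dendrogram, file.path(dir, "dendrogram.newick"))
  }
  report <- list(
    n_groups = system$n_groups,
    c_index = system$c_index,
    g_valid = system$g_valid,
    knees = system$knees,
    factors = attr(system, "factors"),
    age_cutoff = attr(system, "age_cutoff"),
    group_summary = system$group_summary
  )
  ajcc <- tryCatch(compare_with_ajcc(system), error = function(e) NULL)
  if (!is.null(ajcc)) {
    report$ajcc <- list(
      delta = ajcc$comparison$delta,
      z = ajcc$comparison$z,
      p = ajcc$comparison$p,
      c_system = ajcc$comparison$c1,
      c_ajcc = ajcc$comparison$c2,
      spearman_rho = ajcc$association$rho,
      spearman_p = ajcc$association$p
    )
    readr::write_csv(ajcc$assignments, file.path(dir, "ajcc_assignments.csv"))
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
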