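test_that("the reader validates rows and reports exclusions", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    id = c("good", "badT", "badMonths"),
    t = c("T1", "T4NOS", "T2"), n = "N0", m = "M0", age = 50,
    surv_months = c(12, 12, -3), event = c(1, 0, 0)
  ), path)
  expect_message(cases <- read_cases(path), "Excluded 2")
  expect_equal(cases$id, "good")
  excl <- attr(cases, "exclusions")
  expect_equal(unname(excl["t"]), 1L)
  expect_equal(unname(excl["surv_months"]), 1L)
})

test_that("excluded rows can be captured in a side file with reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    id = c("a", "b"), t = c("T1", "Tx"), n = "N0", m = "M0",
    age = 50, surv_months = 1, event = 0
  ), path)
  suppressMessages(read_cases(path, side_file = side))
  rej <- readr::read_csv(side, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_equal(rej$id, "b")
  expect_match(rej$reason, "t")
})

test_that("degenerate files error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,t,n,m,age,surv_months,event", path)
  expect_error(read_cases(path), "Empty")
  writeLines(c("id,t", "x,T1"), path)
  expect_error(read_cases(path), "required")
})

test_that("write/read round trip is lossless", {
  sim <- generate_cohort(three_group_design(seed = 3, size = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cases(sim$cases, path)
  back <- read_cases(path, quiet = TRUE)
  expect_equal(back$id, sim$cases$id)
  expect_equal(back$surv_months, sim$cases$surv_months)
  expect_equal(back$event, sim$cases$event)
  expect_equal(back$t, sim$cases$t)
  expect_equal(back$age, as.numeric(sim$cases$age))
})

test_that("the pipeline writes a complete, reproducible artifact set", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(
    simulate = list(seed = 4, n_cells = 10, size_range = c(30, 200)),
    factor_sets = list(c("T", "N", "M", "A")),
    age_cutoffs = c(45, 55),
    ensemble = list(runs = 100, k_min = 2, k_max = NULL),
    seed = 4
  )
  res <- suppressWarnings(run_pipeline(cfg, out1))
  expect_named(res$systems, c("TNMA_cut45", "TNMA_cut55"))
  for (nm in names(res$systems)) {
    for (f in c("groups.csv", "cindex_curve.csv", "km_curves.csv",
                "merges.csv", "report.json")) {
      expect_true(file.exists(file.path(out1, nm, f)))
    }
  }
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "system_comparisons.json")))
  cmp <- res$comparisons[[1]]
  expect_s3_class(cmp, "cindex_comparison")

  # reruns are byte-identical
  suppressWarnings(run_pipeline(cfg, out2))
  for (f in c("manifest.json", "system_comparisons.json",
              file.path("TNMA_cut55", "report.json"),
              file.path("TNMA_cut55", "groups.csv"))) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("pipeline config via YAML file and AJCC report generation", {
  out <- withr::local_tempdir()
  yml <- withr::local_tempfile(fileext = ".yaml")
  cells <- tidyr::expand_grid(t = c("T1", "T3", "T4b"), a = c("A1", "A2")) |>
    dplyr::mutate(n = "N0", m = c(rep("M0", 4), "M1", "M1"),
                  size = 120L, group = as.integer(rank(paste(t, a))))
  sim <- generate_cohort(sim_design(cells, hazards = 0.0005 * 2^(1:6),
                                    seed = 6))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cases(sim$cases, csv)
  yaml::write_yaml(list(
    input = csv,
    factor_sets = list(c("T", "N", "M", "A")),
    min_count = 25,
    ensemble = list(runs = 100, k_min = 2),
    seed = 6
  ), yml)
  res <- suppressWarnings(run_pipeline(yml, out))
  rep <- jsonlite::read_json(file.path(out, "TNMA_cut55", "report.json"))
  expect_true(!is.null(rep$ajcc))
  expect_true(rep$ajcc$spearman_rho <= 1 && rep$ajcc$spearman_rho >= -1)
  expect_true(file.exists(file.path(out, "TNMA_cut55", "ajcc_assignments.csv")))
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  set.seed(2)
  d <- rand_dissimilarity(6)
  h <- complete_linkage(d)
  path <- withr::local_tempfile(fileext = ".newick")
  export_newick(h, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(d))
})
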