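# shared fixture: 3 well-separated latent groups, 9 combinations
prognosis_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- three_group_cohort(seed = 42, size = 200)
      cb <- cohort$combinations
      d0 <- initial_dissimilarities(cb)
      d1 <- ensemble_learn(d0, runs = 200, seed = 42)
      cache <<- list(cb = cb, truth = cohort$truth,
                     dend = complete_linkage(d1))
    }
    cache
  }
})

test_that("cuts partition the leaves and nest across g", {
  fx <- prognosis_fixture()
  n <- nrow(fx$cb)
  expect_equal(unname(cut_groups(fx$dend, 1)), rep(1L, n))
  expect_equal(sort(unname(cut_groups(fx$dend, n))), seq_len(n))
  prev <- cut_groups(fx$dend, 1)
  for (g in 2:n) {
    cur <- cut_groups(fx$dend, g)
    # refinement: members of one cur-cluster share one prev-cluster
    expect_true(all(tapply(prev, cur, function(x) length(unique(x))) == 1))
    prev <- cur
  }
  expect_error(cut_groups(fx$dend, 0), "between")
  expect_error(cut_groups(fx$dend, n + 1), "between")
})

test_that("groups are renumbered by decreasing pooled 5-year survival", {
  fx <- prognosis_fixture()
  og <- order_groups(cut_groups(fx$dend, 3), fx$cb)
  expect_equal(og$summary$group, 1:3)
  expect_true(all(diff(og$summary$five_year) < 0))
  expect_setequal(unique(og$group_of), 1:3)
  # latent ordering: group 1 must be the lowest-hazard latent group
  truth <- fx$truth$group[match(names(og$group_of), fx$truth$label)]
  expect_equal(unname(og$group_of), truth)
})

test_that("renumbering is a bijection on cluster ids", {
  fx <- prognosis_fixture()
  raw <- cut_groups(fx$dend, 4)
  og <- order_groups(raw, fx$cb)
  expect_equal(sort(unique(og$group_of)), seq_along(unique(raw)))
  tab <- table(raw, og$group_of)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("the C-index curve starts at exactly 0.5 and plateaus after the truth", {
  fx <- prognosis_fixture()
  cv <- c_index_curve(fx$dend, fx$cb)
  expect_equal(cv$c_index[1], 0.5)
  expect_true(all(cv$c_index >= 0 & cv$c_index <= 1))
  # steep rise to g = 3, then plateau
  expect_gt(cv$c_index[3] - cv$c_index[1], 0.1)
  expect_lt(max(cv$c_index) - cv$c_index[3], 0.01)
  # the full cut is within noise of the maximum on this fixture
  expect_lt(max(cv$c_index) - cv$c_index[nrow(cv)], 0.01)
})

test_that("curve crossing detection distinguishes ordering from crossing", {
  mk <- function(times, surv, t_max = max(times)) {
    structure(tibble::tibble(time = times, n_risk = NA, n_event = NA,
                             surv = surv),
              n0 = 100, t_max = t_max,
              class = c("km_curve", "tbl_df", "tbl", "data.frame"))
  }
  a <- mk(1:5, exp(-(1:5)))
  expect_false(overlap(a, a, tol = 0.001))
  b <- mk(1:5, exp(-2 * (1:5)))
  expect_false(overlap(a, b))
  expect_false(overlap(b, a))
  crossing <- mk(c(1, 3), c(0.95, 0.2))
  crossed <- mk(c(1, 3), c(0.5, 0.45))
  expect_true(overlap(crossing, crossed))
  expect_true(overlap(crossed, crossing))
  # touching without crossing is not overlap
  touch <- mk(1:5, c(0.9, 0.8, 0.7, 0.6, 0.5))
  above <- mk(1:5, c(0.95, 0.9, 0.7, 0.65, 0.6))
  expect_false(overlap(touch, above))
})

test_that("knee detection finds constructed elbows and ignores lines", {
  lin <- structure(tibble::tibble(g = 1:6, c_index = seq(0.5, 1, 0.1)),
                   class = c("cindex_curve", "tbl_df", "tbl", "data.frame"))
  expect_length(knees(lin), 0)
  elbow <- structure(
    tibble::tibble(g = 1:6, c_index = c(0.5, 0.7, 0.9, 0.9, 0.9, 0.9)),
    class = c("cindex_curve", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(knees(elbow), 3)
  fx <- prognosis_fixture()
  expect_true(3 %in% knees(c_index_curve(fx$dend, fx$cb)))
})

test_that("select_system recovers three well-separated groups exactly", {
  fx <- prognosis_fixture()
  sys <- select_system(fx$dend, fx$cb)
  expect_equal(sys$n_groups, 3)
  truth <- fx$truth$group[match(sys$groups$label, fx$truth$label)]
  expect_equal(ari(sys$groups$group, truth), 1)
  expect_true(all(diff(sys$group_summary$five_year) < 0))
  gl <- glance(sys)
  expect_equal(gl$n_groups, 3)
  expect_equal(gl$n_cases, sum(fx$cb$size))
  td <- tidy(sys)
  expect_equal(nrow(td), nrow(fx$cb))
})

test_that("no separation collapses to a single group", {
  dat <- tibble::tibble(id = as.character(1:60),
                        surv_months = rep(c(5, 9, 14), 20),
                        event = rep(c(1L, 0L, 1L), 20))
  cb <- tibble::tibble(
    label = c("T1N0", "T2N0"), size = 60L,
    data = list(dat, dplyr::mutate(dat, id = paste0("x", id)))
  )
  d <- initial_dissimilarities(cb)
  sys <- select_system(complete_linkage(d), cb)
  expect_equal(sys$n_groups, 1)
})

test_that("system artifacts are internally consistent", {
  fx <- prognosis_fixture()
  sys <- select_system(fx$dend, fx$cb)
  expect_equal(sort(unique(sys$groups$group)), seq_len(sys$n_groups))
  expect_equal(sum(sys$group_summary$n_cases), sum(fx$cb$size))
  expect_equal(sys$c_index, sys$curve$c_index[sys$n_groups])
  long <- group_curves_tbl(sys)
  expect_setequal(unique(long$group), seq_len(sys$n_groups))
  expect_true(all(long$surv >= 0 & long$surv <= 1))
})
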