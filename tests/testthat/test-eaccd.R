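test_that("identical member data gives zero initial dissimilarity", {
  dat <- tibble::tibble(id = c("a", "b"), surv_months = c(5, 9),
                        event = c(1, 0))
  cb <- tibble::tibble(label = c("x", "y"), size = 2L,
                       data = list(dat, dat))
  d <- initial_dissimilarities(cb)
  expect_equal(d["x", "y"], 0)
  expect_equal(diag(d), c(x = 0, y = 0))
})

test_that("initial dissimilarities separate distinct hazards", {
  set.seed(55)
  mk <- function(lam, n = 200) {
    tibble::tibble(id = as.character(seq_len(n)),
                   surv_months = floor(rexp(n, lam)),
                   event = 1L)
  }
  cb <- tibble::tibble(
    label = c("a", "b", "c"), size = 200L,
    data = list(mk(0.005), mk(0.005), mk(0.05))
  )
  d <- initial_dissimilarities(cb)
  expect_lt(d["a", "b"], d["a", "c"] / 3)
  expect_true(isSymmetric(d))
})

test_that("the matrix equals element-wise Gehan recomputation", {
  cohort <- three_group_cohort(seed = 8, size = 40)
  cb <- cohort$combinations[1:4, ]
  d <- initial_dissimilarities(cb)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      g <- gehan_wilcoxon(cb$data[[i]]$surv_months, cb$data[[i]]$event,
                          cb$data[[j]]$surv_months, cb$data[[j]]$event)
      expect_equal(d[i, j], g$effect_size)
    }
  }
})

test_that("pam saturates at k = n and matches the exhaustive scan at k = 1", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    d <- rand_dissimilarity(n)
    full <- pam_medoids(d, n)
    expect_equal(full$objective, 0)
    expect_equal(sort(full$medoids), seq_len(n))
    one <- pam_medoids(d, 1)
    expect_equal(one$objective, min(colSums(d)))
    expect_equal(one$medoids, unname(which.min(colSums(d))))
  }
})

test_that("pam agrees with a naive from-scratch BUILD+SWAP reimplementation", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    d <- rand_dissimilarity(n)
    mine <- pam_medoids(d, k)
    oracle <- brute_pam(d, k)
    expect_equal(mine$medoids, oracle$medoids)
    expect_equal(mine$objective, oracle$objective)
    expect_equal(canon_partition(mine$assignment),
                 canon_partition(oracle$assignment))
  }
})

test_that("pam's swap phase never worsens the greedy objective and is swap-optimal", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    k <- sample(2:4, 1)
    d <- rand_dissimilarity(n)
    res <- pam_medoids(d, k)
    med <- res$medoids
    obj <- function(m) sum(apply(d[, m, drop = FALSE], 1, min))
    for (m in med) {
      for (h in setdiff(seq_len(n), med)) {
        expect_gte(obj(c(setdiff(med, m), h)), res$objective - 1e-12)
      }
    }
  }
})

test_that("pam objectives typically coincide with cluster::pam", {
  skip_if_not_installed("cluster")
  set.seed(33)
  hits <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    n <- sample(5:9, 1)
    k <- sample(2:3, 1)
    d <- rand_dissimilarity(n)
    mine <- pam_medoids(d, k)$objective
    ref <- cluster::pam(stats::as.dist(d), k, variant = "original")
    refobj <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
    if (abs(mine - refobj) < 1e-9) hits <- hits + 1
  }
  # both are BUILD+SWAP local searches; rare divergent local optima allowed
  expect_gte(hits, 90)
})

test_that("ensemble learning recovers block structure of separated blobs", {
  labels <- paste0("L", 1:6)
  d <- matrix(10, 6, 6, dimnames = list(labels, labels))
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  # at the blob-count cluster number the co-association is exact
  le2 <- ensemble_learn(d, runs = 100, k_min = 2, k_max = 2, seed = 3)
  expect_equal(unname(le2[1:3, 1:3]), matrix(0, 3, 3))
  expect_equal(unname(le2[1:3, 4:6]), matrix(1, 3, 3))
  # over the full k range finer cuts split blobs internally, but the
  # between-blob contrast always dominates and the blobs are recovered
  le <- ensemble_learn(d, runs = 100, seed = 3)
  expect_lt(max(le[1:3, 1:3]), min(le[1:3, 4:6]))
  expect_gte(min(le[1:3, 4:6]), 0.9)
  expect_equal(unname(cutree(complete_linkage(le), 2)),
               rep(1:2, each = 3))
  expect_true(all(le >= 0 & le <= 1))
  expect_true(isSymmetric(le))
  expect_equal(diag(le), setNames(rep(0, 6), labels))
})

test_that("a single ensemble run yields a binary matrix and seeds reproduce", {
  set.seed(91)
  d <- rand_dissimilarity(7)
  one <- ensemble_learn(d, runs = 1, seed = 5)
  expect_true(all(one %in% c(0, 1)))
  a <- ensemble_learn(d, runs = 40, seed = 11)
  b <- ensemble_learn(d, runs = 40, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, ensemble_learn(d, runs = 40, seed = 12)))
})

test_that("complete linkage matches the from-scratch agglomerative oracle", {
  set.seed(45)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    d <- rand_dissimilarity(n)
    h <- complete_linkage(d)
    o <- brute_complete_linkage(d)
    expect_equal(h$height, o$heights)
    for (g in seq_len(n)) {
      mine <- canon_partition(unname(cutree(h, g)))
      ref <- canon_partition(o$partitions[[n - g + 1]])
      expect_equal(mine, ref)
    }
  }
})

test_that("two items merge at their dissimilarity; ultrametrics are fixed points", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h <- complete_linkage(d)
  expect_equal(h$height, 0.4)

  # ultrametric: two tight pairs joined at a higher level
  u <- matrix(0.9, 4, 4)
  u[1, 2] <- u[2, 1] <- 0.2
  u[3, 4] <- u[4, 3] <- 0.3
  diag(u) <- 0
  dimnames(u) <- list(letters[1:4], letters[1:4])
  hu <- complete_linkage(u)
  expect_equal(sort(hu$height), c(0.2, 0.3, 0.9))
  expect_true(all(diff(hu$height) >= 0))
})

test_that("three well-separated latent hazard groups are recovered", {
  hits <- 0
  reps <- 50
  for (s in seq_len(reps)) {
    cohort <- three_group_cohort(seed = 100 + s, size = 120)
    cb <- cohort$combinations
    d0 <- initial_dissimilarities(cb)
    d1 <- ensemble_learn(d0, runs = 200, seed = s)
    cl <- cutree(complete_linkage(d1), 3)
    truth <- cohort$truth$group[match(names(cl), cohort$truth$label)]
    if (ari(cl, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
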