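# Independent brute-force oracles: naive O(n^2)-or-worse reimplementations
# used only to check the package's efficient paths.

# Exhaustive pair scoring for Harrell's C with the package's tie rules.
brute_harrell <- function(risk, time, event, tied_events = TRUE) {
  n <- length(time)
  conc <- disc <- tied <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      earlier <- FALSE
      tied_outcome <- FALSE
      if (time[i] < time[j] && event[i] == 1) {
        earlier <- TRUE
      } else if (time[i] == time[j] && event[i] == 1 && event[j] == 0) {
        earlier <- TRUE
      } else if (time[i] == time[j] && event[i] == 1 && event[j] == 1 &&
                 i < j && tied_events && risk[i] != risk[j]) {
        earlier <- TRUE
        tied_outcome <- TRUE
      }
      if (!earlier) next
      if (tied_outcome) {
        tied <- tied + 1
      } else if (risk[i] > risk[j]) {
        conc <- conc + 1
      } else if (risk[i] < risk[j]) {
        disc <- disc + 1
      } else {
        tied <- tied + 1
      }
    }
  }
  total <- conc + disc + tied
  list(c = if (total > 0) (conc + 0.5 * tied) / total else NA_real_,
       conc = conc, disc = disc, tied = tied, n_comparable = total)
}

# Pairwise Gehan scores: +1 when a definitely outlives b.
gehan_score <- function(ta, ea, tb, eb) {
  if (tb < ta && eb == 1) return(1)
  if (ta < tb && ea == 1) return(-1)
  0
}

brute_gehan <- function(t1, e1, t2, e2) {
  w <- 0
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      w <- w + gehan_score(t1[i], e1[i], t2[j], e2[j])
    }
  }
  tt <- c(t1, t2)
  ee <- c(e1, e2)
  n <- length(tt)
  u <- vapply(seq_len(n), function(k) {
    sum(vapply(seq_len(n), function(l) {
      if (l == k) 0 else gehan_score(tt[k], ee[k], tt[l], ee[l])
    }, numeric(1)))
  }, numeric(1))
  var_w <- length(t1) * length(t2) * sum(u^2) / (n * (n - 1))
  list(w = w, var_w = var_w)
}

# Naive from-scratch BUILD + SWAP (recomputes every objective by scanning
# all points and candidate medoid sets).
brute_pam <- function(d, k) {
  n <- nrow(d)
  obj <- function(med) {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + min(sapply(med, function(m) d[i, m]))
    tot
  }
  med <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(n), med)
    objs <- sapply(cand, function(cc) obj(c(med, cc)))
    med <- c(med, cand[which.min(objs)])
  }
  med <- sort(med)
  repeat {
    best <- obj(med)
    swap <- NULL
    for (m in med) {
      for (h in setdiff(seq_len(n), med)) {
        o <- obj(c(setdiff(med, m), h))
        if (o < best - 1e-12) {
          best <- o
          swap <- c(m, h)
        }
      }
    }
    if (is.null(swap)) break
    med <- sort(c(setdiff(med, swap[1]), swap[2]))
  }
  assign <- sapply(seq_len(n), function(i) which.min(sapply(med, function(m) d[i, m])))
  list(medoids = med, assignment = assign, objective = obj(med))
}

# Agglomerative complete linkage recomputing the max-linkage between every
# cluster pair from scratch at every step.
brute_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list(seq_len(n))  # partition after each merge
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf
    pick <- NULL
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best) {
          best <- link
          pick <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters <- c(clusters[-pick], list(merged))
    heights <- c(heights, best)
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions <- c(partitions, list(part))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition label vector (first-appearance numbering)
canon_partition <- function(p) {
  match(p, unique(p))
}

rand_dissimilarity <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  m
}

rand_surv <- function(n, p_event = 0.6, t_max = 12) {
  list(time = sample.int(t_max, n, replace = TRUE),
       event = stats::rbinom(n, 1, p_event))
}
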