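#' Initial dissimilarities between combinations
#'
#' Step 1 of the ensemble clustering pipeline: the initial dissimilarity
#' between the survival experiences of any two combinations is the
#' Gehan-Wilcoxon effect size of their member records (see
#' [gehan_wilcoxon()]). The formula is pluggable through `effect_fn`, which
#' receives the `gehan_test` object for a pair.
#'
#' @param combinations Tibble from [build_combinations()] (at least two
#'   rows, each non-empty).
#' @param effect_fn Function mapping a `gehan_test` to a non-negative
#'   scalar; default extracts `effect_size`.
#' @return Symmetric matrix of non-negative dissimilarities with zero
#'   diagonal, dimnames = combination labels.
#' @export
initial_dissimilarities <- function(combinations, effect_fn = NULL) {
  n <- nrow(combinations)
  if (n < 2) abort("Need at least two combinations.")
  if (any(combinations$size == 0)) abort("Combinations must be non-empty.")
  if (is.null(effect_fn)) effect_fn <- function(g) g$effect_size
  labels <- combinations$label
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  dat <- combinations$data
  for (i in seq_len(n - 1)) {
    ti <- dat[[i]]$surv_months
    ei <- dat[[i]]$event
    for (j in seq(i + 1, n)) {
      g <- gehan_wilcoxon(ti, ei, dat[[j]]$surv_months, dat[[j]]$event)
      d[i, j] <- d[j, i] <- effect_fn(g)
    }
  }
  d
}

check_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be a square matrix.")
  if (any(d < 0)) abort("Dissimilarities must be non-negative.")
  if (any(abs(d - t(d)) > 1e-12)) abort("`d` must be symmetric.")
  if (any(diag(d) != 0)) abort("`d` must have a zero diagonal.")
  invisible(d)
}

#' Partitioning around medoids (deterministic two-phase)
#'
#' k-medoids clustering of a dissimilarity matrix with the classic two
#' phases. BUILD greedily selects medoids minimizing the total
#' dissimilarity of points to their nearest medoid; SWAP repeatedly applies
#' the best single medoid/non-medoid exchange until no exchange strictly
#' lowers the objective. All tie-breaks are by lowest index / first in scan
#' order, so the result is fully deterministic given the matrix and `k`.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal).
#' @param k Number of medoids, `1 <= k <= n`.
#' @param seed Accepted for interface stability; the algorithm draws no
#'   random numbers.
#' @return A `pam_result` list: `medoids` (column indices), `assignment`
#'   (integer cluster per point, clusters numbered by ascending medoid
#'   index, named by labels when present), `objective`.
#' @export
pam_medoids <- function(d, k, seed = NULL) {
  check_dissimilarity(d)
  n <- nrow(d)
  if (k < 1 || k > n) abort("`k` must be between 1 and n.")

  obj_for <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))

  # BUILD
  med <- unname(which.min(colSums(d)))
  nearest <- d[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    objs <- vapply(cand, function(cc) sum(pmin(nearest, d[, cc])), numeric(1))
    pick <- cand[unname(which.min(objs))]
    med <- c(med, pick)
    nearest <- pmin(nearest, d[, pick])
  }
  med <- sort(med)

  # SWAP: best strictly-improving exchange each round, first-in-scan on ties
  cur <- obj_for(med)
  repeat {
    best_obj <- cur
    best_swap <- NULL
    for (m in med) {
      for (h in setdiff(seq_len(n), med)) {
        trial <- c(setdiff(med, m), h)
        o <- obj_for(trial)
        if (o < best_obj - 1e-12) {
          best_obj <- o
          best_swap <- c(m, h)
        }
      }
    }
    if (is.null(best_swap)) break
    med <- sort(c(setdiff(med, best_swap[1]), best_swap[2]))
    cur <- best_obj
  }

  assignment <- max.col(-d[, med, drop = FALSE], ties.method = "first")
  if (!is.null(rownames(d))) names(assignment) <- rownames(d)
  structure(
    list(medoids = med, assignment = assignment,
         objective = sum(d[cbind(seq_len(n), med[assignment])])),
    class = "pam_result"
  )
}

#' Ensemble-learned dissimilarities
#'
#' Step 2 of the pipeline: the initial dissimilarities are refined by a
#' clustering ensemble. For each run a cluster count `k` is drawn uniformly
#' from `[k_min, k_max]` and the combinations are partitioned with
#' [pam_medoids()]; the learned dissimilarity between two combinations is
#' the fraction of runs in which they fall in different clusters. Per-run
#' draws use counter-based seeds derived from the master `seed`, so
#' increasing `runs` extends the ensemble without reshuffling earlier runs.
#'
#' @param d Initial dissimilarity matrix.
#' @param runs Number of ensemble runs (default 1000; co-association
#'   fractions are stable well below this at a few dozen combinations).
#' @param k_min,k_max Range of cluster counts (defaults 2 and `n - 1`).
#' @param seed Master seed for the `k` draws.
#' @return Learned dissimilarity matrix in `[0, 1]`, symmetric, zero
#'   diagonal, same dimnames as `d`.
#' @export
ensemble_learn <- function(d, runs = 1000, k_min = 2, k_max = nrow(d) - 1,
                           seed = 1) {
  check_dissimilarity(d)
  n <- nrow(d)
  if (runs < 1) abort("`runs` must be >= 1.")
  if (k_min < 2 || k_max > n - 1 || k_min > k_max) {
    abort("Need 2 <= k_min <= k_max <= n - 1.")
  }
  ks <- vapply(seq_len(runs), function(b) {
    set.seed((as.numeric(seed) * 48271 + b * 16807) %% 2147483647)
    # sample from the candidate set, never sample.int-style from 1:k
    seq(k_min, k_max)[sample.int(k_max - k_min + 1, 1)]
  }, numeric(1))

  # PAM is deterministic given (d, k): memoize one partition per k
  partitions <- new.env(parent = emptyenv())
  same <- matrix(0, n, n)
  for (k in unique(ks)) {
    p <- pam_medoids(d, k)$assignment
    assign(as.character(k), outer(p, p, "=="), envir = partitions)
  }
  for (b in seq_len(runs)) {
    same <- same + get(as.character(ks[b]), envir = partitions)
  }
  learned <- 1 - same / runs
  diag(learned) <- 0
  dimnames(learned) <- dimnames(d)
  learned
}

#' Complete-linkage dendrogram
#'
#' Step 3 of the pipeline: agglomerative hierarchical clustering of the
#' learned dissimilarities with complete linkage (inter-cluster distance =
#' maximum pairwise dissimilarity), via [stats::hclust()].
#'
#' @param d Dissimilarity matrix (typically from [ensemble_learn()]).
#' @return An `hclust` object whose labels are the combination labels.
#' @export
complete_linkage <- function(d) {
  check_dissimilarity(d)
  if (nrow(d) < 2) abort("Need at least two items.")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cut a dendrogram into a fixed number of groups
#'
#' @param dendrogram An `hclust` object from [complete_linkage()].
#' @param g Number of clusters, `1 <= g <=` number of leaves.
#' @return Named integer vector mapping each leaf label to a cluster id.
#' @export
cut_groups <- function(dendrogram, g) {
  n <- length(dendrogram$order)
  if (g < 1 || g > n) abort("`g` must be between 1 and the number of leaves.")
  stats::cutree(dendrogram, k = g)
}

#' Export a dendrogram as Newick and as a merge table
#'
#' `export_newick()` writes a Newick tree with branch lengths derived from
#' the merge heights (requires the \pkg{ape} package);
#' `export_merges()` writes a flat CSV of the merge sequence
#' (left, right, height; negative entries are leaves).
#'
#' @param dendrogram An `hclust` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_newick <- function(dendrogram, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Package `ape` is required for Newick export.")
  }
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname export_newick
#' @export
export_merges <- function(dendrogram, path) {
  readr::write_csv(
    tibble::tibble(left = dendrogram$merge[, 1],
                   right = dendrogram$merge[, 2],
                   height = dendrogram$height),
    path
  )
  invisible(path)
}
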