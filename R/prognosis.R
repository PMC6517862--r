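# From dendrogram to prognostic system: C-index curve over cut sizes, knee
# detection, the non-crossing constraint on group survival curves, and the
# assembly of the selected system.

# Per-combination counts on a shared (time, event) grid, as a dense matrix
# (rows = combinations, columns = grid cells). Pooling any subset of
# combinations is then a column sum, which keeps repeated dendrogram cuts
# cheap.
pool_cache <- function(combinations) {
  cached <- attr(combinations, "pool")
  if (!is.null(cached)) return(cached)
  times <- purrr::map(combinations$data, "surv_months")
  events <- purrr::map(combinations$data, "event")
  grid <- dplyr::distinct(
    tibble::tibble(time = unlist(times, use.names = FALSE),
                   event = unlist(events, use.names = FALSE))
  )
  grid <- grid[order(grid$time, grid$event), , drop = FALSE]
  key <- paste(grid$time, grid$event)
  mat <- t(vapply(seq_len(nrow(combinations)), function(i) {
    tabulate(match(paste(times[[i]], events[[i]]), key),
             nbins = nrow(grid))
  }, numeric(nrow(grid))))
  rownames(mat) <- combinations$label
  list(time = grid$time, event = grid$event, mat = mat)
}

# Pool member records of each cluster and return, per cluster id:
# aggregated counts, KM curve, 5-year rate, mean observed time, smallest label.
pool_clusters <- function(assignment, combinations) {
  pc <- pool_cache(combinations)
  ids <- sort(unique(assignment))
  purrr::map(ids, function(cl) {
    labs <- names(assignment)[assignment == cl]
    w <- colSums(pc$mat[labs, , drop = FALSE])
    keep <- w > 0
    pooled <- tibble::tibble(time = pc$time[keep], event = pc$event[keep],
                             w = w[keep])
    curve <- km_from_counts(pooled)
    list(
      id = cl,
      labels = labs,
      n_cases = sum(pooled$w),
      curve = curve,
      five_year = unname(survival_at_silent(curve, 60)),
      mean_time = sum(pooled$time * pooled$w) / sum(pooled$w),
      first_label = min(labs)
    )
  })
}

# survival_at() without the beyond-follow-up warning (internal pooling can
# legitimately evaluate short groups at 60 months).
survival_at_silent <- function(curve, t) {
  suppressWarnings(survival_at(curve, t))
}

# single-combination KM curves from the shared grid
combination_curves <- function(combinations) {
  pc <- pool_cache(combinations)
  out <- purrr::map(seq_len(nrow(combinations)), function(i) {
    w <- pc$mat[i, ]
    keep <- w > 0
    km_from_counts(tibble::tibble(time = pc$time[keep],
                                  event = pc$event[keep], w = w[keep]))
  })
  names(out) <- combinations$label
  out
}

#' Precompute pooled count tables for a combination set
#'
#' Attaches per-combination aggregated (time, event, weight) tables as an
#' attribute so repeated cuts of the same cohort do not re-aggregate
#' patient records. Called automatically by the higher-level functions;
#' exposed for long experiment loops.
#'
#' @param combinations Tibble from [build_combinations()].
#' @return The same tibble with a `counts` attribute.
#' @export
cache_counts <- function(combinations) {
  attr(combinations, "pool") <- pool_cache(combinations)
  combinations
}

#' Order prognostic groups by survival
#'
#' Renumbers an arbitrary cluster assignment so that group 1 has the
#' highest pooled 5-year Kaplan-Meier survival and rates decrease with the
#' group number. Ties in the 5-year rate are broken by mean observed
#' survival time (longer = more favorable), then by the lexicographically
#' smallest member label.
#'
#' @param assignment Named integer vector (label -> cluster), e.g. from
#'   [cut_groups()].
#' @param combinations Tibble from [build_combinations()] covering every
#'   assigned label.
#' @return A list: `group_of` (named integer vector, renumbered),
#'   `summary` (tibble with `group`, `n_combinations`, `n_cases`,
#'   `five_year`), `curves` (list of `km_curve`, one per group).
#' @export
order_groups <- function(assignment, combinations) {
  if (!all(names(assignment) %in% combinations$label)) {
    abort("Every assigned label must appear in `combinations`.")
  }
  if (!all(combinations$label %in% names(assignment))) {
    abort("Every combination must be labeled.")
  }
  info <- pool_clusters(assignment, combinations)
  five <- vapply(info, `[[`, numeric(1), "five_year")
  mt <- vapply(info, `[[`, numeric(1), "mean_time")
  fl <- vapply(info, `[[`, character(1), "first_label")
  ord <- order(-five, -mt, fl)
  info <- info[ord]
  new_id <- setNames(seq_along(info), vapply(info, `[[`, numeric(1), "id"))
  group_of <- as.integer(new_id[as.character(assignment)])
  names(group_of) <- names(assignment)
  list(
    group_of = group_of,
    summary = tibble::tibble(
      group = seq_along(info),
      n_combinations = vapply(info, function(x) length(x$labels), integer(1)),
      n_cases = vapply(info, `[[`, numeric(1), "n_cases"),
      five_year = vapply(info, `[[`, numeric(1), "five_year")
    ),
    curves = purrr::map(info, "curve")
  )
}

#' C-index curve over dendrogram cuts
#'
#' For each number of groups g = 1..n, cuts the dendrogram, orders the
#' groups by survival, assigns every patient the ordinal group number of
#' its combination as the predicted risk, and computes Harrell's C over all
#' patients. The curve typically rises steeply for small g and plateaus
#' once the latent risk structure is resolved.
#'
#' @param dendrogram `hclust` object whose leaves are combination labels.
#' @param combinations Tibble from [build_combinations()].
#' @param tied_events Passed to [harrell_c()].
#' @return A `cindex_curve` tibble with columns `g` and `c_index`.
#' @export
c_index_curve <- function(dendrogram, combinations, tied_events = TRUE) {
  all_cuts(dendrogram, combinations, tied_events)$curve
}

# Shared engine: for every g, the cut, the survival-ordered groups and the
# patient-level C-index. Both the exported curve and the system selection
# reuse this so each cut is ordered exactly once.
all_cuts <- function(dendrogram, combinations, tied_events = TRUE) {
  if (!setequal(dendrogram$labels, combinations$label)) {
    abort("Dendrogram leaves must match the combination labels.")
  }
  combinations <- cache_counts(combinations)
  pl <- patient_level(combinations)
  n <- nrow(combinations)
  ogs <- purrr::map(seq_len(n), function(g) {
    order_groups(cut_groups(dendrogram, g), combinations)
  })
  cs <- vapply(ogs, function(og) {
    risk <- og$group_of[pl$label]
    harrell_c(risk, pl$times, pl$events, tied_events = tied_events)$c
  }, numeric(1))
  curve <- structure(tibble::tibble(g = seq_len(n), c_index = cs),
                     class = c("cindex_curve", class(tibble::tibble())))
  list(curve = curve, ogs = ogs, combinations = combinations)
}

#' Do two survival curves cross?
#'
#' Operationalizes "overlapping" survival curves as a sign change of
#' \eqn{S_A(t) - S_B(t)} beyond `tol`, evaluated on the union of step times
#' within the common follow-up window. Touching without crossing is not
#' overlap.
#'
#' @param curve_a,curve_b `km_curve` objects.
#' @param tol Tolerance below which a difference is treated as zero
#'   (default 0).
#' @return `TRUE` if the curves cross, else `FALSE`.
#' @export
overlap <- function(curve_a, curve_b, tol = 0) {
  if (nrow(curve_a) == 0 && nrow(curve_b) == 0) return(FALSE)
  t_max <- min(attr(curve_a, "t_max"), attr(curve_b, "t_max"))
  ts <- sort(unique(c(curve_a$time, curve_b$time)))
  ts <- ts[ts <= t_max]
  if (length(ts) == 0) return(FALSE)
  da <- survival_at_silent(curve_a, ts)
  db <- survival_at_silent(curve_b, ts)
  diff <- da - db
  any(diff > tol) && any(diff < -tol)
}

any_crossing <- function(curves, tol = 0) {
  k <- length(curves)
  if (k < 2) return(FALSE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (overlap(curves[[i]], curves[[j]], tol = tol)) return(TRUE)
    }
  }
  FALSE
}

#' Knee points of a C-index curve
#'
#' Candidate group counts where the marginal C-index gain drops sharply:
#' interior points whose discrete second difference falls below
#' `-drop` times the mean absolute first difference. Returned in
#' descending order of g (the convention for walking down from the highest
#' knee until the non-crossing constraint is met).
#'
#' @param curve A `cindex_curve` (at least 3 points).
#' @param drop Sharpness threshold as a fraction of the mean absolute
#'   first difference (default 0.25).
#' @return Integer vector of knee locations, possibly empty.
#' @export
knees <- function(curve, drop = 0.25) {
  if (nrow(curve) < 3) abort("Need a curve with at least 3 points.")
  cs <- curve$c_index
  d1 <- diff(cs)
  scale <- mean(abs(d1))
  g_int <- curve$g[c(-1, -nrow(curve))]
  s2 <- cs[-c(1, 2)] - 2 * cs[-c(1, nrow(curve))] + cs[-c(nrow(curve) - 1, nrow(curve))]
  out <- g_int[s2 < -drop * scale]
  sort(out, decreasing = TRUE)
}

#' Select the prognostic system from a dendrogram
#'
#' Implements the selection rule for the optimal number of groups
#' \eqn{n^*}: the largest cut whose ordered group Kaplan-Meier curves are
#' pairwise non-crossing defines the admissible range; \eqn{n^*} is the
#' largest knee of the C-index curve within that range, falling back to the
#' admissible maximum itself (with a warning) when no knee qualifies.
#'
#' @param dendrogram `hclust` over combination labels.
#' @param combinations Tibble from [build_combinations()].
#' @param tol Crossing tolerance passed to [overlap()].
#' @param drop Knee threshold passed to [knees()].
#' @param tied_events Passed to [harrell_c()].
#' @return A `prognostic_system` object; see [tidy.prognostic_system()]
#'   and [glance.prognostic_system()].
#' @export
select_system <- function(dendrogram, combinations, tol = 0, drop = 0.25,
                          tied_events = TRUE) {
  ac <- all_cuts(dendrogram, combinations, tied_events)
  combinations <- ac$combinations
  curve <- ac$curve
  n <- nrow(combinations)
  kn <- if (n >= 3) knees(curve, drop = drop) else integer(0)

  # a cut is admissible when its ordered group curves are pairwise
  # non-crossing AND the 5-year rates strictly separate the groups
  g_valid <- 1L
  for (g in rev(seq_len(n))) {
    og <- ac$ogs[[g]]
    separated <- all(diff(og$summary$five_year) < 0)
    if (separated && !any_crossing(og$curves, tol = tol)) {
      g_valid <- g
      break
    }
  }

  qualifying <- kn[kn <= g_valid]
  if (length(qualifying)) {
    n_star <- max(qualifying)
  } else {
    n_star <- g_valid
    if (n > 2) {
      warn(paste0("No knee point at or below the largest admissible cut (",
                  g_valid, "); using that cut itself."))
    }
  }

  og <- ac$ogs[[n_star]]
  if (any(diff(og$summary$five_year) >= 0)) {
    warn("Group 5-year survival rates are not strictly decreasing; ordering used tie-breaks.")
  }

  comb_five <- vapply(combination_curves(combinations), function(cv) {
    survival_at_silent(cv, 60)
  }, numeric(1))
  groups <- tibble::tibble(
    label = combinations$label,
    group = unname(og$group_of[combinations$label]),
    size = combinations$size,
    five_year = unname(comb_five[combinations$label])
  )
  structure(
    list(
      groups = groups,
      group_of = og$group_of,
      group_summary = og$summary,
      group_curves = og$curves,
      n_groups = n_star,
      c_index = curve$c_index[n_star],
      curve = curve,
      knees = kn,
      g_valid = g_valid,
      dendrogram = dendrogram,
      params = list(tol = tol, drop = drop, tied_events = tied_events)
    ),
    class = "prognostic_system"
  )
}

#' @export
print.prognostic_system <- function(x, ...) {
  cat("Prognostic system:", x$n_groups, "groups,",
      nrow(x$groups), "combinations,",
      format(sum(x$groups$size)), "cases\n")
  cat("  C-index at n* =", format(x$c_index, digits = 4),
      "| largest non-crossing cut =", x$g_valid,
      "| knees:", paste(x$knees, collapse = ", "), "\n")
  print(x$group_summary)
  invisible(x)
}

#' Tidy a prognostic system
#'
#' @param x A `prognostic_system`.
#' @param ... Unused.
#' @return One row per combination: `label`, `group`, `size`, `five_year`.
#' @export
tidy.prognostic_system <- function(x, ...) {
  x$groups
}

#' One-row summary of a prognostic system
#'
#' @param x A `prognostic_system`.
#' @param ... Unused.
#' @return A tibble with `n_groups`, `c_index`, `g_valid`,
#'   `n_combinations`, `n_cases`.
#' @export
glance.prognostic_system <- function(x, ...) {
  tibble::tibble(
    n_groups = x$n_groups,
    c_index = x$c_index,
    g_valid = x$g_valid,
    n_combinations = nrow(x$groups),
    n_cases = sum(x$groups$size)
  )
}

#' Long-format group survival curves
#'
#' @param system A `prognostic_system`.
#' @return Tibble with `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
group_curves_tbl <- function(system) {
  purrr::imap_dfr(system$group_curves, function(cv, g) {
    tibble::tibble(group = g, time = cv$time, surv = cv$surv,
                   n_risk = cv$n_risk, n_event = cv$n_event)
  })
}
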