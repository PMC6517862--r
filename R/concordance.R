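# Pair-count engine behind the concordance index.
#
# All pair totals are computed from an R x T table of (risk level, distinct
# time) counts, so cost is O(R*T) after aggregation rather than O(n^2).
# Comparable pairs, with "higher risk predicts earlier death":
#   (1) t_i < t_j with event_i = 1 (j's status irrelevant);
#   (2) t_i = t_j with event_i = 1, event_j = 0 (the death is the earlier);
#   (3) t_i = t_j, both events, different predictions: counted as a tied
#       pair (0.5) when `tied_events` is TRUE; same-prediction tied-death
#       pairs are never comparable.
# Prediction ties in (1)-(2) contribute 0.5.

rowcs <- function(m) {
  if (ncol(m) == 1) return(m)
  t(apply(m, 1, cumsum))
}

colcs <- function(m) {
  if (nrow(m) == 1) return(m)
  apply(m, 2, cumsum)
}

concordance_core <- function(risk, time, event,
                             tied_events = TRUE, per_subject = FALSE) {
  n <- length(time)
  rl <- sort(unique(risk))
  tl <- sort(unique(time))
  nr <- length(rl)
  nt <- length(tl)
  ri <- match(risk, rl)
  ti <- match(time, tl)
  lin <- (ti - 1L) * nr + ri
  nall <- matrix(tabulate(lin, nbins = nr * nt), nr, nt)
  ndeath <- matrix(tabulate(lin[event == 1], nbins = nr * nt), nr, nt)
  ncens <- nall - ndeath

  ctot <- function(m) matrix(colSums(m), nr, nt, byrow = TRUE)
  suffix_after <- rowSums(nall) - rowcs(nall)      # same risk, time > t
  cS <- colcs(suffix_after)
  lower_after <- cS - suffix_after                 # risk' < r, time > t
  upper_after <- ctot(suffix_after) - cS           # risk' > r, time > t
  cC <- colcs(ncens)
  lower_cens <- cC - ncens                         # risk' < r, censored at t
  upper_cens <- ctot(ncens) - cC

  conc <- sum(ndeath * (lower_after + lower_cens))
  disc <- sum(ndeath * (upper_after + upper_cens))
  tied <- sum(ndeath * (suffix_after + ncens))
  deaths_t <- colSums(ndeath)
  if (tied_events) {
    tied <- tied + sum((deaths_t^2 - colSums(ndeath^2)) / 2)
  }

  out <- list(conc = conc, disc = disc, tied = tied, n = n)
  if (per_subject) {
    deaths_before <- rowcs(ndeath) - ndeath        # same risk, deaths < t
    cDB <- colcs(deaths_before)
    cD <- colcs(ndeath)
    concE <- lower_after + lower_cens
    discE <- upper_after + upper_cens
    tieE <- suffix_after + ncens +
      if (tied_events) ctot(ndeath) - ndeath else 0
    concL <- ctot(deaths_before) - cDB             # earlier death, higher risk
    discL <- cDB - deaths_before
    tieL <- deaths_before
    concC <- ctot(ndeath) - cD                     # death at same t, higher risk
    discC <- cD - ndeath
    tieC <- ndeath
    cell <- cbind(ri, ti)
    e <- as.numeric(event)
    out$conc_i <- e * concE[cell] + concL[cell] + (1 - e) * concC[cell]
    out$disc_i <- e * discE[cell] + discL[cell] + (1 - e) * discC[cell]
    out$tied_i <- e * tieE[cell] + tieL[cell] + (1 - e) * tieC[cell]
  }
  out
}

check_concordance_input <- function(pred_risk, times, events) {
  if (length(pred_risk) != length(times) || length(times) != length(events)) {
    abort("`pred_risk`, `times` and `events` must have equal length.")
  }
  if (length(times) == 0) abort("Empty input.")
  if (anyNA(pred_risk) || anyNA(times) || anyNA(events)) {
    abort("Missing values are not allowed.")
  }
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
}

#' Harrell's concordance index
#'
#' Estimates the probability that of two comparable subjects, the one dying
#' earlier had the higher predicted risk. Comparable pairs are those where
#' the earlier observed time belongs to an event, including pairs tied in
#' time where exactly one subject has an event (the death counts as
#' earlier). Prediction ties contribute 0.5. Pairs of deaths at the same
#' time with different predictions are counted as tied (0.5) when
#' `tied_events = TRUE` (the default, appropriate for month-resolution data
#' with many ties); set it to `FALSE` to exclude them.
#'
#' @param pred_risk Predicted risk scores; higher means worse prognosis.
#'   Ordinal group numbers are the typical input here.
#' @param times Follow-up months.
#' @param events 0/1 event indicators.
#' @param tied_events Count tied-death pairs with differing predictions as
#'   comparable-tied (default `TRUE`).
#' @return A `concordance_result` list: `c`, `n_comparable`,
#'   `n_concordant`, `n_discordant`, `n_tied`.
#' @export
#' @examples
#' harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))$c  # perfect ordering
harrell_c <- function(pred_risk, times, events, tied_events = TRUE) {
  check_concordance_input(pred_risk, times, events)
  cc <- concordance_core(pred_risk, times, events, tied_events = tied_events)
  n_comp <- cc$conc + cc$disc + cc$tied
  if (n_comp == 0) abort("No comparable pairs.")
  structure(
    list(c = (cc$conc + 0.5 * cc$tied) / n_comp,
         n_comparable = n_comp,
         n_concordant = cc$conc,
         n_discordant = cc$disc,
         n_tied = cc$tied),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("C-index:", format(x$c, digits = 4),
      sprintf("(%s comparable pairs)\n", format(x$n_comparable)))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::tibble(c_index = x$c, n_comparable = x$n_comparable,
                 n_concordant = x$n_concordant,
                 n_discordant = x$n_discordant, n_tied = x$n_tied)
}

#' Compare the concordance of two predictors on the same subjects
#'
#' Tests `delta = c1 - c2` between two risk predictors evaluated on the same
#' cohort. The variance of the paired difference is estimated by the
#' jackknife over subjects: each subject's pair contributions are removed in
#' closed form to obtain the leave-one-out `delta`, and the usual jackknife
#' variance is applied. A two-sided normal p-value is reported.
#'
#' @param pred1,pred2 Two predicted-risk vectors on the same subjects.
#' @param times,events Shared follow-up months and 0/1 event indicators.
#' @param tied_events Passed to the concordance computation.
#' @return A `cindex_comparison` list: `delta`, `z`, `p`, `c1`, `c2`,
#'   `se_delta`, `n`.
#' @export
compare_c <- function(pred1, pred2, times, events, tied_events = TRUE) {
  check_concordance_input(pred1, times, events)
  check_concordance_input(pred2, times, events)
  n <- length(times)
  r1 <- concordance_core(pred1, times, events, tied_events, per_subject = TRUE)
  r2 <- concordance_core(pred2, times, events, tied_events, per_subject = TRUE)
  c_full <- function(r) {
    d <- r$conc + r$disc + r$tied
    if (d == 0) abort("No comparable pairs.")
    (r$conc + 0.5 * r$tied) / d
  }
  c_loo <- function(r) {
    denom <- (r$conc - r$conc_i) + (r$disc - r$disc_i) + (r$tied - r$tied_i)
    if (any(denom <= 0)) {
      abort("Degenerate jackknife: removing one subject leaves no comparable pairs.")
    }
    (r$conc - r$conc_i + 0.5 * (r$tied - r$tied_i)) / denom
  }
  c1 <- c_full(r1)
  c2 <- c_full(r2)
  delta <- c1 - c2
  d_i <- c_loo(r1) - c_loo(r2)
  var_j <- (n - 1) / n * sum((d_i - mean(d_i))^2)
  se <- sqrt(var_j)
  if (se == 0) {
    if (delta == 0) {
      z <- 0
      p <- 1
    } else {
      abort("Degenerate variance: jackknife SE is zero but delta is not.")
    }
  } else {
    z <- delta / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(delta = delta, z = z, p = p, c1 = c1, c2 = c2,
         se_delta = se, n = n),
    class = "cindex_comparison"
  )
}

#' @export
print.cindex_comparison <- function(x, ...) {
  cat("C-index comparison: c1 =", format(x$c1, digits = 4),
      "vs c2 =", format(x$c2, digits = 4),
      "\n  delta =", format(x$delta, digits = 4),
      ", z =", format(x$z, digits = 4),
      ", p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.cindex_comparison <- function(x, ...) {
  tibble::tibble(delta = x$delta, z = x$z, p = x$p,
                 c1 = x$c1, c2 = x$c2, se_delta = x$se_delta, n = x$n)
}
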