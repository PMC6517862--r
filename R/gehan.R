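#' Gehan-Wilcoxon two-sample test and effect size
#'
#' The censored-data generalization of the two-sample Wilcoxon test.
#' Each cross-pair (i in sample 1, j in sample 2) is scored +1 when i
#' definitely survives longer than j (j's event occurs strictly before i's
#' observation time), -1 in the mirror case, and 0 when censoring leaves the
#' order indeterminate; ties in observed time are always indeterminate.
#' `w` is the sum of the cross-pair scores, `var_w` the permutation variance
#' computed from the pooled per-subject scores
#' \eqn{Var(W) = n_1 n_2 \sum_k U_k^2 / (N(N-1))}, and
#' `z = w / sqrt(var_w)`.
#'
#' The effect size used as the initial dissimilarity between two patient
#' cohorts is the standardized statistic scaled by the pooled size,
#' \eqn{d = |z| / \sqrt{n_1 + n_2}} — scale-free, symmetric in the two
#' samples and zero for identical cohorts.
#'
#' @param time1,event1 Follow-up months and 0/1 event indicators, sample 1.
#' @param time2,event2 Same for sample 2.
#' @return A `gehan_test` list: `w`, `var_w`, `z`, `effect_size`, `n1`, `n2`.
#'   When all pooled scores are tied (`var_w = 0`), `z` and `effect_size`
#'   are 0 by convention.
#' @export
#' @examples
#' gehan_wilcoxon(c(2, 4), c(1, 1), c(5, 7), c(1, 1))$w  # all pairs definite
gehan_wilcoxon <- function(time1, event1, time2, event2) {
  if (length(time1) == 0 || length(time2) == 0) {
    abort("Both samples must be non-empty.")
  }
  n1 <- length(time1)
  n2 <- length(time2)
  time <- c(time1, time2)
  event <- c(event1, event2)
  if (length(event) != n1 + n2) abort("times/events length mismatch.")
  n <- n1 + n2

  # pooled per-subject Gehan scores:
  # U_k = (# pooled deaths strictly before t_k) - e_k * (# strictly after t_k)
  ot <- sort(unique(time))
  idx <- match(time, ot)
  deaths_at <- tabulate(idx[event == 1], nbins = length(ot))
  count_at <- tabulate(idx, nbins = length(ot))
  deaths_before <- cumsum(deaths_at) - deaths_at
  after <- n - cumsum(count_at)
  u <- deaths_before[idx] - event * after[idx]

  w <- sum(u[seq_len(n1)])
  var_w <- if (n > 1) n1 * n2 * sum(u^2) / (n * (n - 1)) else 0
  z <- if (var_w > 0) w / sqrt(var_w) else 0
  structure(
    list(w = w, var_w = var_w, z = z,
         effect_size = abs(z) / sqrt(n1 + n2),
         n1 = n1, n2 = n2),
    class = "gehan_test"
  )
}

#' @export
print.gehan_test <- function(x, ...) {
  cat("Gehan-Wilcoxon: w =", format(x$w), ", z =", format(x$z, digits = 4),
      ", effect size =", format(x$effect_size, digits = 4),
      sprintf("(n1 = %d, n2 = %d)\n", x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.gehan_test <- function(x, ...) {
  tibble::tibble(w = x$w, var_w = x$var_w, z = x$z,
                 effect_size = x$effect_size, n1 = x$n1, n2 = x$n2)
}
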