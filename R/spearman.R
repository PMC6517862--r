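#' Spearman rank correlation with ties
#'
#' Spearman's rho computed as the Pearson correlation of average (midrank)
#' ranks, with the t approximation for the two-sided p-value:
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' This is the form appropriate for ordinal data with many ties, such as
#' prognostic group numbers against staging categories.
#'
#' @param x,y Equal-length numeric or ordered vectors, n >= 3.
#' @return A `cor_result` list: `rho`, `t_stat`, `df`, `p`, `n`.
#' @export
#' @examples
#' spearman_ties(1:3, 1:3)$rho
spearman_ties <- function(x, y) {
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("Zero variance in `x` or `y`; the correlation is undefined.")
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2
  if (1 - rho^2 < .Machine$double.eps) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(rho = rho, t_stat = t_stat, df = df, p = p, n = n),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat("Spearman rho =", format(x$rho, digits = 4),
      sprintf("(t = %s, df = %d, p = %s)\n",
              format(x$t_stat, digits = 4), x$df, format(x$p, digits = 3)))
  invisible(x)
}

#' @export
tidy.cor_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, t_stat = x$t_stat, df = x$df, p = x$p, n = x$n)
}
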