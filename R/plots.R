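# ggplot2 methods for the result types. Data exports stay in the pipeline;
# these are convenience views of objects already in memory.

km_step_data <- function(curve) {
  tibble::tibble(time = c(0, curve$time), surv = c(1, curve$surv))
}

#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(km_step_data(object),
                  ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(...) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Disease-specific survival") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cindex_curve <- function(object, mark_knees = TRUE, drop = 0.25,
                                  ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$g, y = .data$c_index)) +
    ggplot2::geom_line(...) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Number of groups", y = "C-index") +
    ggplot2::theme_minimal()
  if (mark_knees && nrow(object) >= 3) {
    kn <- knees(object, drop = drop)
    if (length(kn)) {
      p <- p + ggplot2::geom_vline(xintercept = kn, linetype = "dashed",
                                   colour = "grey50")
    }
  }
  p
}

#' Plot a prognostic system
#'
#' `type = "km"` draws the per-group Kaplan-Meier curves with the 5-year
#' rates in the legend; `type = "cindex"` draws the C-index curve with the
#' selected number of groups marked.
#'
#' @param object A `prognostic_system`.
#' @param type `"km"` or `"cindex"`.
#' @param ... Passed to the geoms.
#' @return A ggplot object.
#' @export
autoplot.prognostic_system <- function(object, type = c("km", "cindex"),
                                       ...) {
  type <- match.arg(type)
  if (type == "cindex") {
    return(
      autoplot(object$curve, drop = object$params$drop, ...) +
        ggplot2::geom_vline(xintercept = object$n_groups, colour = "red") +
        ggplot2::annotate("text", x = object$n_groups,
                          y = min(object$curve$c_index),
                          label = paste0("n* = ", object$n_groups),
                          hjust = -0.2, colour = "red")
    )
  }
  lab <- sprintf("%d (5y %.1f%%)", object$group_summary$group,
                 100 * object$group_summary$five_year)
  df <- purrr::imap_dfr(object$group_curves, function(cv, g) {
    dplyr::mutate(km_step_data(cv), group = factor(lab[g], levels = lab))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(...) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Disease-specific survival",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot the dendrogram of a prognostic system
#'
#' Base-graphics dendrogram with leaves reordered by prognostic group and,
#' within group, by decreasing 5-year survival, echoing the left-to-right
#' survival gradient convention. Reordering affects display only.
#'
#' @param system A `prognostic_system`.
#' @param ... Passed to [plot()].
#' @return The reordered dendrogram, invisibly.
#' @export
plot_dendrogram <- function(system, ...) {
  dend <- stats::as.dendrogram(system$dendrogram)
  g <- system$groups
  wts <- g$group * 1000 - rank(g$five_year)
  names(wts) <- g$label
  dend <- stats::reorder(dend, wts[labels(dend)], agglo.FUN = mean)
  plot(dend, ...)
  invisible(dend)
}
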