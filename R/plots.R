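#' Plot the motif decay profile
#'
#' Proportion of deletions with at least one full-RSS hit within each
#' distance of the breakpoint, interior and exterior curves separately.
#'
#' @param decay tibble from [decay_profile()].
#' @return a ggplot object.
#' @export
plot_decay_profile <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$distance,
                                      y = .data$proportion,
                                      colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance from breakpoint (bp)",
                  y = "proportion of deletions with an RSS motif",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of group proportions with bootstrap confidence intervals
#'
#' @param annotations output of [annotate_deletions()].
#' @param patients patient metadata tibble.
#' @param outcome logical annotation column (default `"rag_mediated"`).
#' @param target deletions to include (default `"off_target"`).
#' @param B,seed bootstrap settings (see [bootstrap_proportion_ci()]).
#' @return a ggplot object.
#' @export
plot_group_proportions <- function(annotations, patients,
                                   outcome = "rag_mediated",
                                   target = "off_target", B = 10000,
                                   seed = 1) {
  x <- annotations
  if (target != "all") x <- x[x$target_status == target, ]
  grp <- patients$exposure_group[match(x$patient_id, patients$patient_id)]
  df <- bind_rows(lapply(c("high", "low"), function(g) {
    ci <- bootstrap_proportion_ci(x[[outcome]][grp == g], B = B,
                                  seed = seed)
    mutate(ci, exposure_group = g)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure_group,
                                   y = .data$prop)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.15) +
    ggplot2::labs(x = "prenatal tobacco exposure",
                  y = paste0("proportion of deletions: ", outcome)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of a multilevel fit
#'
#' @param object a `rag_mlfit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rag_mlfit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.1) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (high vs low exposure)", y = NULL) +
    ggplot2::theme_minimal()
}
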