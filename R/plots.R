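#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of primary classification prevalences
#'
#' @param prev A prevalence table from [prevalence_table()] (single
#'   subgroup or stratified; strata are faceted).
#' @param classifications Which classification rows to plot; defaults to
#'   the nine primary constitutions plus the tendency-only group.
#' @return A ggplot.
#' @export
plot_prevalence <- function(prev,
                            classifications = c(constitutions(),
                                                "tendency_only")) {
  df <- filter(prev, .data$classification %in% classifications)
  lab <- function(x) {
    out <- .ccmq_labels[x]
    if_else(is.na(out), gsub("_", " ", x), unname(out))
  }
  df <- mutate(df,
               classification = stats::reorder(lab(.data$classification),
                                               -.data$prevalence))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$classification,
                                        .data$prevalence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Prevalence (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(df$subgroup)) > 1) {
    p <- p + ggplot2::facet_wrap(~subgroup)
  }
  p
}

#' Forest-style plot of adjusted prevalence ratios
#'
#' @param object A `ccmq_pr` model.
#' @param ... Unused.
#' @return A ggplot of the PR and robust 95\% CI per exposure level.
#' @method autoplot ccmq_pr
#' @export
autoplot.ccmq_pr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pr, .data$level)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Prevalence ratio (robust 95% CI)",
                  y = object$exposure) +
    ggplot2::theme_minimal()
}
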