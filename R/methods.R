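# broom-style accessors and plots for the two result objects.

#' @export
print.hla_trio_scores <- function(x, ...) {
  cat("<hla_trio_scores> ", x$dataset, "\n", sep = "")
  cat("  families: ", x$n_families, "; loci: ", length(x$loci),
      "; resolutions: ", paste(x$resolutions, collapse = ","), "\n", sep = "")
  inc <- x$scores[x$scores$resolution == x$resolutions[1], ]
  cat("  excluded family-locus combinations: ", sum(!inc$included), "\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.hla_dup_scores <- function(x, ...) {
  cat("<hla_dup_scores> ", x$dataset, "\n", sep = "")
  cat("  pairs: ", x$n_pairs, "; loci: ", length(x$loci),
      "; resolutions: ", paste(x$resolutions, collapse = ","), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.hla_tool_comparison <- function(x, ...) {
  cat("<hla_tool_comparison> at resolution ", x$resolution, "\n", sep = "")
  print(x$summary)
  cat("  discrepant pair-loci: ", nrow(x$discrepancies), "\n", sep = "")
  invisible(x)
}

#' Tidy trio or duplicate scores
#'
#' @param x An `hla_trio_scores` or `hla_dup_scores` object.
#' @param ... Unused.
#' @return The long per-unit score tibble (one row per family-or-pair x
#'   locus x resolution, exclusions included with their reason).
#' @export
tidy.hla_trio_scores <- function(x, ...) x$scores

#' @rdname tidy.hla_trio_scores
#' @export
tidy.hla_dup_scores <- function(x, ...) x$scores

#' One-row summary of a scoring result
#'
#' @param x An `hla_trio_scores` or `hla_dup_scores` object.
#' @param ... Unused.
#' @return Tibble `dataset, mean_field1, mean_field2, mean_field3,
#'   overall_mean, n_loci` (per-resolution means are unweighted across loci).
#' @export
glance.hla_trio_scores <- function(x, ...) {
  summarize_consistency(consistency_table(x), dataset = x$dataset)
}

#' @rdname glance.hla_trio_scores
#' @export
glance.hla_dup_scores <- glance.hla_trio_scores

plot_table <- function(tab, n_col, ylab) {
  long <- tidyr::pivot_longer(tab, dplyr::ends_with("_field_pct"),
                              names_to = "resolution", values_to = "pct")
  long$resolution <- factor(
    long$resolution,
    levels = res_col(1:3),
    labels = c("first field", "second field", "third field"))
  long$locus <- factor(long$locus, levels = unique(tab$locus))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$locus, y = .data$pct,
                               fill = .data$resolution)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      na.rm = TRUE) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(x = NULL, y = ylab, fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-locus consistency by resolution
#'
#' Grouped bar chart of per-locus percentages at each field resolution, the
#' standard way these evaluations are displayed.
#'
#' @param object An `hla_trio_scores` or `hla_dup_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_trio_scores <- function(object, ...) {
  plot_table(consistency_table(object), "n_families",
             "trio consistency (%)")
}

#' @rdname autoplot.hla_trio_scores
#' @export
autoplot.hla_dup_scores <- function(object, ...) {
  plot_table(consistency_table(object), "n_pairs",
             "duplicate concordance (%)")
}

#' Plot typing success rates per locus
#'
#' @param rates Tibble from [success_rate()] (rows from several datasets can
#'   be combined with [dplyr::bind_rows()]).
#' @return A ggplot object.
#' @export
plot_success_rate <- function(rates) {
  rates$locus <- factor(rates$locus, levels = unique(rates$locus))
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$locus, y = .data$pct_typed,
                               fill = .data$dataset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = NULL, y = "samples typed (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
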