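#' Plot canonical correlations against their permutation null
#'
#' Bars show the observed canonical correlation per mode; the violin-like
#' jitter shows the permutation null, which for a maximized statistic does
#' not center on zero.
#'
#' @param object A `cca_model` with permutation results.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cca_model <- function(object, ...) {
  obs <- tidy(object)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = factor(.data$mode), y = .data$r))
  if (!is.null(object$null_r)) {
    null_long <- tibble::tibble(
      mode = rep(seq_len(ncol(object$null_r)), each = nrow(object$null_r)),
      r = as.numeric(object$null_r)
    )
    p <- p + ggplot2::geom_jitter(
      data = null_long, width = 0.25, alpha = 0.05, size = 0.3,
      colour = "grey50"
    )
  }
  p +
    ggplot2::geom_point(colour = "firebrick", size = 3) +
    ggplot2::labs(x = "canonical mode", y = "canonical correlation",
                  title = "Observed canonical correlations vs permutation null")
}

#' Plot an equipercentile linking curve
#'
#' @param link A `linking_table` from [equipercentile_link()].
#' @param source_name,target_name Axis labels.
#' @return A ggplot object.
#' @export
plot_linking <- function(link, source_name = "source score",
                         target_name = "mapped score") {
  ggplot2::ggplot(link, ggplot2::aes(.data$source_score,
                                     .data$mapped_score)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = source_name, y = target_name,
                  title = "Equipercentile linkage")
}

#' Boxplots of test-retest reliability by modality
#'
#' @param table A `reliability_table`.
#' @param adjusted Overlay the interval-adjusted ICCs when present.
#' @return A ggplot object.
#' @export
plot_reliability <- function(table, adjusted = TRUE) {
  long <- tidyr::pivot_longer(
    table,
    cols = dplyr::any_of(c("icc",
                           if (adjusted) "icc_interval_adj" else NULL)),
    names_to = "variant", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$modality, .data$value,
                                     fill = .data$variant)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, position = "dodge") +
    ggplot2::labs(x = NULL, y = "ICC(A,1)",
                  title = "Test-retest reliability by modality") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Boxplots of absolute univariate effect sizes by modality
#'
#' @param table An `effect_size_table`.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(table) {
  long <- tidyr::pivot_longer(
    table, cols = c("cohen_d", "r_rds4", "r_phq9", "r_gad7", "r_n12"),
    names_to = "measure", values_to = "effect"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$modality, abs(.data$effect))) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "steelblue",
                          alpha = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "|effect size|",
                  title = "Held-out univariate effect sizes by modality") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histograms of the summary-score distributions
#'
#' @param scores Score table from [score_phenotypes()] (timepoint 1 rows).
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores) {
  long <- tidyr::pivot_longer(
    dplyr::filter(scores, .data$timepoint == 1L),
    cols = c("rds4", "phq9", "gad7", "n12"),
    names_to = "measure", values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$score)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "score", y = "subjects",
                  title = "Summary-score distributions")
}
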