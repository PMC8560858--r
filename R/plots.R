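#' Plot imputation quality by MAF bin
#'
#' Stacked proportions of low / medium / high imputation quality within
#' each minor-allele-frequency bin.
#'
#' @param object A `quality_summary` from [summarize_quality()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.quality_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$maf_bin, y = .data$prop,
                               fill = .data$quality)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(low = "#d73027", medium = "#fee090", high = "#4575b4")
    ) +
    ggplot2::labs(x = "MAF bin", y = "proportion of variants",
                  fill = expression(R^2 ~ "bin")) +
    ggplot2::theme_minimal()
}

#' Plot genome-wide coverage per ancestry
#'
#' @param object A `coverage_result` from [coverage_by_ancestry()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coverage_result <- function(object, ...) {
  d <- as_tibble(object)
  if (!"ancestry" %in% names(d)) d$ancestry <- "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ancestry, y = .data$cr)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "ancestry", y = "genome-wide coverage (CR)") +
    ggplot2::theme_minimal()
}

#' Plot the inter-array overlap matrix
#'
#' @param object An `overlap_matrix` from [overlap_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$array_a, y = .data$array_b,
                               fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4575b4") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared sites") +
    ggplot2::theme_minimal()
}

#' Plot per-sample concordance
#'
#' @param object A `concordance_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = "", y = .data$concordance)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "per-sample concordance") +
    ggplot2::theme_minimal()
}
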