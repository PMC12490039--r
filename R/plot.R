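# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_line geom_hline labs scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Eigengene heatmap of a module partition
#' @param object a `module_partition` with eigengenes computed.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.module_partition <- function(object, ...) {
  if (is.null(object$eigengenes)) abort("compute eigengenes first")
  df <- as_expr_tibble(object$eigengenes) |>
    dplyr::rename(module = "gene") |>
    tidyr::pivot_longer(-"module", names_to = "sample", values_to = "eigengene")
  ggplot(df, aes(x = .data$sample, y = .data$module, fill = .data$eigengene)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, title = "Module eigengenes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Soft-power scan plot
#' @param power a [pick_soft_power()] result (carries the `scan` attribute).
#' @param fit_threshold threshold line (default 0.8).
#' @return A ggplot of fit index against candidate power.
#' @export
plot_soft_power_scan <- function(power, fit_threshold = 0.8) {
  scan <- attr(power, "scan")
  if (is.null(scan)) abort("no scan attribute; use pick_soft_power()")
  ggplot(scan, aes(x = .data$power, y = .data$fit_index)) +
    geom_line(colour = "grey60") +
    geom_point() +
    geom_hline(yintercept = fit_threshold, linetype = 2, colour = "firebrick") +
    labs(x = "soft-thresholding power", y = "scale-free fit index") +
    theme_minimal()
}

#' Relative module proximity bar plot
#' @param proximity a [module_proximity()] tibble.
#' @return A ggplot with the reference level at 1.
#' @export
plot_proximity <- function(proximity) {
  ggplot(proximity, aes(x = stats::reorder(.data$module, -.data$relative_proximity),
                        y = .data$relative_proximity)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = 1, linetype = 2, colour = "firebrick") +
    labs(x = "module", y = "relative average adjacency") +
    theme_minimal()
}

#' Bootstrap-network arc strength/direction plot
#' @param object a `bootstrap_network`.
#' @param ... unused.
#' @return A ggplot of arc strength against direction confidence.
#' @export
autoplot.bootstrap_network <- function(object, ...) {
  ggplot(object$edges, aes(x = .data$strength, y = .data$direction,
                           colour = .data$retained)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$strength_floor, linetype = 2) +
    labs(x = "arc strength", y = "direction confidence", colour = "retained") +
    theme_minimal()
}

#' Ranked connectivity-score plot for a drug screen
#' @param results a [normalize_scores()] tibble.
#' @param threshold screen threshold line (default -0.7).
#' @return A ggplot of ranked normalized connectivity scores.
#' @export
plot_connectivity <- function(results, threshold = -0.7) {
  df <- dplyr::arrange(results, .data$normalized_score) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot(df, aes(x = .data$rank, y = .data$normalized_score)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = threshold, linetype = 2, colour = "firebrick") +
    labs(x = "drug rank", y = "normalized connectivity score") +
    theme_minimal()
}
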