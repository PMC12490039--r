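# Gene-level preprocessing: transcript collapse, variability filter, and the
# two-group differential ranking that feeds GSEA and the drug-screen query.

#' Collapse duplicate transcripts to one row per gene symbol
#'
#' When several transcripts map to one gene symbol, the highest expressed
#' transcript (largest mean across samples) is retained. Ties are broken by
#' keeping the row that appears first in the input.
#'
#' @param expr wide expression tibble (first column `gene`).
#' @return Tibble with unique gene symbols, in order of first appearance.
#' @export
collapse_transcripts <- function(expr) {
  m <- as_expr_matrix(expr)
  means <- rowMeans(m)
  # within each symbol keep the highest mean; earlier row wins ties
  ord <- order(rownames(m), -means, seq_len(nrow(m)))
  keep_idx <- sort(ord[!duplicated(rownames(m)[ord])])
  expr[keep_idx, , drop = FALSE]
}

#' Filter out low-variability genes by median absolute deviation
#'
#' Computes each gene's MAD (median absolute deviation about the gene median)
#' and discards genes strictly below the first quartile of the MAD
#' distribution (linear-interpolation quantile). For continuous MAD
#' distributions this retains `ceiling(0.75 * G)` genes. With `center =
#' "mean"` the deviations are taken about the gene mean instead.
#'
#' @param expr wide expression tibble (first column `gene`).
#' @param center `"median"` (default) or `"mean"` centring of deviations.
#' @return Filtered tibble.
#' @export
mad_filter <- function(expr, center = c("median", "mean")) {
  center <- match.arg(center)
  m <- as_expr_matrix(expr)
  if (nrow(m) < 4) abort("mad_filter needs >= 4 genes")
  ctr <- if (center == "median") apply(m, 1, stats::median) else rowMeans(m)
  mads <- apply(abs(m - ctr), 1, stats::median)
  if (all(mads == 0)) {
    warn("all genes have zero MAD; nothing removed")
    return(expr)
  }
  q1 <- stats::quantile(mads, 0.25, type = 7, names = FALSE)
  expr[mads >= q1, , drop = FALSE]
}

#' Two-group differential expression ranking
#'
#' For data already on log2 scale, log2 fold change is the difference of
#' group means (condition B minus condition A), tested per gene by Welch's
#' t-test and adjusted by Benjamini-Hochberg. The result is sorted by log2
#' fold change, descending, with ties broken by gene symbol so the ranking
#' is total and reproducible.
#'
#' @param expr wide expression tibble (first column `gene`).
#' @param conditions tibble (`sample`, `condition`) with two levels; the
#'   lexicographically first level is treated as the reference (A).
#' @return Tibble (`gene`, `log2fc`, `t_stat`, `p_value`, `adj_p`) sorted by
#'   `log2fc` descending.
#' @export
differential_ranking <- function(expr, conditions) {
  m <- as_expr_matrix(expr)
  cond <- check_conditions(conditions, colnames(m))
  lv <- sort(unique(cond))
  if (length(lv) != 2) abort("exactly two condition levels required")
  a <- m[, cond == lv[1], drop = FALSE]
  b <- m[, cond == lv[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    abort("each condition needs >= 2 samples (variance undefined otherwise)")
  }
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[is.na(p)] <- 1  # zero-variance genes in both groups
  t_stat[is.na(t_stat)] <- 0
  tibble(gene = rownames(m), log2fc = unname(mb - ma), t_stat = unname(t_stat),
         p_value = unname(p), adj_p = unname(bh_adjust(p))) |>
    dplyr::arrange(dplyr::desc(.data$log2fc), .data$gene)
}
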