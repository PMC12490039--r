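# Internal helpers shared across stages.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Convert a wide expression tibble (first column = gene symbols) to a
# genes-by-samples numeric matrix. Errors name the offending cell so malformed
# TSVs are diagnosable.
as_expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  genes <- as.character(expr[[1]])
  vals <- expr[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      abort(sprintf("non-numeric expression value in column '%s', row %d",
                    names(vals)[j], if (is.na(bad)) 1L else bad))
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing expression value at gene '%s', sample '%s'",
                  genes[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- genes
  m
}

# Inverse of as_expr_matrix().
as_expr_tibble <- function(m) {
  tibble::as_tibble(cbind(tibble(gene = rownames(m)), as.data.frame(m)))
}

# Validate and align a (sample, condition) table against expression columns.
check_conditions <- function(conditions, sample_ids) {
  stopifnot(is.data.frame(conditions), all(c("sample", "condition") %in% names(conditions)))
  if (anyDuplicated(conditions$sample)) {
    abort("duplicate sample id in condition table")
  }
  missing <- setdiff(sample_ids, conditions$sample)
  if (length(missing) > 0) {
    abort(paste0("condition missing for sample(s): ", paste(missing, collapse = ", ")))
  }
  cond <- conditions$condition[match(sample_ids, conditions$sample)]
  if (length(unique(cond)) > 2) abort("more than two condition levels")
  as.character(cond)
}

# Derive a stream-specific RNG seed from a global seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483587L
}

# Wilcoxon-statistic AUROC of scores against binary truth (1 = positive).
auroc <- function(score, truth) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Benjamini-Hochberg via stats; kept as a single chokepoint.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
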