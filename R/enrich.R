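# Gene-set statistics: hypergeometric overrepresentation and the cluster
# enrichment score, rank-based gene set enrichment, partition overlap,
# ontology semantic similarity, and expression-matched signature scoring.

#' Gene-set overrepresentation analysis (hypergeometric)
#'
#' One-sided upper-tail hypergeometric test per gene set: with universe size
#' N, set size K, module size n and overlap k, `p = P(X >= k)`. Sets are
#' intersected with the universe; p-values are Benjamini-Hochberg adjusted
#' across the tested sets.
#'
#' @param module_genes character vector of module genes (subset of universe).
#' @param collection named list of gene sets, or a `geneset_collection`.
#' @param universe character vector of all eligible genes (the preprocessed
#'   gene list).
#' @return Tibble (`term`, `overlap_count`, `set_size`, `gene_ratio`,
#'   `p_value`, `adj_p`) sorted by `p_value`.
#' @export
gsoa <- function(module_genes, collection, universe) {
  sets <- if (inherits(collection, "geneset_collection")) collection$sets else collection
  if (length(universe) == 0) abort("empty universe")
  if (length(module_genes) == 0) abort("empty module")
  universe <- unique(universe)
  module_genes <- intersect(unique(module_genes), universe)
  n_univ <- length(universe)
  n_mod <- length(module_genes)
  res <- purrr::imap_dfr(sets, function(genes, nm) {
    set <- intersect(unique(genes), universe)
    k <- length(intersect(set, module_genes))
    p <- stats::phyper(k - 1, length(set), n_univ - length(set), n_mod,
                       lower.tail = FALSE)
    tibble(term = nm, overlap_count = k, set_size = length(set),
           gene_ratio = k / n_mod, p_value = p)
  })
  res$adj_p <- bh_adjust(res$p_value)
  dplyr::arrange(res, .data$p_value, .data$term)
}

#' Cluster enrichment score
#'
#' The absolute base-10 log of the most significant adjusted p-value among a
#' module's enrichment results: `CES = -log10(min adj_p)`. A module whose
#' best adjusted p-value is 0.001 scores exactly 3. Zero p-values are capped
#' at the double-precision floor with a warning.
#'
#' @param results a [gsoa()] result tibble (needs column `adj_p`).
#' @return Single numeric CES (>= 0).
#' @export
ces <- function(results) {
  stopifnot(nrow(results) >= 1, "adj_p" %in% names(results))
  best <- min(results$adj_p)
  if (best == 0) {
    warn("adjusted p-value of 0 capped at machine precision")
    best <- .Machine$double.xmin
  }
  abs(log10(best))
}

# Weighted running-sum enrichment of `hits` (logical, in ranking order) with
# scores `r` (same order, descending). Returns the full running sum.
running_sum <- function(r, hits, weight_p) {
  w <- abs(r)^weight_p
  nr <- sum(w[hits])
  n_miss <- sum(!hits)
  inc <- ifelse(hits, if (nr > 0) w / nr else 0, -1 / n_miss)
  cumsum(inc)
}

# ES = maximum deviation from zero of the running sum; on an exact absolute
# tie the positive extreme is reported.
es_from_running <- function(rs) {
  hi <- max(rs); lo <- min(rs)
  if (hi >= -lo) hi else lo
}

#' Gene set enrichment analysis on a fold-change ranking
#'
#' Classic weighted running-sum statistic: hit increments `|r_i|^p / sum|r|^p`,
#' miss decrements `1/(G - K)`; the enrichment score is the maximum deviation
#' from zero. Significance by gene-label permutation: the null re-draws the
#' hit positions uniformly; `NES = ES / mean |same-sign null ES|` and the
#' permutation p-value is the same-sign exceedance fraction.
#'
#' @param ranked a [differential_ranking()] tibble, or any tibble with
#'   columns `gene` and `log2fc` sorted by `log2fc` descending.
#' @param gene_set character vector of set members.
#' @param weight_p hit-weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-type statistic).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return One-row tibble (`es`, `nes`, `p_value`, `n_hits`, `n_perm`).
#' @export
gsea <- function(ranked, gene_set, weight_p = 1, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  genes <- ranked$gene
  r <- ranked$log2fc
  hits <- genes %in% gene_set
  k <- sum(hits)
  if (k == 0) abort("gene_set is disjoint from the ranking")
  if (k == length(genes)) abort("gene_set covers the whole ranking")
  es <- es_from_running(running_sum(r, hits, weight_p))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(length(genes))
    h[sample(length(genes), k)] <- TRUE
    es_from_running(running_sum(r, h, weight_p))
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0) {
    nes <- sign(es)
    p <- 1 / (n_perm + 1)
  } else {
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  tibble(es = es, nes = nes, p_value = p, n_hits = k, n_perm = n_perm)
}

#' Overlap statistics between two module partitions
#'
#' For every pair of modules (one from each partition) the Jaccard index
#' `|A intersect B| / |A union B|` and the upper-tail hypergeometric p-value
#' (universe = union of assigned genes) are computed, with BH adjustment
#' across all pairs.
#'
#' @param partition_a,partition_b `module_partition` objects or tibbles with
#'   columns `gene` and `module`.
#' @return Tibble (`module_a`, `module_b`, `jaccard`, `overlap_count`,
#'   `p_value`, `adj_p`, `empty_flag`).
#' @export
partition_overlap <- function(partition_a, partition_b) {
  a <- if (inherits(partition_a, "module_partition")) partition_a$assignment else partition_a
  b <- if (inherits(partition_b, "module_partition")) partition_b$assignment else partition_b
  mods_a <- sort(unique(a$module[a$module > 0]))
  mods_b <- sort(unique(b$module[b$module > 0]))
  universe <- union(a$gene[a$module > 0], b$gene[b$module > 0])
  n_univ <- length(universe)
  res <- purrr::map_dfr(mods_a, function(ma) {
    ga <- a$gene[a$module == ma]
    purrr::map_dfr(mods_b, function(mb) {
      gb <- b$gene[b$module == mb]
      k <- length(intersect(ga, gb))
      un <- length(union(ga, gb))
      j <- if (un == 0) 0 else k / un
      p <- stats::phyper(k - 1, length(gb), n_univ - length(gb), length(ga),
                         lower.tail = FALSE)
      tibble(module_a = ma, module_b = mb, jaccard = j, overlap_count = k,
             p_value = p, empty_flag = un == 0)
    })
  })
  res$adj_p <- bh_adjust(res$p_value)
  res
}

# Ancestors (inclusive) of a term in a child->parent edge table.
term_ancestors <- function(term, edges) {
  anc <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    anc <- union(anc, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], anc)
  }
  anc
}

#' Semantic similarity between two term sets over an ontology
#'
#' Pairwise term similarity by Lin's measure,
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` with information content
#' `IC = -log(annotation frequency)` from cumulative annotation counts, or by
#' Resnik's `IC(MICA)` (normalized by the maximum IC) behind the `measure`
#' flag. Set-level similarity is the best-match average. Pairs whose only
#' common ancestor is the root score 0.
#'
#' @param terms_a,terms_b character vectors of ontology terms.
#' @param ontology list with `edges` (tibble `child`, `parent`) and `counts`
#'   (named cumulative annotation counts including the root).
#' @param measure `"lin"` (default) or `"resnik"`.
#' @return Similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(terms_a, terms_b, ontology,
                                measure = c("lin", "resnik")) {
  measure <- match.arg(measure)
  edges <- ontology$edges
  counts <- ontology$counts
  all_terms <- union(unique(c(edges$child, edges$parent)), names(counts))
  missing <- setdiff(c(terms_a, terms_b), all_terms)
  if (length(missing) > 0) {
    abort(paste0("term(s) absent from ontology: ", paste(missing, collapse = ", ")))
  }
  root_n <- max(counts)
  ic <- -log(counts / root_n)
  max_ic <- max(ic)
  pair_sim <- function(t1, t2) {
    common <- intersect(term_ancestors(t1, edges), term_ancestors(t2, edges))
    mica_ic <- if (length(common) == 0) 0 else max(ic[common], na.rm = TRUE)
    if (measure == "resnik") return(if (max_ic > 0) mica_ic / max_ic else 0)
    denom <- ic[t1] + ic[t2]
    if (is.na(denom) || denom == 0) return(0)  # root-only pairs
    2 * mica_ic / denom
  }
  sim <- outer(terms_a, terms_b, Vectorize(pair_sim))
  # best-match average
  (mean(apply(sim, 1, max)) + mean(apply(sim, 2, max))) / 2
}

#' Expression-matched signature score per sample
#'
#' Genes are binned by average expression into `n_bins` equal-count bins;
#' each signature gene draws `n_ctrl` control genes from its bin, and the
#' score of a sample is the mean expression of the signature minus the mean
#' of the pooled controls — the standard control-matched module scoring used
#' for single-cell signature enrichment.
#'
#' @param expr wide expression tibble.
#' @param gene_set signature genes.
#' @param n_bins expression bins (default 24).
#' @param n_ctrl controls per signature gene (default 100; sampled with
#'   replacement, with a warning, when a bin is smaller).
#' @param seed integer RNG seed.
#' @return Tibble (`sample`, `score`).
#' @export
signature_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1) {
  m <- as_expr_matrix(expr)
  sig <- intersect(gene_set, rownames(m))
  if (length(sig) == 0) abort("gene_set has no genes in the matrix")
  set.seed(seed)
  avg <- rowMeans(m)
  bins <- ggplot2::cut_number(rank(avg, ties.method = "first"),
                              n = min(n_bins, nrow(m)), labels = FALSE)
  names(bins) <- rownames(m)
  small_bins <- 0L
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- names(bins)[bins == bins[g]]
    if (length(pool) < n_ctrl) {
      small_bins <<- small_bins + 1L
      sample(pool, n_ctrl, replace = TRUE)
    } else {
      sample(pool, n_ctrl)
    }
  }))
  if (small_bins > 0) {
    warn(sprintf("%d signature gene(s) sit in bins smaller than n_ctrl; controls sampled with replacement",
                 small_bins))
  }
  score <- colMeans(m[sig, , drop = FALSE]) - colMeans(m[ctrl, , drop = FALSE])
  tibble(sample = colnames(m), score = unname(score))
}
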