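# Weighted co-expression network construction: soft-thresholded adjacency,
# scale-free topology criterion, topological overlap, module detection by
# average-linkage clustering of TOM dissimilarity, eigengene computation and
# merging, and the module-proximity statistic.

#' Soft-thresholded Pearson adjacency
#'
#' Computes `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the default) or
#' `((1 + cor)/2)^beta` (signed) between all gene pairs. Genes with zero
#' variance are removed with a warning before computation.
#'
#' @param expr wide expression tibble (first column `gene`).
#' @param power soft-thresholding power beta (>= 1).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return Gene-by-gene adjacency matrix of class `adjacency_matrix` with
#'   attributes `power` and `mode`. The diagonal is set to 0 (excluded from
#'   connectivity).
#' @export
pearson_adjacency <- function(expr, power = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  stopifnot(power >= 1)
  m <- as_expr_matrix(expr)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("removing %d zero-variance gene(s) before adjacency", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  structure(a, power = power, mode = mode,
            class = c("adjacency_matrix", class(a)))
}

#' Scale-free topology fit index
#'
#' Connectivity `k_i = sum_j a_ij` is binned into `n_bins` equal-width bins
#' on the log10 scale; the index is the R-squared of the regression of
#' log10(frequency) on log10(mean connectivity) per bin, signed by the slope
#' (a negative slope yields a positive index, so positively sloped fits
#' cannot pass).
#'
#' @param adjacency an [pearson_adjacency()] matrix.
#' @param n_bins number of connectivity bins (default 10).
#' @return Signed fit index in `[-1, 1]`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  if (nrow(adjacency) < 10) abort("scale_free_fit needs >= 10 genes")
  k <- rowSums(adjacency)
  k <- k[k > 0]
  if (length(unique(signif(k, 12))) < 2) {
    warn("constant connectivity; scale-free index reported as 0")
    return(0)
  }
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9
  bin <- cut(lk, br, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  mean_k <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(mean_k)
  if (sum(ok) < 3) {
    warn("too few occupied connectivity bins; scale-free index reported as 0")
    return(0)
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] < 0) r2 else -r2
}

#' Choose the soft-thresholding power by the scale-free criterion
#'
#' Scans candidate powers and returns the smallest whose scale-free fit index
#' reaches `fit_threshold`; if none qualifies, the argmax is returned with a
#' warning. The full scan is attached as attribute `scan`.
#'
#' @param expr wide expression tibble.
#' @param candidate_powers powers to scan (default 1:10).
#' @param fit_threshold required fit index (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @param mode adjacency mode.
#' @return Selected power with attribute `scan` (tibble `power`, `fit_index`,
#'   `mean_k`).
#' @export
pick_soft_power <- function(expr, candidate_powers = 1:10, fit_threshold = 0.8,
                            n_bins = 10, mode = "unsigned") {
  stopifnot(length(candidate_powers) > 0)
  m <- as_expr_matrix(expr)
  v <- apply(m, 1, stats::var)
  m <- m[v > 0, , drop = FALSE]
  r <- stats::cor(t(m))
  base <- if (mode == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- 0
  scan <- purrr::map_dfr(candidate_powers, function(p) {
    a <- base^p
    diag(a) <- 0
    tibble(power = p,
           fit_index = suppressWarnings(scale_free_fit(a, n_bins)),
           mean_k = mean(rowSums(a)))
  })
  pass <- scan$power[scan$fit_index >= fit_threshold]
  if (length(pass) > 0) {
    beta <- min(pass)
  } else {
    beta <- scan$power[which.max(scan$fit_index)]
    warn(sprintf(paste0("no candidate power reached fit index %.2f; ",
                        "falling back to argmax (power %s)"), fit_threshold, beta))
  }
  structure(beta, scan = scan)
}

#' Topological overlap matrix
#'
#' Standard unsigned TOM:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj`, diagonal similarity 1.
#'
#' @param adjacency an [pearson_adjacency()] matrix (diagonal 0).
#' @return Matrix of class `tom_matrix`; dissimilarity for clustering is
#'   `1 - TOM`.
#' @export
tom_similarity <- function(adjacency) {
  a <- unclass(adjacency)
  diag(a) <- 0
  l <- a %*% a            # l_ij sums over all u != i, j since diag(a) = 0
  k <- rowSums(a)
  n <- length(k)
  min_k <- pmin(matrix(k, n, n), matrix(k, n, n, byrow = TRUE))
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  structure(tom, class = c("tom_matrix", class(tom)))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically. The
#' default cut height of 0.8 sits between typical within-module join heights
#' (below ~0.75 at power 6 for gene correlations of 0.55 and above) and
#' cross-module join heights (0.9 and up for modestly coupled modules), so
#' genuinely co-expressed blocks separate without fragmenting. Clusters
#' below `min_module_size` are unassigned (module 0); labels are ordered by
#' decreasing module size.
#'
#' @param tom a [tom_similarity()] matrix.
#' @param min_module_size smallest retained module (default 30, >= 3).
#' @param cut_height static cut height on TOM dissimilarity (default 0.8).
#' @return A `module_partition` object: list with `assignment` (tibble
#'   `gene`, `module`), `dendrogram` (the hclust tree), and empty eigengene
#'   slots to be filled by [module_eigengenes()].
#' @export
cluster_modules <- function(tom, min_module_size = 30, cut_height = 0.8) {
  stopifnot(min_module_size >= 3)
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warn("fewer genes than min_module_size; all genes unassigned")
    part <- tibble(gene = genes, module = 0L)
    return(new_module_partition(part, dendrogram = NULL))
  }
  diss <- stats::as.dist(1 - unclass(tom))
  tree <- stats::hclust(diss, method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- integer(length(raw))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) module[raw == as.integer(ord[i])] <- i
  }
  new_module_partition(tibble(gene = genes, module = module), dendrogram = tree)
}

new_module_partition <- function(assignment, eigengenes = NULL,
                                 variance_explained = NULL, dendrogram = NULL) {
  structure(list(assignment = assignment, eigengenes = eigengenes,
                 variance_explained = variance_explained,
                 dendrogram = dendrogram),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(x$assignment$module[x$assignment$module > 0])
  cat(sprintf("module_partition: %d genes, %d modules (sizes %s), %d unassigned\n",
              nrow(x$assignment), length(sizes),
              paste(sizes, collapse = "/"),
              sum(x$assignment$module == 0)))
  if (!is.null(x$eigengenes)) {
    cat(sprintf("eigengenes computed for %d modules over %d samples\n",
                nrow(x$eigengenes), ncol(x$eigengenes)))
  }
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardized module submatrix with samples as observations, scaled to unit
#' norm and sign-aligned so it correlates positively with the module's mean
#' expression profile. The fraction of variance explained is recorded.
#'
#' @param expr wide expression tibble.
#' @param partition a `module_partition`.
#' @return The partition with `eigengenes` (module-by-sample matrix, rows
#'   `M1`, `M2`, ...) and `variance_explained` (tibble) filled.
#' @export
module_eigengenes <- function(expr, partition) {
  m <- as_expr_matrix(expr)
  assign <- partition$assignment
  mods <- sort(unique(assign$module[assign$module > 0]))
  if (length(mods) == 0) abort("no modules to compute eigengenes for")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(m),
               dimnames = list(paste0("M", mods), colnames(m)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    genes <- assign$gene[assign$module == mods[i]]
    if (length(genes) < 3) abort(sprintf("module %d has fewer than 3 genes", mods[i]))
    sub <- t(m[genes, , drop = FALSE])          # samples x genes
    if (any(apply(sub, 2, stats::var) == 0)) {
      abort(sprintf("module %d contains constant genes; eigengene undefined", mods[i]))
    }
    xs <- scale(sub)
    sv <- svd(xs, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::cor(e, rowMeans(xs)) < 0) e <- -e
    me[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  new_module_partition(assign, eigengenes = me,
                       variance_explained = tibble(module = mods,
                                                   variance_explained = ve),
                       dendrogram = partition$dendrogram)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` while that dissimilarity is below
#' `me_diss_threshold` (default 0.25), recomputing eigengenes after each
#' merge. Labels are re-ordered by decreasing module size on exit, so the
#' result does not depend on the initial labelling.
#'
#' @param expr wide expression tibble.
#' @param partition a `module_partition` (eigengenes are computed as needed).
#' @param me_diss_threshold merge threshold on eigengene dissimilarity.
#' @return Merged `module_partition` with eigengenes recomputed.
#' @export
merge_modules <- function(expr, partition, me_diss_threshold = 0.25) {
  part <- module_eigengenes(expr, partition)
  repeat {
    me <- part$eigengenes
    if (nrow(me) < 2) break
    d <- 1 - stats::cor(t(me))
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)
    # deterministic pick: smallest label pair among ties
    idx <- idx[order(rownames(me)[idx[, 1]], rownames(me)[idx[, 2]]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    if (d[i, j] >= me_diss_threshold) break
    la <- as.integer(sub("^M", "", rownames(me)[min(i, j)]))
    lb <- as.integer(sub("^M", "", rownames(me)[max(i, j)]))
    assign <- part$assignment
    assign$module[assign$module == lb] <- la
    part <- module_eigengenes(expr, new_module_partition(assign,
                                                         dendrogram = part$dendrogram))
  }
  # relabel by decreasing size
  assign <- part$assignment
  sizes <- table(assign$module[assign$module > 0])
  ord <- as.integer(names(sizes)[order(-sizes, as.integer(names(sizes)))])
  new <- integer(nrow(assign))
  for (i in seq_along(ord)) new[assign$module == ord[i]] <- i
  module_eigengenes(expr, new_module_partition(
    tibble(gene = assign$gene, module = new), dendrogram = part$dendrogram))
}

#' Relative average adjacency of modules to a focal module
#'
#' For each non-focal module, the mean adjacency over pairs (focal gene,
#' module gene) is computed; the reference is the mean adjacency between the
#' focal module and all non-focal genes, normalized to 1. A `reference` row
#' carries the reference group itself.
#'
#' @param adjacency an [pearson_adjacency()] matrix.
#' @param partition a `module_partition`.
#' @param focal_module integer label of the focal module.
#' @return Tibble (`module`, `avg_adjacency`, `relative_proximity`) with a
#'   final `reference` row whose relative value is exactly 1.
#' @export
module_proximity <- function(adjacency, partition, focal_module) {
  assign <- partition$assignment
  assign <- assign[assign$gene %in% rownames(adjacency), ]
  focal <- assign$gene[assign$module == focal_module]
  if (length(focal) == 0) abort("focal module not found in adjacency")
  others <- sort(unique(assign$module[assign$module != focal_module & assign$module > 0]))
  if (length(others) == 0) abort("focal module is the only module")
  nonfocal_genes <- assign$gene[assign$module != focal_module & assign$module > 0]
  a <- unclass(adjacency)
  ref <- mean(a[focal, nonfocal_genes])
  rows <- purrr::map_dfr(others, function(mm) {
    mg <- assign$gene[assign$module == mm]
    tibble(module = as.character(mm), avg_adjacency = mean(a[focal, mg]))
  })
  rows <- dplyr::bind_rows(rows, tibble(module = "reference", avg_adjacency = ref))
  dplyr::mutate(rows, relative_proximity = .data$avg_adjacency / ref)
}
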