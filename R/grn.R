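# Regulator prioritization: tree-ensemble importance GRN, mutual-information
# GRN with data-processing-inequality pruning, weighted node-degree TF
# ranking, and three-way consensus with a motif-support table.

#' Tree-ensemble regulatory importances
#'
#' For each target gene, an extra-trees ensemble regresses the target on all
#' candidate regulators (excluding the target itself); per-target
#' variance-reduction importances are normalized to sum to one and become the
#' directed regulator-to-target edge weights.
#'
#' @param expr wide expression tibble.
#' @param regulators character vector of candidate regulator genes (>= 2,
#'   subset of the matrix genes).
#' @param targets optional target genes (default: all genes).
#' @param n_trees trees per ensemble (default 1000).
#' @param seed integer RNG seed.
#' @return A `grn_weights` object: regulator-by-target weight matrix with
#'   attribute `method = "genie3"`.
#' @export
genie3_weights <- function(expr, regulators, targets = NULL, n_trees = 1000,
                           seed = 1) {
  m <- as_expr_matrix(expr)
  if (!all(regulators %in% rownames(m))) {
    abort("regulators must be a subset of the matrix genes")
  }
  if (length(regulators) < 2) abort("need >= 2 regulators")
  if (is.null(targets)) targets <- rownames(m)
  w <- matrix(0, nrow = length(regulators), ncol = length(targets),
              dimnames = list(regulators, targets))
  xs <- t(m[regulators, , drop = FALSE])  # samples x regulators
  for (i in seq_along(targets)) {
    tg <- targets[i]
    y <- m[tg, ]
    if (stats::var(y) == 0) {
      warn(sprintf("target %s has zero variance; skipped", tg))
      next
    }
    preds <- setdiff(regulators, tg)
    if (length(preds) < 2) next
    fit <- ranger::ranger(
      x = xs[, preds, drop = FALSE], y = y,
      num.trees = n_trees,
      mtry = max(1, floor(sqrt(length(preds)))),
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1,
      importance = "impurity",
      seed = derive_seed(seed, i), num.threads = 1)
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) > 0) w[preds, tg] <- imp / sum(imp)
  }
  structure(w, method = "genie3", class = c("grn_weights", class(w)))
}

#' Pairwise mutual information matrix
#'
#' Equal-frequency discretization into `n_bins` bins (default the cube-root
#' rule `ceiling(n^(1/3))`, which keeps the Miller-Madow-corrected estimator
#' essentially unbiased on independent data at typical sample sizes),
#' maximum-likelihood MI in nats with Miller-Madow bias correction, clipped
#' at zero. Constant genes get zero rows with a warning.
#'
#' @param expr wide expression tibble.
#' @param n_bins number of bins; `NULL` for the cube-root rule.
#' @return Symmetric gene-by-gene MI matrix (nats), diagonal 0.
#' @export
mi_matrix <- function(expr, n_bins = NULL) {
  m <- as_expr_matrix(expr)
  n <- ncol(m)
  if (n < 8) abort("mi_matrix needs >= 8 samples")
  if (is.null(n_bins)) n_bins <- max(2L, ceiling(n^(1 / 3)))
  b <- as.integer(n_bins)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) warn(sprintf("%d constant gene(s); MI rows set to 0", sum(v == 0)))
  g <- nrow(m)
  disc <- matrix(0L, nrow = g, ncol = n)
  for (i in seq_len(g)) {
    disc[i, ] <- ceiling(rank(m[i, ], ties.method = "first") * b / n)
  }
  marg <- lapply(seq_len(g), function(i) tabulate(disc[i, ], b) / n)
  h_marg <- vapply(seq_len(g), function(i) {
    p <- marg[[i]][marg[[i]] > 0]
    -sum(p * log(p)) + (sum(marg[[i]] > 0) - 1) / (2 * n)
  }, numeric(1))
  mi <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(g - 1)) {
    if (v[i] == 0) next
    di <- disc[i, ]
    for (j in seq(i + 1, g)) {
      if (v[j] == 0) next
      joint <- tabulate((di - 1L) * b + disc[j, ], b * b) / n
      pj <- joint[joint > 0]
      h_joint <- -sum(pj * log(pj)) + (length(pj) - 1) / (2 * n)
      mi[i, j] <- mi[j, i] <- max(0, h_marg[i] + h_marg[j] - h_joint)
    }
  }
  mi
}

#' Data-processing-inequality pruning of an MI network
#'
#' In every complete triangle, the weakest edge (ties broken by
#' lexicographic gene-pair order) is removed when it is at most
#' `(1 - epsilon)` times the smaller of the other two edges; fully tied
#' triangles are left intact. On continuous data this coincides with strict
#' DPI pruning. Decisions are taken on the input matrix (mark-and-sweep),
#' which makes the operation idempotent. If `regulators` is given, the
#' surviving entries are restricted to regulator rows.
#'
#' @param mi symmetric MI matrix.
#' @param regulators optional regulator gene names.
#' @param epsilon DPI tolerance (default 0, strict).
#' @return The pruned matrix; with `regulators`, a `grn_weights`
#'   regulator-by-target matrix (`method = "aracne"`, self-edges zeroed).
#' @export
dpi_prune <- function(mi, regulators = NULL, epsilon = 0) {
  w <- unclass(mi)
  g <- nrow(w)
  genes <- rownames(w)
  remove <- matrix(FALSE, g, g)
  ties_present <- anyDuplicated(w[upper.tri(w)][w[upper.tri(w)] > 0]) > 0
  if (!ties_present) {
    # vectorized strict DPI: edge (i,j) goes when some k dominates it
    for (k in seq_len(g)) {
      cap <- outer(w[, k], w[k, ], pmin)     # min(w_ik, w_kj) for all (i, j)
      dom <- w > 0 & w[, k] > 0 & w[k, ] > 0 & w < (1 - epsilon) * cap
      remove <- remove | dom
    }
    diag(remove) <- FALSE
  } else {
    # exact per-triangle pass with the documented tie-break
    for (i in seq_len(g - 2)) {
      for (j in seq(i + 1, g - 1)) {
        if (w[i, j] == 0) next
        for (k in seq(j + 1, g)) {
          if (w[i, k] == 0 || w[j, k] == 0) next
          e <- rbind(c(i, j), c(i, k), c(j, k))
          vals <- w[e]
          if (length(unique(vals)) == 1) next  # fully tied triangle
          ord <- order(vals, genes[e[, 1]], genes[e[, 2]])
          weakest <- e[ord[1], , drop = FALSE]
          others <- vals[ord[2:3]]
          if (vals[ord[1]] <= (1 - epsilon) * min(others)) {
            remove[weakest[1], weakest[2]] <- TRUE
            remove[weakest[2], weakest[1]] <- TRUE
          }
        }
      }
    }
  }
  w[remove | t(remove)] <- 0
  if (is.null(regulators)) return(w)
  out <- w[regulators, , drop = FALSE]
  for (r in regulators) out[r, r] <- 0
  structure(out, method = "aracne", class = c("grn_weights", class(out)))
}

#' Rank regulators by weighted node degree into a target set
#'
#' The node degree of a regulator is the sum of its edge weights into the
#' target gene set; the top `top_k` regulators are returned in non-increasing
#' degree order, ties broken alphabetically.
#'
#' @param weights a `grn_weights` matrix (regulators-by-targets).
#' @param target_set character vector of target genes (e.g. a module).
#' @param top_k ranking length (default 100).
#' @return Tibble (`rank`, `tf`, `node_degree`, `method`).
#' @export
rank_tfs <- function(weights, target_set, top_k = 100) {
  if (length(target_set) == 0) abort("target_set is empty")
  tg <- intersect(colnames(weights), target_set)
  deg <- if (length(tg) == 0) stats::setNames(rep(0, nrow(weights)), rownames(weights))
         else rowSums(weights[, tg, drop = FALSE])
  if (all(deg == 0)) warn("no regulator touches the target set")
  ord <- order(-deg, names(deg))
  keep <- ord[seq_len(min(top_k, length(ord)))]
  tibble(rank = seq_along(keep), tf = names(deg)[keep],
         node_degree = unname(deg[keep]),
         method = attr(weights, "method") %||% "unknown")
}

#' Consensus transcription factors across two rankings and motif support
#'
#' Stage 1 intersects the two top-k rankings; stage 2 keeps stage-1 members
#' whose motif-support NES reaches `nes_floor` for at least one target inside
#' the module. Per-TF provenance (method ranks, best NES, motif target
#' count) is reported. Consensus operates on ranks only — weights from
#' different engines are not comparable.
#'
#' @param ranking_a,ranking_b [rank_tfs()] tibbles over the same regulator
#'   universe.
#' @param motif_table tibble (`tf`, `target`, `nes`); may be empty.
#' @param module_genes genes of the focal module (motif targets outside it
#'   are ignored); `NULL` to accept any target.
#' @param nes_floor minimum motif NES (default 3).
#' @return Tibble (`tf`, `rank_a`, `rank_b`, `best_nes`, `motif_targets`,
#'   `consensus`) where `consensus` is `TRUE` for stage-2 members; stage 1 is
#'   the full set of rows.
#' @export
consensus_tfs <- function(ranking_a, ranking_b, motif_table,
                          module_genes = NULL, nes_floor = 3) {
  stage1 <- intersect(ranking_a$tf, ranking_b$tf)
  if (length(stage1) == 0) {
    return(tibble(tf = character(0), rank_a = integer(0), rank_b = integer(0),
                  best_nes = numeric(0), motif_targets = integer(0),
                  consensus = logical(0)))
  }
  mt <- motif_table
  if (is.null(mt) || nrow(mt) == 0) {
    warn("empty motif table; stage-2 consensus is empty")
    mt <- tibble(tf = character(0), target = character(0), nes = numeric(0))
  }
  if (!is.null(module_genes)) mt <- dplyr::filter(mt, .data$target %in% module_genes)
  out <- purrr::map_dfr(sort(stage1), function(tf) {
    rows <- mt[mt$tf == tf & mt$nes >= nes_floor, , drop = FALSE]
    tibble(tf = tf,
           rank_a = ranking_a$rank[match(tf, ranking_a$tf)],
           rank_b = ranking_b$rank[match(tf, ranking_b$tf)],
           best_nes = if (nrow(rows) > 0) max(rows$nes) else NA_real_,
           motif_targets = nrow(rows),
           consensus = nrow(rows) > 0)
  })
  dplyr::arrange(out, dplyr::desc(.data$consensus), .data$rank_a + .data$rank_b, .data$tf)
}

#' Regulon subnetwork of consensus TFs over a module
#'
#' Edges from consensus TFs to module genes that have motif support, weighted
#' by the GRN weight; reports coverage (fraction of module genes reached) as
#' attribute `coverage`.
#'
#' @param weights a `grn_weights` matrix.
#' @param consensus a [consensus_tfs()] tibble (rows with `consensus = TRUE`
#'   are used).
#' @param module_genes genes of the focal module.
#' @param motif_table tibble (`tf`, `target`, `nes`).
#' @param nes_floor minimum motif NES (default 3).
#' @return Edge tibble (`tf`, `target`, `weight`, `nes`) with attribute
#'   `coverage`.
#' @export
regulon_subnetwork <- function(weights, consensus, module_genes, motif_table,
                               nes_floor = 3) {
  tfs <- consensus$tf[consensus$consensus]
  if (length(tfs) == 0) abort("consensus is empty")
  mt <- dplyr::filter(motif_table, .data$tf %in% tfs,
                      .data$target %in% module_genes, .data$nes >= nes_floor)
  if (nrow(mt) == 0) {
    return(structure(tibble(tf = character(0), target = character(0),
                            weight = numeric(0), nes = numeric(0)),
                     coverage = 0))
  }
  edges <- purrr::pmap_dfr(mt, function(tf, target, nes, ...) {
    w <- if (tf %in% rownames(weights) && target %in% colnames(weights)) {
      weights[tf, target]
    } else 0
    tibble(tf = tf, target = target, weight = w, nes = nes)
  })
  coverage <- length(unique(edges$target)) / length(unique(module_genes))
  structure(dplyr::arrange(edges, .data$tf, .data$target), coverage = coverage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
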