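# Bayesian network structure learning over module eigengenes: Gaussian-BIC
# hill climbing with random restarts, an exhaustive small-network oracle, and
# bootstrap aggregation with strength/direction thresholds.

# ---- Gaussian BIC local scores -------------------------------------------

# Local BIC (natural-log units) of `node` given `parents`, computed on the
# sample-by-node matrix `x` and memoised in `cache`.
local_bic <- function(x, node, parents, cache) {
  key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  y <- x[, node]
  n <- length(y)
  if (length(parents) == 0) {
    rss <- sum((y - mean(y))^2)
  } else {
    fit <- stats::lm.fit(cbind(1, x[, parents, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
  }
  sigma2 <- max(rss / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  val <- ll - 0.5 * (length(parents) + 2) * log(n)
  cache[[key]] <- val
  val
}

dag_score <- function(x, adj, cache) {
  nodes <- colnames(adj)
  sum(vapply(nodes, function(v) {
    local_bic(x, v, nodes[adj[, v]], cache)
  }, numeric(1)))
}

# TRUE if a directed path from -> to exists in adj.
has_path <- function(adj, from, to) {
  seen <- stats::setNames(logical(nrow(adj)), rownames(adj))
  frontier <- from
  while (length(frontier) > 0) {
    seen[frontier] <- TRUE
    nxt <- colnames(adj)[colSums(adj[frontier, , drop = FALSE]) > 0]
    frontier <- nxt[!seen[nxt]]
  }
  seen[to]
}

# Boolean transitive closure (Warshall), used for cycle checks on add moves.
reachability <- function(adj) {
  reach <- adj
  for (k in seq_len(ncol(adj))) {
    reach <- reach | outer(reach[, k], reach[k, ], `&`)
  }
  reach
}

adj_to_edges <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  tibble(from = rownames(adj)[idx[, 1]], to = colnames(adj)[idx[, 2]]) |>
    dplyr::arrange(.data$from, .data$to)
}

check_bn_data <- function(data) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    abort(paste0("constant node(s): ", paste(colnames(x)[v == 0], collapse = ", ")))
  }
  x
}

# One greedy hill climb from a given start adjacency; deterministic move
# enumeration with lexicographic (from, to) tie-breaks.
hc_once <- function(x, adj, cache) {
  nodes <- colnames(x)
  score <- dag_score(x, adj, cache)
  repeat {
    best <- list(delta = 1e-10, apply = NULL)
    reach <- reachability(adj)
    for (from in nodes) {
      for (to in nodes) {
        if (from == to) next
        if (!adj[from, to] && !adj[to, from]) {
          if (reach[to, from]) next  # would create a cycle
          old <- local_bic(x, to, nodes[adj[, to]], cache)
          new <- local_bic(x, to, c(nodes[adj[, to]], from), cache)
          d <- new - old
          if (d > best$delta) best <- list(delta = d, apply = c("add", from, to))
        } else if (adj[from, to]) {
          old <- local_bic(x, to, nodes[adj[, to]], cache)
          new <- local_bic(x, to, setdiff(nodes[adj[, to]], from), cache)
          d <- new - old
          if (d > best$delta) best <- list(delta = d, apply = c("delete", from, to))
          # reverse from -> to
          adj[from, to] <- FALSE
          cyclic <- has_path(adj, from, to)
          adj[from, to] <- TRUE
          if (!cyclic) {
            old2 <- local_bic(x, from, nodes[adj[, from]], cache)
            new2 <- local_bic(x, from, c(nodes[adj[, from]], to), cache)
            d2 <- (new - old) + (new2 - old2)
            if (d2 > best$delta) best <- list(delta = d2, apply = c("reverse", from, to))
          }
        }
      }
    }
    if (is.null(best$apply)) break
    op <- best$apply
    if (op[1] == "add") adj[op[2], op[3]] <- TRUE
    if (op[1] == "delete") adj[op[2], op[3]] <- FALSE
    if (op[1] == "reverse") { adj[op[2], op[3]] <- FALSE; adj[op[3], op[2]] <- TRUE }
    score <- score + best$delta
  }
  list(adj = adj, score = dag_score(x, adj, cache))
}

random_start_adj <- function(nodes, p_edge = stats::runif(1, 0.1, 0.5)) {
  k <- length(nodes)
  ord <- sample(nodes)
  adj <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (stats::runif(1) < p_edge) adj[ord[i], ord[j]] <- TRUE
    }
  }
  adj
}

# Perturb a DAG by a few random edge removals/reversals/insertions while
# keeping it acyclic; used to escape local optima between restarts.
perturb_adj <- function(adj, n_moves = 3) {
  nodes <- rownames(adj)
  for (m in seq_len(n_moves)) {
    i <- sample(nodes, 1); j <- sample(setdiff(nodes, i), 1)
    if (adj[i, j]) {
      adj[i, j] <- FALSE
      if (stats::runif(1) < 0.5 && !has_path(adj, i, j)) adj[j, i] <- TRUE
    } else if (!adj[j, i]) {
      if (!has_path(adj, j, i)) adj[i, j] <- TRUE
    }
  }
  adj
}

#' Hill-climbing Bayesian network structure search
#'
#' Greedy hill climbing over single-edge add/delete/reverse moves with a
#' Gaussian BIC score (natural-log units) and random restarts. Moves are
#' enumerated in a fixed lexicographic order, so the search is deterministic
#' under a fixed seed. The first restart starts from the empty graph.
#'
#' @param data sample-by-node numeric matrix or data frame.
#' @param seed integer RNG seed (governs the random restarts).
#' @param n_restarts number of hill climbs (default 10).
#' @return A `dag_structure`: list with `nodes`, `edges` (tibble `from`,
#'   `to`) and `score` (total BIC).
#' @export
hc_search <- function(data, seed = 1, n_restarts = 10) {
  x <- check_bn_data(data)
  if (nrow(x) < 3 * ncol(x)) {
    warn("fewer than 3 samples per node; structure estimates will be unstable")
  }
  set.seed(seed)
  nodes <- colnames(x)
  cache <- new.env(parent = emptyenv())
  empty <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  best <- hc_once(x, empty, cache)
  if (n_restarts > 1) {
    for (r in seq_len(n_restarts - 1)) {
      start <- if (r %% 2 == 0) perturb_adj(best$adj) else random_start_adj(nodes)
      res <- hc_once(x, start, cache)
      if (res$score > best$score + 1e-9) best <- res
    }
  }
  structure(list(nodes = nodes, edges = adj_to_edges(best$adj),
                 score = best$score, adjacency = best$adj),
            class = "dag_structure")
}

#' @export
print.dag_structure <- function(x, ...) {
  cat(sprintf("dag_structure: %d nodes, %d edges, BIC %.3f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}

#' Exhaustive Bayesian network search (test oracle, <= 4 nodes)
#'
#' Enumerates every DAG on up to four nodes (25 structures for three nodes,
#' 543 for four) and returns the globally BIC-optimal one.
#'
#' @param data sample-by-node numeric matrix or data frame with <= 4 columns.
#' @return A `dag_structure` with attribute `n_structures`.
#' @export
exhaustive_dag_search <- function(data) {
  x <- check_bn_data(data)
  nodes <- colnames(x)
  p <- length(nodes)
  if (p > 4) abort("exhaustive search refuses more than 4 nodes")
  cache <- new.env(parent = emptyenv())
  pairs <- if (p >= 2) utils::combn(p, 2) else matrix(integer(0), 2, 0)
  n_pairs <- ncol(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), n_pairs)))
  best <- NULL; best_score <- -Inf; n_dags <- 0L
  for (s in seq_len(max(1, nrow(states)))) {
    adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    if (n_pairs > 0) {
      st <- states[s, ]
      for (q in seq_len(n_pairs)) {
        if (st[q] == 1) adj[pairs[1, q], pairs[2, q]] <- TRUE
        if (st[q] == 2) adj[pairs[2, q], pairs[1, q]] <- TRUE
      }
    }
    ix <- which(adj, arr.ind = TRUE)
    if (is.null(topo_order_edges(p, data.frame(from = ix[, 1], to = ix[, 2])))) next
    n_dags <- n_dags + 1L
    sc <- dag_score(x, adj, cache)
    if (sc > best_score) { best_score <- sc; best <- adj }
  }
  structure(list(nodes = nodes, edges = adj_to_edges(best), score = best_score,
                 adjacency = best),
            class = "dag_structure", n_structures = n_dags)
}

#' Restrict eigengenes to modules passing a cluster-enrichment-score cut
#'
#' Keeps only modules whose CES strictly exceeds `ces_threshold` (default 3,
#' i.e. best adjusted p-value below 0.001), preserving row order.
#'
#' @param ces_scores tibble (`module`, `ces`).
#' @param eigengenes module-by-sample eigengene matrix (rows `M<label>`).
#' @param ces_threshold strict lower bound on CES.
#' @return Eigengene submatrix.
#' @export
select_bn_inputs <- function(ces_scores, eigengenes, ces_threshold = 3) {
  pass <- ces_scores$module[ces_scores$ces > ces_threshold]
  rows <- rownames(eigengenes) %in% c(as.character(pass), paste0("M", pass))
  if (!any(rows)) {
    abort("no module passes the CES threshold; consider lowering it")
  }
  eigengenes[rows, , drop = FALSE]
}

#' Bootstrap-aggregated Bayesian network
#'
#' Resamples the rows of `data` with replacement `n_boot` times, learns one
#' hill-climbing DAG per replicate, and tallies for every edge its strength
#' (fraction of replicates containing the edge in either direction) and
#' direction (fraction of those supporting the reported orientation). The
#' averaged network keeps, by default, arcs whose undirected strength reaches
#' `aggregate_threshold`, oriented by majority direction, then removes arcs
#' with `strength < strength_floor`; `threshold_on = "support"` instead
#' applies `aggregate_threshold` to the direction-aware support
#' (`strength * direction`), a stricter rule that also demands orientation
#' consensus and therefore discards arcs whose direction is not identifiable
#' from observational data. If the
#' thresholded network contains a cycle, the lowest-support arc inside a
#' cyclic component is dropped iteratively.
#'
#' @param data sample-by-node numeric matrix (e.g. transposed eigengenes).
#' @param n_boot bootstrap replicates (>= 100; the study-scale default is
#'   1000).
#' @param aggregate_threshold averaged-network inclusion threshold in (0, 1].
#' @param strength_floor minimum retained strength (default 0.7).
#' @param seed integer RNG seed.
#' @param n_restarts hill-climbing restarts per replicate (default 1).
#' @param threshold_on `"strength"` (default) or `"support"`.
#' @return A `bootstrap_network`: list with `edges` (all observed arcs with
#'   `strength`, `direction`, `support`, `retained`), `retained` (the
#'   averaged network arcs), and the settings used.
#' @export
bootstrap_network <- function(data, n_boot = 1000, aggregate_threshold = 0.85,
                              strength_floor = 0.7, seed = 1, n_restarts = 1,
                              threshold_on = c("strength", "support")) {
  threshold_on <- match.arg(threshold_on)
  if (n_boot < 100) abort("n_boot must be >= 100")
  if (aggregate_threshold <= 0 || aggregate_threshold > 1) {
    abort("configuration error: aggregate_threshold must be in (0, 1]",
          class = "plaquenet_config_error")
  }
  x <- check_bn_data(data)
  nodes <- colnames(x)
  k <- length(nodes)
  counts <- matrix(0, k, k, dimnames = list(nodes, nodes))
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    idx <- sample(nrow(x), replace = TRUE)
    xb <- x[idx, , drop = FALSE]
    if (any(apply(xb, 2, stats::var) == 0)) next
    fit <- hc_search(xb, seed = derive_seed(seed, n_boot + b),
                     n_restarts = n_restarts)
    counts <- counts + fit$adjacency
  }
  edges <- purrr::map_dfr(seq_len(k - 1), function(i) {
    purrr::map_dfr(seq(i + 1, k), function(j) {
      both <- counts[i, j] + counts[j, i]
      if (both == 0) return(NULL)
      if (counts[i, j] >= counts[j, i]) { f <- nodes[i]; t <- nodes[j]; c_f <- counts[i, j] }
      else { f <- nodes[j]; t <- nodes[i]; c_f <- counts[j, i] }
      tibble(from = f, to = t, strength = both / n_boot,
             direction = c_f / both, support = c_f / n_boot)
    })
  })
  if (nrow(edges) == 0) {
    return(structure(list(edges = edges, retained = edges, n_boot = n_boot,
                          aggregate_threshold = aggregate_threshold,
                          strength_floor = strength_floor,
                          threshold_on = threshold_on),
                     class = "bootstrap_network"))
  }
  crit <- if (threshold_on == "support") edges$support else edges$strength
  edges$retained <- crit >= aggregate_threshold & edges$strength >= strength_floor
  retained <- edges[edges$retained, , drop = FALSE]
  # acyclicity post-processing: drop weakest arc in any strongly connected cycle
  repeat {
    if (nrow(retained) == 0) break
    g <- igraph::graph_from_data_frame(retained[, c("from", "to")],
                                       directed = TRUE)
    comp <- igraph::components(g, mode = "strong")
    cyc <- which(comp$csize > 1)
    if (length(cyc) == 0) break
    bad_nodes <- names(comp$membership)[comp$membership %in% cyc]
    in_cycle <- retained$from %in% bad_nodes & retained$to %in% bad_nodes
    drop <- which(in_cycle)[which.min(retained$support[in_cycle])]
    retained <- retained[-drop, , drop = FALSE]
  }
  edges$retained <- paste(edges$from, edges$to) %in% paste(retained$from, retained$to)
  structure(list(edges = dplyr::arrange(edges, dplyr::desc(.data$strength)),
                 retained = dplyr::arrange(retained, dplyr::desc(.data$strength)),
                 n_boot = n_boot, aggregate_threshold = aggregate_threshold,
                 strength_floor = strength_floor, threshold_on = threshold_on),
            class = "bootstrap_network")
}

#' @export
print.bootstrap_network <- function(x, ...) {
  cat(sprintf("bootstrap_network: %d arcs observed, %d retained (n_boot = %d)\n",
              nrow(x$edges), nrow(x$retained), x$n_boot))
  invisible(x)
}
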