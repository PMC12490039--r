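# Shared fixtures and independent oracles used across the suite.

# Wide expression tibble from a plain matrix.
expr_tbl <- function(m, genes = rownames(m)) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  tibble::as_tibble(cbind(tibble::tibble(gene = genes), as.data.frame(m)))
}

# Pair of centred unit vectors with an exact sample correlation rho.
exact_cor_pair <- function(n, rho) {
  u1 <- seq_len(n) - mean(seq_len(n))
  u1 <- u1 / sqrt(sum(u1^2))
  raw <- (seq_len(n) %% 3) - mean(seq_len(n) %% 3)
  raw <- raw - sum(raw * u1) * u1
  u2 <- raw / sqrt(sum(raw^2))
  list(x = u1, y = rho * u1 + sqrt(1 - rho^2) * u2)
}

# Exhaustive hypergeometric upper tail by enumeration of all draws.
hyper_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements are the set
  mean(hits >= k)
}

# Unweighted (KS-type) enrichment statistic from explicit ECDF differences.
ks_es_oracle <- function(hits) {
  K <- sum(hits); G <- length(hits)
  d <- cumsum(hits) / K - cumsum(!hits) / (G - K)
  hi <- max(d); lo <- min(d)
  if (hi >= -lo) hi else lo
}

# Step-up Benjamini-Hochberg, written independently of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Wilcoxon AUROC (duplicated from the package on purpose: oracle stays
# independent of the code under test).
auroc_oracle <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# A small module-structured configuration used where full study scale is not
# needed.
small_config <- function(seed = 1, ...) {
  simulation_config(n_genes = 300, module_sizes = c(80, 60, 40),
                    factor_dag = data.frame(from = 1, to = 2, coef = 0.4),
                    n_tfs = 3, n_targets_per_tf = 15, n_decoy_tfs = 7,
                    seed = seed, ...)
}

# Planted 10-node linear SEM with identifiable v-structures.
sem10 <- function(n = 200, seed = 7, coef = 0.7) {
  set.seed(seed)
  p <- 10
  edges <- rbind(c(1, 3), c(2, 3), c(3, 5), c(4, 5), c(5, 7), c(6, 7),
                 c(7, 9), c(8, 9), c(2, 6), c(1, 4), c(9, 10))
  x <- matrix(0, n, p)
  A <- matrix(0, p, p)
  A[edges] <- coef
  for (j in seq_len(p)) x[, j] <- x %*% A[, j] + stats::rnorm(n)
  colnames(x) <- sprintf("Z%02d", seq_len(p))
  list(x = x, edges = edges,
       skeleton = apply(edges, 1, function(e) {
         paste(sort(sprintf("Z%02d", e)), collapse = "-")
       }))
}

skeleton_of <- function(edge_df) {
  if (nrow(edge_df) == 0) return(character(0))
  apply(edge_df[, c("from", "to")], 1, function(e) paste(sort(e), collapse = "-"))
}
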