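test_that("tree-ensemble importances separate true from decoy regulators", {
  wins <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    n <- 60
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    y <- 2 * x1 + stats::rnorm(n, sd = 0.5)
    e <- expr_tbl(rbind(x1, x2, y), genes = c("TF1", "TF2", "y"))
    w <- genie3_weights(e, c("TF1", "TF2"), targets = "y", n_trees = 50, seed = s)
    w["TF1", "y"] > w["TF2", "y"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("per-target importances are normalized and deterministic", {
  bench <- simulate_grn_benchmark(n_tfs = 8, n_targets = 15, n_samples = 50, seed = 2)
  tg <- setdiff(bench$expr$gene, bench$regulators)
  w <- genie3_weights(bench$expr, bench$regulators, targets = tg,
                      n_trees = 100, seed = 9)
  expect_true(all(abs(colSums(w) - 1) < 1e-9))
  w2 <- genie3_weights(bench$expr, bench$regulators, targets = tg,
                       n_trees = 100, seed = 9)
  expect_identical(unclass(w), unclass(w2))

  flat <- bench$expr
  flat[flat$gene == tg[1], -1] <- 1
  expect_warning(genie3_weights(flat, bench$regulators, targets = tg[1:2],
                                n_trees = 50, seed = 1), "zero variance")
})

test_that("edge ranking on a planted benchmark reaches high AUROC", {
  bench <- simulate_grn_benchmark(n_tfs = 10, n_targets = 60,
                                  n_samples = 100, seed = 13)
  tg <- setdiff(bench$expr$gene, bench$regulators)
  pairs <- expand.grid(tf = bench$regulators, target = tg,
                       stringsAsFactors = FALSE)
  lab <- as.integer(paste(pairs$tf, pairs$target) %in%
                      paste(bench$truth_edges$tf, bench$truth_edges$target))
  g3 <- genie3_weights(bench$expr, bench$regulators, targets = tg,
                       n_trees = 100, seed = 3)
  expect_gte(auroc_oracle(g3[cbind(pairs$tf, pairs$target)], lab), 0.8)
  mi <- mi_matrix(bench$expr)
  expect_gte(auroc_oracle(mi[cbind(pairs$tf, pairs$target)], lab), 0.8)
})

test_that("mutual information vanishes for independent data, peaks for copies", {
  set.seed(17)
  ind <- expr_tbl(matrix(stats::runif(6 * 1000), 6, 1000))
  mi <- mi_matrix(ind)
  expect_lt(max(abs(mi[upper.tri(mi)])), 0.05)

  x <- stats::rnorm(200)
  dep <- expr_tbl(rbind(x, x, stats::rnorm(200), stats::rnorm(200)),
                  genes = c("a", "b", "c", "d"))
  mid <- mi_matrix(dep)
  expect_identical(which.max(mid[upper.tri(mid)]), 1L)  # pair (a, b)
  expect_true(max(abs(mid - t(mid))) < 1e-12)

  cst <- expr_tbl(rbind(x, rep(1, 200)), genes = c("a", "b"))
  expect_warning(mic <- mi_matrix(cst), "constant")
  expect_true(all(mic["b", ] == 0))

  expect_error(mi_matrix(expr_tbl(matrix(1:12, 2, 6))), ">= 8 samples")
})

test_that("DPI removes the indirect edge of Gaussian chains", {
  removed <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    n <- 500
    x <- stats::rnorm(n); y <- 0.9 * x + 0.5 * stats::rnorm(n)
    z <- 0.9 * y + 0.5 * stats::rnorm(n)
    mi <- mi_matrix(expr_tbl(rbind(x, y, z), genes = c("x", "y", "z")))
    pruned <- dpi_prune(mi)
    pruned["x", "z"] == 0 && pruned["x", "y"] > 0 && pruned["y", "z"] > 0
  }, logical(1))
  expect_gte(mean(removed), 0.95)
})

test_that("DPI honors tie-breaks, idempotence and never adds edges", {
  # two nodes: no triangle, nothing changes
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(dpi_prune(m2), m2)

  # exact tie for weakest: the lexicographically smallest pair goes
  m3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m3["a", "b"] <- m3["b", "a"] <- 0.2
  m3["a", "c"] <- m3["c", "a"] <- 0.2
  m3["b", "c"] <- m3["c", "b"] <- 0.5
  p3 <- dpi_prune(m3)
  expect_identical(p3["a", "b"], 0)
  expect_identical(p3["a", "c"], 0.2)
  expect_identical(p3["b", "c"], 0.5)

  # fully tied triangle is left intact
  mt <- matrix(0.3, 3, 3, dimnames = dimnames(m3)); diag(mt) <- 0
  expect_identical(dpi_prune(mt), mt)

  set.seed(23)
  r <- matrix(stats::runif(64, 0.01, 1), 8, 8)
  r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(letters[1:8], letters[1:8])
  once <- dpi_prune(r)
  expect_lte(sum(once > 0), sum(r > 0))
  expect_identical(dpi_prune(once), once)
})

test_that("TF node-degree ranking sums weights into the target set", {
  w <- matrix(0, 2, 3, dimnames = list(c("TF1", "TF2"), c("g1", "g2", "g3")))
  w["TF1", c("g1", "g2")] <- c(0.5, 0.4)
  w["TF2", "g1"] <- 0.3
  r <- rank_tfs(w, c("g1", "g2"), top_k = 100)
  expect_identical(r$tf, c("TF1", "TF2"))
  expect_equal(r$node_degree, c(0.9, 0.3))
  expect_identical(nrow(rank_tfs(w, "g1", top_k = 50)), 2L)  # top_k > #TFs

  # ties broken alphabetically; uniform scaling leaves the order unchanged
  w2 <- w; w2["TF2", "g2"] <- 0.6
  r2 <- rank_tfs(w2, c("g1", "g2"))
  expect_identical(r2$tf, c("TF1", "TF2"))
  r3 <- rank_tfs(w2 * 7, c("g1", "g2"))
  expect_identical(r3$tf, r2$tf)
  expect_equal(r3$node_degree, r2$node_degree * 7)

  expect_warning(r0 <- rank_tfs(w, "g3"), "no regulator")
  expect_true(all(r0$node_degree == 0))
  expect_error(rank_tfs(w, character(0)), "empty")
})

test_that("consensus intersects rankings and applies the motif NES floor", {
  ra <- tibble::tibble(rank = 1:3, tf = c("T1", "T2", "T3"),
                       node_degree = 3:1, method = "genie3")
  rb <- ra; rb$method <- "aracne"
  motif <- tibble::tibble(tf = c("T1", "T2", "T3"),
                          target = c("g1", "g1", "g1"),
                          nes = c(5, 4, 3.2))
  full <- consensus_tfs(ra, rb, motif, module_genes = "g1")
  expect_true(all(full$consensus))
  expect_setequal(full$tf, c("T1", "T2", "T3"))

  rb2 <- tibble::tibble(rank = 1:3, tf = c("T4", "T5", "T6"),
                        node_degree = 3:1, method = "aracne")
  expect_identical(nrow(consensus_tfs(ra, rb2, motif)), 0L)

  # sub-floor NES fails stage 2 but stays in stage 1 with provenance
  motif_low <- motif; motif_low$nes <- c(5, 2, 3.2)
  mixed <- consensus_tfs(ra, rb, motif_low, module_genes = "g1")
  expect_setequal(mixed$tf[mixed$consensus], c("T1", "T3"))
  expect_identical(mixed$motif_targets[mixed$tf == "T2"], 0L)
  expect_warning(consensus_tfs(ra, rb, motif[0, ]), "empty motif")
})

test_that("planted drivers survive the full consensus with exact provenance", {
  sim <- simulate_dataset(small_config(seed = 41))
  truth <- sim$truth
  mod1 <- truth$membership$gene[truth$membership$module == 1]
  g3 <- genie3_weights(sim$expr, truth$regulators, targets = mod1,
                       n_trees = 100, seed = 1)
  mi <- mi_matrix(sim$expr[sim$expr$gene %in% c(truth$regulators, mod1), ])
  ar <- dpi_prune(mi, regulators = truth$regulators)
  ra <- rank_tfs(g3, mod1, top_k = 6)
  rb <- rank_tfs(ar, mod1, top_k = 6)
  expect_true(all(truth$tfs %in% ra$tf))
  expect_true(all(truth$tfs %in% rb$tf))
  motif <- simulate_motif_table(truth, n_detected = 2, seed = 5)
  cons <- consensus_tfs(ra, rb, motif, module_genes = mod1)
  detected <- intersect(unique(motif$tf[motif$nes >= 3]), truth$tfs)
  expect_setequal(cons$tf[cons$consensus], detected)

  reg <- regulon_subnetwork(g3, cons, mod1, motif)
  expect_true(all(reg$tf %in% detected))
  truth_cov <- unique(truth$tf_edges$target[truth$tf_edges$tf %in% detected])
  expect_equal(attr(reg, "coverage"),
               length(intersect(truth_cov, mod1)) / length(mod1))
})

test_that("regulon subnetwork reports coverage and skips motif-free TFs", {
  w <- matrix(0.5, 2, 4, dimnames = list(c("T1", "T2"), paste0("g", 1:4)))
  cons <- tibble::tibble(tf = c("T1", "T2"), rank_a = 1:2, rank_b = 1:2,
                         best_nes = c(5, 4), motif_targets = c(2L, 1L),
                         consensus = TRUE)
  motif <- tibble::tibble(tf = c("T1", "T1", "T2"),
                          target = c("g1", "g2", "g3"), nes = 5)
  reg <- regulon_subnetwork(w, cons, paste0("g", 1:4), motif)
  expect_equal(attr(reg, "coverage"), 0.75)
  expect_identical(nrow(reg), 3L)

  motif_t1 <- motif[motif$tf == "T1", ]
  reg2 <- regulon_subnetwork(w, cons, paste0("g", 1:4), motif_t1)
  expect_false("T2" %in% reg2$tf)
  expect_equal(attr(reg2, "coverage"), 0.5)
})
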