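test_that("hypergeometric overrepresentation matches exhaustive enumeration", {
  u10 <- sprintf("u%02d", 1:10)
  res <- gsoa(u10[1:5], list(S = u10[1:5]), u10)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252

  u6 <- sprintf("u%02d", 1:6)
  # module = {u1,u2,u6}, set = {u1,u2,u3}: overlap 2 of 3
  res2 <- gsoa(c("u01", "u02", "u06"), list(S = c("u01", "u02", "u03")), u6)
  expect_equal(res2$p_value, 0.5, tolerance = 1e-12)

  res3 <- gsoa(u6[1:3], list(EMPTY = character(0)), u6)
  expect_equal(res3$p_value, 1)

  # random small universes against the draw-enumeration oracle
  set.seed(77)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    univ <- sprintf("x%02d", 1:N)
    mod <- sample(univ, n)
    p <- gsoa(mod, list(S = univ[1:K]), univ)$p_value
    k <- sum(mod %in% univ[1:K])
    expect_equal(p, hyper_enum(k, K, N, n), tolerance = 1e-12)
  }

  expect_error(gsoa(character(0), list(S = u6), u6), "empty module")
  expect_error(gsoa(u6[1], list(S = u6), character(0)), "empty universe")
})

test_that("cluster enrichment score is the |log10| of the best adjusted p", {
  expect_equal(ces(tibble::tibble(adj_p = c(0.001, 0.5, 1))), 3)
  expect_equal(ces(tibble::tibble(adj_p = 1)), 0)
  expect_equal(ces(tibble::tibble(adj_p = 0.05)), -log10(0.05), tolerance = 1e-9)
  expect_warning(capped <- ces(tibble::tibble(adj_p = 0)), "capped")
  expect_true(is.finite(capped) && capped > 300)
})

test_that("GSEA running sum matches hand traces and the KS oracle", {
  ranked4 <- tibble::tibble(gene = paste0("g", 1:4), log2fc = c(2, 1, -1, -2))
  # weight 0, set = top 2: running sum peaks at +1
  r0 <- gsea(ranked4, c("g1", "g2"), weight_p = 0, n_perm = 100, seed = 1)
  expect_equal(r0$es, 1, tolerance = 1e-12)
  # weight 1, set = {g1, g4}: hand trace (0.5, 0, -0.5, 0) -> ES 0.5
  r1 <- gsea(ranked4, c("g1", "g4"), weight_p = 1, n_perm = 100, seed = 1)
  expect_equal(r1$es, 0.5, tolerance = 1e-12)

  # weight 0 equals the two-sample ECDF statistic on random rankings
  set.seed(21)
  for (i in 1:20) {
    g <- sample(8:20, 1)
    ranked <- tibble::tibble(gene = paste0("g", 1:g),
                             log2fc = sort(stats::rnorm(g), decreasing = TRUE))
    hits <- ranked$gene %in% sample(ranked$gene, sample(2:(g - 2), 1))
    out <- gsea(ranked, ranked$gene[hits], weight_p = 0, n_perm = 100, seed = i)
    expect_equal(out$es, ks_es_oracle(hits), tolerance = 1e-12)
  }

  expect_error(gsea(ranked4, c("zz"), n_perm = 100), "disjoint")
})

test_that("GSEA permutation p matches exhaustive enumeration on 8 genes", {
  ranked <- tibble::tibble(gene = paste0("g", 1:8),
                           log2fc = c(3, 2.5, 2, 1, -1, -2, -2.5, -3))
  set <- c("g1", "g2", "g3")
  out <- gsea(ranked, set, weight_p = 1, n_perm = 2000, seed = 4)
  # exact null: every placement of 3 hits among 8 positions
  combos <- utils::combn(8, 3)
  null_es <- apply(combos, 2, function(idx) {
    hits <- seq_len(8) %in% idx
    plaquenet:::es_from_running(
      plaquenet:::running_sum(ranked$log2fc, hits, weight_p = 1))
  })
  same <- null_es[sign(null_es) == sign(out$es)]
  p_exact <- mean(abs(same) >= abs(out$es))
  ci <- stats::binom.test(round(out$p_value * 2000), 2000)$conf.int
  expect_true(p_exact >= ci[1] - 0.02 && p_exact <= ci[2] + 0.02)
})

test_that("weighted ES agrees with the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:5) {
    g <- 40
    stats_vec <- sort(stats::rnorm(g), decreasing = TRUE)
    names(stats_vec) <- paste0("g", 1:g)
    sel <- sort(sample(g, 8))
    ranked <- tibble::tibble(gene = names(stats_vec), log2fc = stats_vec)
    ours <- gsea(ranked, names(stats_vec)[sel], weight_p = 1,
                 n_perm = 100, seed = i)$es
    theirs <- fgsea::calcGseaStat(stats_vec, selectedStats = sel,
                                  gseaParam = 1, scoreType = "std")
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("ES stays within [-1, 1] over random rankings and sets", {
  set.seed(55)
  for (i in 1:100) {
    g <- sample(5:40, 1)
    r <- stats::rnorm(g)
    hits <- logical(g)
    hits[sample(g, sample(1:(g - 1), 1))] <- TRUE
    es <- plaquenet:::es_from_running(
      plaquenet:::running_sum(sort(r, decreasing = TRUE), hits,
                              weight_p = sample(c(0, 1, 2), 1)))
    expect_true(es >= -1 - 1e-12 && es <= 1 + 1e-12)
  }
})

test_that("partition overlap reports Jaccard and enumerated hypergeometric p", {
  pa <- tibble::tibble(gene = c("A", "B", "C"), module = 1L)
  pb <- tibble::tibble(gene = c("B", "C", "D"), module = 1L)
  ov <- partition_overlap(pa, pb)
  expect_equal(ov$jaccard, 0.5)

  ident <- partition_overlap(pa, pa)
  expect_equal(ident$jaccard, 1)

  u10 <- sprintf("x%02d", 1:10)
  pc <- tibble::tibble(gene = u10, module = rep(c(1L, 2L), each = 5))
  pd <- tibble::tibble(gene = u10, module = rep(c(2L, 1L), each = 5))
  od <- partition_overlap(pc, pd)
  d11 <- od[od$module_a == 1 & od$module_b == 1, ]
  expect_equal(d11$jaccard, 0)
  expect_equal(d11$p_value, hyper_enum(0, 5, 10, 5), tolerance = 1e-12)
  expect_true(all(od$adj_p >= od$p_value - 1e-15))
})

test_that("Lin similarity with best-match average matches the hand oracle", {
  ont <- list(edges = tibble::tibble(child = c("A", "B", "C"),
                                     parent = c("ROOT", "ROOT", "A")),
              counts = c(ROOT = 100, A = 50, B = 20, C = 10))
  expect_equal(semantic_similarity("C", "C", ont), 1)
  expect_equal(semantic_similarity("C", "B", ont), 0)   # root-only ancestor
  ic <- -log(c(A = 0.5, C = 0.1))
  sim_ca <- 2 * ic["A"] / (ic["C"] + ic["A"])
  bma <- (sim_ca + (sim_ca + 0) / 2) / 2
  expect_equal(semantic_similarity("C", c("A", "B"), ont), unname(bma),
               tolerance = 1e-12)
  # symmetry
  expect_equal(semantic_similarity(c("A", "B"), "C", ont),
               semantic_similarity("C", c("A", "B"), ont))
  expect_error(semantic_similarity("Z", "C", ont), "absent")
  # Resnik variant is also bounded and symmetric
  expect_equal(semantic_similarity("C", "C", ont, measure = "resnik"),
               1, tolerance = 1e-12)
})

test_that("signature scores recover uniform shifts and planted modules", {
  set.seed(61)
  # baselines spread wide so expression-matched bins mix signature genes with
  # unshifted neighbours; a shift applied only in half the samples then shows
  # up as a between-group score contrast of delta (a shift uniform across ALL
  # samples is absorbed by the matched controls by construction)
  m <- matrix(stats::rnorm(200 * 10, sd = 0.2), 200, 10) +
    stats::runif(200, 0, 20)
  rownames(m) <- sprintf("g%03d", 1:200)
  sig <- sample(rownames(m), 30)
  shifted_samples <- 6:10
  m[sig, shifted_samples] <- m[sig, shifted_samples] + 2
  sc <- suppressWarnings(signature_score(expr_tbl(m), sig, seed = 1))
  contrast <- mean(sc$score[shifted_samples]) - mean(sc$score[-shifted_samples])
  expect_equal(contrast, 2, tolerance = 0.3)

  all_sc <- suppressWarnings(signature_score(expr_tbl(m), rownames(m), seed = 1))
  expect_true(all(abs(all_sc$score) < 0.2))

  # planted shifted module scores higher in condition B across seeds
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_dataset(small_config(seed = 500 + s))
    mod1 <- sim$truth$membership$gene[sim$truth$membership$module == 1]
    sc <- suppressWarnings(signature_score(sim$expr, mod1, seed = s))
    ab <- dplyr::left_join(sc, sim$conditions, by = "sample")
    stats::t.test(score ~ condition, data = ab, alternative = "less")$p.value
  }, numeric(1))
  expect_gte(mean(pvals < 0.01), 0.9)
})
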