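test_that("soft-thresholded adjacency follows |cor|^beta", {
  pair <- exact_cor_pair(20, 0.5)
  e <- expr_tbl(rbind(pair$x, pair$y), genes = c("a", "b"))
  a <- pearson_adjacency(e, power = 6)
  expect_equal(a["a", "b"], 0.5^6, tolerance = 1e-12)   # 0.015625

  neg <- expr_tbl(rbind(pair$x, -pair$y), genes = c("a", "b"))
  expect_equal(pearson_adjacency(neg, power = 6)["a", "b"], 0.5^6,
               tolerance = 1e-12)                        # unsigned symmetry

  dup <- expr_tbl(rbind(pair$x, 2 * pair$x + 1), genes = c("a", "b"))
  expect_equal(pearson_adjacency(dup, power = 3)["a", "b"], 1, tolerance = 1e-12)

  withzero <- expr_tbl(rbind(pair$x, pair$y, rep(1, 20)),
                       genes = c("a", "b", "const"))
  expect_warning(az <- pearson_adjacency(withzero, power = 2), "zero-variance")
  expect_identical(rownames(az), c("a", "b"))
})

test_that("scale-free index separates power-law from homogeneous networks", {
  set.seed(5)
  # adjacency engineered so row sums follow a discrete power law
  k <- (1 - stats::runif(400))^(-1 / 1.5)
  a <- outer(k, k) / sum(k)
  diag(a) <- 0
  expect_gte(scale_free_fit(a), 0.95)

  er <- matrix(stats::runif(300^2), 300)
  er <- (er + t(er)) / 2
  diag(er) <- 0
  expect_lt(scale_free_fit(er), 0.5)

  expect_error(scale_free_fit(matrix(0.5, 2, 2)), ">= 10 genes")
  expect_warning(z <- scale_free_fit(matrix(0.3, 12, 12) - diag(0.3, 12)),
                 "constant")
  expect_identical(z, 0)
})

test_that("soft-power selection honours the threshold and its own scan", {
  sim <- simulate_dataset(small_config(seed = 31))
  p0 <- suppressWarnings(pick_soft_power(sim$expr, candidate_powers = 1:6,
                                         fit_threshold = -1))
  expect_identical(as.numeric(p0), 1)   # every power qualifies: smallest wins

  expect_warning(
    pmax_ <- pick_soft_power(sim$expr, candidate_powers = 1:6, fit_threshold = 0.999),
    "falling back")
  scan <- attr(pmax_, "scan")
  expect_identical(as.numeric(pmax_), as.numeric(scan$power[which.max(scan$fit_index)]))

  # the returned power is always the first scan entry meeting the threshold,
  # else the argmax
  thr <- 0.5
  sel <- suppressWarnings(pick_soft_power(sim$expr, 1:6, fit_threshold = thr))
  scan2 <- attr(sel, "scan")
  qual <- scan2$power[scan2$fit_index >= thr]
  expected <- if (length(qual)) min(qual) else scan2$power[which.max(scan2$fit_index)]
  expect_identical(as.numeric(sel), as.numeric(expected))
})

test_that("TOM matches hand-computed values on three-gene graphs", {
  tri <- matrix(1, 3, 3) - diag(1, 3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  tt <- tom_similarity(tri)
  expect_true(all(abs(tt - 1) < 1e-12))          # identical neighbourhoods

  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- 1
  path["b", "c"] <- path["c", "b"] <- 1
  tp <- tom_similarity(path)
  expect_equal(tp["a", "c"], 0.5, tolerance = 1e-12)  # (1+0)/(min(1,1)+1-0)
  expect_equal(tp["a", "b"], (0 + 1) / (1 + 1 - 1), tolerance = 1e-12)

  empty <- matrix(0, 3, 3)
  te <- tom_similarity(empty)
  expect_true(all(te[upper.tri(te)] == 0))
  expect_true(all(diag(te) == 1))
})

test_that("adjacency and TOM stay symmetric in [0,1]; duplicated nodes reach TOM 1", {
  set.seed(42)
  for (i in 1:100) {
    g <- sample(5:15, 1)
    a <- matrix(stats::runif(g * g), g)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tt <- tom_similarity(a)
    expect_true(max(abs(tt - t(tt))) < 1e-12)
    expect_true(all(tt >= -1e-12 & tt <= 1 + 1e-12))
  }
  # duplicated nodes in a random binary graph: identical neighbourhoods plus
  # a unit mutual edge give full topological overlap
  set.seed(43)
  for (rep in 1:10) {
    g <- sample(5:9, 1)
    base <- matrix(stats::rbinom(g * g, 1, 0.5), g)
    base <- 1 * ((base + t(base)) > 0)
    diag(base) <- 0
    a <- rbind(cbind(base, 0), 0)
    a[g + 1, seq_len(g - 1) + 1] <- a[seq_len(g - 1) + 1, g + 1] <- base[1, -1]
    a[1, g + 1] <- a[g + 1, 1] <- 1
    dimnames(a) <- list(letters[seq_len(g + 1)], letters[seq_len(g + 1)])
    expect_equal(unname(tom_similarity(a)[1, g + 1]), 1, tolerance = 1e-12)
  }
})

test_that("planted modules are recovered from TOM clustering", {
  # noise-free orthogonal modules: exact recovery
  set.seed(9)
  z1 <- stats::rnorm(40); z2 <- stats::rnorm(40)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))       # exactly uncorrelated
  m <- rbind(t(sapply(stats::runif(40, 0.5, 1), function(l) l * z1)),
             t(sapply(stats::runif(40, 0.5, 1), function(l) l * z2)))
  tom <- tom_similarity(pearson_adjacency(expr_tbl(m), power = 6))
  part <- cluster_modules(tom, min_module_size = 10)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(part$assignment$module, truth), 1)

  # an all-noise matrix yields mostly unassigned genes
  unassigned <- vapply(1:20, function(s) {
    set.seed(300 + s)
    noise <- expr_tbl(matrix(stats::rnorm(150 * 30), 150, 30))
    tomn <- tom_similarity(pearson_adjacency(noise, power = 6))
    pn <- cluster_modules(tomn, min_module_size = 30)
    mean(pn$assignment$module == 0)
  }, numeric(1))
  expect_gte(mean(unassigned >= 0.9), 0.9)
})

test_that("eigengenes summarize modules and respect the sign convention", {
  set.seed(13)
  z <- stats::rnorm(30)
  lam <- stats::runif(6, 0.5, 1)
  perfect <- expr_tbl(outer(lam, z))
  part <- plaquenet:::new_module_partition(
    tibble::tibble(gene = perfect$gene, module = 1L))
  pe <- module_eigengenes(perfect, part)
  me <- pe$eigengenes[1, ]
  expect_equal(abs(stats::cor(me, z)), 1, tolerance = 1e-12)
  expect_equal(pe$variance_explained$variance_explained, 1, tolerance = 1e-12)
  m <- as.matrix(perfect[, -1])
  expect_gte(stats::cor(me, rowMeans(scale(t(m)))), 0)

  const <- perfect
  const[3, -1] <- 1
  expect_error(module_eigengenes(const, part), "constant genes")
})

test_that("synthetic eigengenes track the planted factors", {
  sim <- simulate_dataset(small_config(seed = 17))
  tom <- tom_similarity(pearson_adjacency(sim$expr, power = 6))
  part <- merge_modules(sim$expr, cluster_modules(tom))
  me <- part$eigengenes
  z <- sim$truth$factor_values
  best <- vapply(seq_len(nrow(z)), function(j) {
    max(abs(stats::cor(z[j, ], t(me))))
  }, numeric(1))
  expect_true(all(best >= 0.9))
  # sign convention holds for every module
  m <- plaquenet:::as_expr_matrix(sim$expr)
  for (i in seq_len(nrow(me))) {
    genes <- part$assignment$gene[part$assignment$module == i]
    expect_gte(stats::cor(me[i, ], rowMeans(scale(t(m[genes, ])))), 0)
  }
})

test_that("modules merge on eigengene dissimilarity below the threshold", {
  build <- function(rho) {
    pair <- exact_cor_pair(24, rho)
    m <- rbind(outer(stats::runif(10, 0.5, 1), pair$x),
               outer(stats::runif(10, 0.5, 1), pair$y))
    e <- expr_tbl(m)
    part <- plaquenet:::new_module_partition(
      tibble::tibble(gene = e$gene, module = rep(1:2, each = 10)))
    merge_modules(e, part, me_diss_threshold = 0.25)
  }
  merged <- build(0.8)     # dissimilarity 0.2 < 0.25
  expect_identical(length(unique(merged$assignment$module)), 1L)
  kept <- build(0.7)       # dissimilarity 0.3: fixed point
  expect_identical(sort(unique(kept$assignment$module)), 1:2)

  # three mutually similar modules collapse regardless of label order
  pair <- exact_cor_pair(24, 0.9)
  m3 <- rbind(outer(rep(1, 8), pair$x), outer(rep(1, 8), pair$y),
              outer(rep(1, 8), 0.5 * (pair$x + pair$y)))
  e3 <- expr_tbl(m3)
  for (labels in list(rep(1:3, each = 8), rep(c(2, 3, 1), each = 8))) {
    part <- plaquenet:::new_module_partition(
      tibble::tibble(gene = e3$gene, module = as.integer(labels)))
    out <- merge_modules(e3, part, me_diss_threshold = 0.25)
    expect_identical(length(unique(out$assignment$module)), 1L)
  }
})

test_that("module proximity is reference-normalized and scale-invariant", {
  # constant adjacency: everything sits at the reference level
  g <- 30
  const <- matrix(0.2, g, g) - diag(0.2, g)
  dimnames(const) <- list(sprintf("g%03d", 1:g), sprintf("g%03d", 1:g))
  part <- plaquenet:::new_module_partition(
    tibble::tibble(gene = rownames(const), module = rep(1:3, each = 10)))
  prox <- module_proximity(const, part, 1)
  expect_true(all(abs(prox$relative_proximity - 1) < 1e-12))

  # block adjacency oracle: focal-m2 pairs at 0.4, all other cross pairs 0.1
  blocks <- matrix(0.1, g, g)
  blocks[1:10, 11:20] <- blocks[11:20, 1:10] <- 0.4
  diag(blocks) <- 0
  dimnames(blocks) <- dimnames(const)
  p2 <- module_proximity(blocks, part, 1)
  ref <- (100 * 0.4 + 100 * 0.1) / 200
  expect_equal(p2$relative_proximity[p2$module == "2"], 0.4 / ref)
  expect_equal(p2$relative_proximity[p2$module == "3"], 0.1 / ref)
  expect_equal(p2$relative_proximity[p2$module == "reference"], 1)

  # uniform rescaling leaves the relative values unchanged
  p3 <- module_proximity(blocks * 2.5, part, 1)
  expect_equal(p3$relative_proximity, p2$relative_proximity, tolerance = 1e-12)

  solo <- plaquenet:::new_module_partition(
    tibble::tibble(gene = rownames(const), module = rep(1L, g)))
  expect_error(module_proximity(const, solo, 1), "only module")
})
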