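#' Simulation configuration for the synthetic plaque-like cohort
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The generator emulates the statistical structure the pipeline assumes:
#' genes loading on latent module factors, a linear-Gaussian DAG among the
#' factors, condition-specific factor mean shifts, TF-to-target regulatory
#' effects inside one designated module, and pure-noise background genes.
#'
#' Defaults mirror the study design at desk scale: 1000 genes, five modules
#' of 250/150/100/70/50 genes (the 250-gene first module plays the role of
#' the T cell-specific cluster and carries the TF effects), and 16 + 27
#' samples in conditions A (stable) and B (unstable).
#'
#' @param n_genes total number of genes, background included.
#' @param module_sizes integer vector of module sizes (each >= 3); remaining
#'   genes are unassigned background.
#' @param n_samples_per_condition length-2 integer vector `c(A, B)` (a scalar
#'   is recycled to both conditions).
#' @param factor_dag data frame `(from, to, coef)` of directed edges among
#'   module indices; must be acyclic.
#' @param condition_shift named numeric vector mapping module index to the
#'   additive factor shift delta applied in condition B (log-expression units).
#' @param loading_range length-2 numeric, uniform range for gene loadings.
#' @param gene_noise_sd,factor_noise_sd,background_sd noise standard deviations
#'   for gene-level residuals, factor innovations, and background genes.
#' @param baseline_range length-2 numeric, uniform range of per-gene baseline
#'   mean expression (log scale); use `c(0, 0)` for a centred matrix.
#' @param n_tfs number of true transcription-factor drivers planted inside
#'   module 1.
#' @param n_targets_per_tf targets regulated by each TF (module-1 genes).
#' @param tf_effect_sd standard deviation of normal TF-to-target weights.
#' @param n_decoy_tfs background genes added to the candidate-regulator list.
#' @param random_sign if `TRUE`, loadings receive random signs (off by
#'   default: the downstream co-expression network is unsigned).
#' @param seed integer RNG seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              module_sizes = c(250, 150, 100, 70, 50),
                              n_samples_per_condition = c(16, 27),
                              factor_dag = data.frame(
                                from = c(1, 1, 2, 3),
                                to = c(2, 3, 4, 5),
                                coef = 0.4),
                              condition_shift = c(`1` = 2),
                              loading_range = c(0.6, 1),
                              gene_noise_sd = 0.3,
                              factor_noise_sd = 1,
                              background_sd = 1,
                              baseline_range = c(6, 10),
                              n_tfs = 5,
                              n_targets_per_tf = 20,
                              tf_effect_sd = 0.8,
                              n_decoy_tfs = 15,
                              random_sign = FALSE,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              n_samples_per_condition = rep(as.integer(n_samples_per_condition),
                                            length.out = 2),
              factor_dag = as.data.frame(factor_dag),
              condition_shift = condition_shift,
              loading_range = as.numeric(loading_range),
              gene_noise_sd = gene_noise_sd,
              factor_noise_sd = factor_noise_sd,
              background_sd = background_sd,
              baseline_range = as.numeric(baseline_range),
              n_tfs = as.integer(n_tfs),
              n_targets_per_tf = as.integer(n_targets_per_tf),
              tf_effect_sd = tf_effect_sd,
              n_decoy_tfs = as.integer(n_decoy_tfs),
              random_sign = isTRUE(random_sign),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (any(cfg$module_sizes < 3)) {
    abort("configuration error: every module must have >= 3 genes",
          class = "plaquenet_config_error")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort("configuration error: module_sizes sum above n_genes",
          class = "plaquenet_config_error")
  }
  if (cfg$loading_range[1] > cfg$loading_range[2]) {
    abort("configuration error: loading_range must be increasing",
          class = "plaquenet_config_error")
  }
  if (cfg$gene_noise_sd < 0 || cfg$factor_noise_sd < 0 || cfg$background_sd < 0) {
    abort("configuration error: noise sds must be >= 0",
          class = "plaquenet_config_error")
  }
  m <- length(cfg$module_sizes)
  dag <- cfg$factor_dag
  if (nrow(dag) > 0) {
    if (any(dag$from < 1 | dag$from > m | dag$to < 1 | dag$to > m)) {
      abort("configuration error: factor_dag references unknown modules",
            class = "plaquenet_config_error")
    }
    if (is.null(topo_order_edges(m, dag))) {
      abort("configuration error: factor_dag is cyclic",
            class = "plaquenet_config_error")
    }
  }
  invisible(cfg)
}

# Kahn topological sort over node indices 1..m; NULL if cyclic.
topo_order_edges <- function(m, edges) {
  indeg <- tabulate(edges$to, m)
  adj <- split(edges$to, factor(edges$from, levels = seq_len(m)))
  order <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  if (length(order) == m) order else NULL
}

#' Simulate an expression cohort with planted module and regulatory structure
#'
#' Draws factor values from the linear-Gaussian structural equation model
#' `z_j = sum_k b_jk z_k + delta_j 1[condition B] + eps_j`, then gene values
#' `x_g = mu_g + lambda_g z_m(g) + N(0, sigma_g^2)` for module genes, adds
#' `sum w x_TF` regulatory terms to planted TF targets, and fills background
#' genes with independent noise. Deterministic under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A list of class `plaquenet_sim` with elements `expr` (wide tibble,
#'   first column `gene`), `conditions` (tibble `sample`, `condition`), and
#'   `truth` (memberships, loadings, factor values, DAG edges, TF edges,
#'   shifted modules, candidate regulators).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  set.seed(config$seed)

  m <- length(config$module_sizes)
  n_a <- config$n_samples_per_condition[1]
  n_b <- config$n_samples_per_condition[2]
  n <- n_a + n_b
  cond <- c(rep("A", n_a), rep("B", n_b))
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))

  # factors in topological order so condition shifts propagate through the DAG
  dag <- config$factor_dag
  ord <- if (nrow(dag) > 0) topo_order_edges(m, dag) else seq_len(m)
  shift <- stats::setNames(rep(0, m), seq_len(m))
  if (length(config$condition_shift) > 0) {
    shift[names(config$condition_shift)] <- config$condition_shift
  }
  z <- matrix(0, nrow = m, ncol = n,
              dimnames = list(paste0("M", seq_len(m)), samples))
  for (j in ord) {
    zj <- stats::rnorm(n, sd = config$factor_noise_sd)
    if (nrow(dag) > 0) {
      for (r in which(dag$to == j)) zj <- zj + dag$coef[r] * z[dag$from[r], ]
    }
    zj <- zj + shift[as.character(j)] * (cond == "B")
    z[j, ] <- zj
  }

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  membership <- integer(config$n_genes)
  membership[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(m), times = config$module_sizes)

  lambda <- stats::runif(config$n_genes, config$loading_range[1], config$loading_range[2])
  if (config$random_sign) lambda <- lambda * sample(c(-1, 1), config$n_genes, replace = TRUE)
  mu <- stats::runif(config$n_genes, config$baseline_range[1], config$baseline_range[2])

  x <- matrix(0, nrow = config$n_genes, ncol = n, dimnames = list(genes, samples))
  for (g in seq_len(config$n_genes)) {
    if (membership[g] > 0) {
      x[g, ] <- mu[g] + lambda[g] * z[membership[g], ] +
        stats::rnorm(n, sd = config$gene_noise_sd)
    } else {
      x[g, ] <- mu[g] + stats::rnorm(n, sd = config$background_sd)
    }
  }

  # TF regulatory effects, confined to module 1
  tf_edges <- tibble(tf = character(0), target = character(0), weight = numeric(0))
  tfs <- character(0)
  mod1 <- genes[membership == 1]
  if (config$n_tfs > 0 && length(mod1) > config$n_tfs) {
    tfs <- sort(sample(mod1, config$n_tfs))
    pool <- setdiff(mod1, tfs)
    for (tf in tfs) {
      targets <- sort(sample(pool, min(config$n_targets_per_tf, length(pool))))
      # activating regulators: half-normal weights keep the planted condition
      # shift coherently signed across the module
      w <- abs(stats::rnorm(length(targets), sd = config$tf_effect_sd))
      x[targets, ] <- x[targets, ] + outer(w, x[tf, ])
      tf_edges <- dplyr::bind_rows(tf_edges,
                                   tibble(tf = tf, target = targets, weight = w))
    }
  }
  decoys <- character(0)
  bg <- genes[membership == 0]
  if (config$n_decoy_tfs > 0 && length(bg) >= config$n_decoy_tfs) {
    decoys <- sort(sample(bg, config$n_decoy_tfs))
  }

  truth <- list(
    membership = tibble(gene = genes, module = membership),
    loadings = tibble(gene = genes, module = membership, loading = lambda),
    factor_values = z,
    dag_edges = tibble::as_tibble(dag),
    tf_edges = tf_edges,
    tfs = tfs,
    regulators = sort(c(tfs, decoys)),
    shifted_modules = sort(unique(as.integer(
      names(config$condition_shift)[config$condition_shift != 0])))
  )
  structure(list(expr = as_expr_tibble(x),
                 conditions = tibble(sample = samples, condition = cond),
                 truth = truth,
                 config = config),
            class = "plaquenet_sim")
}

#' Simulate module-aligned gene sets and a toy ontology
#'
#' Produces one "matched" set per planted module sharing `overlap_frac` of the
#' module's genes (topped up with background genes to the module's size),
#' `n_decoys` random sets, and a rooted term DAG over the sets with cumulative
#' annotation counts enabling information-content computation.
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param overlap_frac fraction of each module's genes shared by its matched
#'   set, in (0, 1].
#' @param n_decoys number of random decoy sets.
#' @param seed integer RNG seed.
#' @return A list of class `geneset_collection` with `sets` (named list of
#'   gene vectors) and `ontology` (list with `edges` child/parent tibble,
#'   `term_genes`, and cumulative `counts`).
#' @export
simulate_genesets <- function(truth, overlap_frac = 0.8, n_decoys = 20, seed = 1) {
  if (overlap_frac <= 0 || overlap_frac > 1) {
    abort("configuration error: overlap_frac must be in (0, 1]",
          class = "plaquenet_config_error")
  }
  set.seed(seed)
  memb <- truth$membership
  mods <- sort(unique(memb$module[memb$module > 0]))
  universe <- memb$gene
  bg <- memb$gene[memb$module == 0]

  sets <- list()
  for (mm in mods) {
    mg <- memb$gene[memb$module == mm]
    k <- round(overlap_frac * length(mg))
    if (k < 1) {
      abort("configuration error: overlap_frac * module size below 1",
            class = "plaquenet_config_error")
    }
    core <- if (k == length(mg)) mg else sort(sample(mg, k))
    filler <- if (k < length(mg)) sort(sample(setdiff(bg, core), length(mg) - k)) else character(0)
    sets[[paste0("MATCHED_", mm)]] <- c(core, filler)
  }
  med <- max(10L, as.integer(stats::median(lengths(sets))))
  for (d in seq_len(n_decoys)) {
    sz <- sample(10:med, 1)
    sets[[sprintf("DECOY_%02d", d)]] <- sort(sample(universe, sz))
  }

  # rooted DAG: ROOT -> 3 branches -> leaf terms (each leaf under >= 1 branch)
  branches <- paste0("BRANCH_", 1:3)
  edges <- tibble(child = branches, parent = "ROOT")
  term_genes <- sets
  for (nm in names(sets)) {
    par <- sample(branches, sample(1:2, 1))
    edges <- dplyr::bind_rows(edges, tibble(child = nm, parent = par))
  }
  for (b in branches) {
    kids <- edges$child[edges$parent == b]
    term_genes[[b]] <- sort(unique(unlist(sets[kids])))
  }
  term_genes[["ROOT"]] <- sort(unique(unlist(sets)))
  counts <- lengths(term_genes)

  structure(list(sets = sets,
                 ontology = list(edges = edges, term_genes = term_genes,
                                 counts = counts)),
            class = "geneset_collection")
}

#' Simulate a drug-signature library with planted reversers and mimickers
#'
#' Emulates a connectivity-map style library of per-drug full gene rankings:
#' reverser profiles place the query's up genes at the bottom and down genes
#' at the top (signature reversal), mimickers the opposite, neutrals are
#' uniform permutations. `noise_swaps` random transpositions perturb each
#' non-neutral profile.
#'
#' @param query_up,query_down disjoint character vectors of query genes.
#' @param universe gene universe ranked by every profile (superset of the
#'   query).
#' @param n_per_class profiles per class (reverser / mimicker / neutral uses
#'   `4 * n_per_class` neutrals by default to dominate the library).
#' @param n_neutral number of neutral profiles.
#' @param noise_swaps number of random transpositions per non-neutral profile.
#' @param seed integer RNG seed.
#' @return List with `library` (long tibble `drug`, `gene`, `score`) and
#'   `classes` (tibble `drug`, `class`).
#' @export
simulate_drug_profiles <- function(query_up, query_down, universe,
                                   n_per_class = 10, n_neutral = 4 * n_per_class,
                                   noise_swaps = 0, seed = 1) {
  if (length(intersect(query_up, query_down)) > 0) {
    abort("input error: query_up and query_down overlap",
          class = "plaquenet_input_error")
  }
  if (noise_swaps < 0) abort("noise_swaps must be >= 0")
  stopifnot(all(c(query_up, query_down) %in% universe))
  set.seed(seed)
  g <- length(universe)
  scores <- stats::qnorm(1 - (seq_len(g) - 0.5) / g)  # descending by rank
  rest <- setdiff(universe, c(query_up, query_down))

  one_profile <- function(class) {
    ord <- switch(class,
      reverser = c(sample(query_down), sample(rest), sample(query_up)),
      mimicker = c(sample(query_up), sample(rest), sample(query_down)),
      neutral = sample(universe))
    if (class != "neutral" && noise_swaps > 0) {
      for (s in seq_len(noise_swaps)) {
        ij <- sample(g, 2)
        ord[ij] <- ord[rev(ij)]
      }
    }
    tibble(gene = ord, score = scores)
  }

  classes <- tibble(
    drug = c(sprintf("REV%02d", seq_len(n_per_class)),
             sprintf("MIM%02d", seq_len(n_per_class)),
             sprintf("NEU%03d", seq_len(n_neutral))),
    class = rep(c("reverser", "mimicker", "neutral"),
                c(n_per_class, n_per_class, n_neutral)))
  lib <- purrr::map2_dfr(classes$drug, classes$class,
                         function(d, cl) dplyr::mutate(one_profile(cl), drug = d, .before = 1))
  list(library = lib, classes = classes)
}

#' Simulate a motif-support table for planted TF drivers
#'
#' Stands in for upstream motif-scanning output: true regulatory edges of a
#' chosen subset of the planted TFs receive normalized enrichment scores above
#' the conventional floor, remaining candidate regulators receive sub-floor
#' decoy rows.
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param n_detected number of true TFs covered by the motif table.
#' @param nes_range NES range for detected TF-target rows.
#' @param decoy_nes_range NES range for non-driver decoy rows.
#' @param seed integer RNG seed.
#' @return Tibble `(tf, target, nes)`.
#' @export
simulate_motif_table <- function(truth, n_detected = 3, nes_range = c(3.5, 6),
                                 decoy_nes_range = c(0.5, 2.5), seed = 1) {
  set.seed(seed)
  detected <- sort(sample(truth$tfs, min(n_detected, length(truth$tfs))))
  rows <- dplyr::filter(truth$tf_edges, .data$tf %in% detected)
  out <- tibble(tf = rows$tf, target = rows$target,
                nes = stats::runif(nrow(rows), nes_range[1], nes_range[2]))
  others <- setdiff(truth$regulators, detected)
  mod_genes <- truth$membership$gene[truth$membership$module == 1]
  if (length(others) > 0) {
    decoy <- tibble(tf = others,
                    target = sample(mod_genes, length(others), replace = TRUE),
                    nes = stats::runif(length(others),
                                       decoy_nes_range[1], decoy_nes_range[2]))
    out <- dplyr::bind_rows(out, decoy)
  }
  dplyr::arrange(out, .data$tf, .data$target)
}

#' Simulate a planted regulator-target benchmark without shared factors
#'
#' Generates independent standard-normal regulator profiles and targets that
#' are linear combinations of one to `max_parents` regulators plus noise: the
#' canonical benchmark for ranking regulatory edges, free of module-level
#' confounding.
#'
#' @param n_tfs,n_targets,n_samples problem size.
#' @param max_parents maximum regulators per target.
#' @param coef_range absolute coefficient range (signs random).
#' @param noise_sd target residual standard deviation.
#' @param seed integer RNG seed.
#' @return List with `expr` (wide tibble of TFs and targets), `regulators`,
#'   and `truth_edges` (tibble `tf`, `target`).
#' @export
simulate_grn_benchmark <- function(n_tfs = 20, n_targets = 200, n_samples = 100,
                                   max_parents = 3, coef_range = c(0.6, 1.1),
                                   noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  tg_names <- sprintf("T%03d", seq_len(n_targets))
  tf_x <- matrix(stats::rnorm(n_tfs * n_samples), nrow = n_tfs,
                 dimnames = list(tf_names, sprintf("S%03d", seq_len(n_samples))))
  edges <- list()
  tg_x <- matrix(0, nrow = n_targets, ncol = n_samples,
                 dimnames = list(tg_names, colnames(tf_x)))
  for (i in seq_len(n_targets)) {
    k <- sample(max_parents, 1)
    pa <- sample(tf_names, k)
    w <- stats::runif(k, coef_range[1], coef_range[2]) * sample(c(-1, 1), k, replace = TRUE)
    tg_x[i, ] <- drop(w %*% tf_x[pa, , drop = FALSE]) + stats::rnorm(n_samples, sd = noise_sd)
    edges[[i]] <- tibble(tf = pa, target = tg_names[i])
  }
  list(expr = as_expr_tibble(rbind(tf_x, tg_x)),
       regulators = tf_names,
       truth_edges = dplyr::arrange(dplyr::bind_rows(edges), .data$tf, .data$target))
}
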