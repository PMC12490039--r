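# End-to-end orchestration: a single validated configuration, per-stage
# derived seeds, TSV/GMT/GraphML outputs and JSON manifests with input
# hashes, so deterministic stages re-run byte-identically.

#' Pipeline configuration
#'
#' Collects every stage parameter with the study-scale defaults: soft power
#' scanned over 1..10 at fit threshold 0.8, eigengene merge threshold 0.25,
#' minimum module size 30, CES threshold 3, 1000 bootstrap replicates with
#' aggregate threshold 0.85 and strength floor 0.7, top-100 TF rankings,
#' motif NES floor 3, and a -0.7 connectivity screen.
#'
#' @param simulation a [simulation_config()] for the synthetic stage.
#' @param power fixed soft-thresholding power (default 6, the study's
#'   setting); `NULL` to select by the scale-free scan instead.
#' @param power_candidates,fit_threshold soft-power scan settings (used when
#'   `power` is `NULL`).
#' @param me_diss_threshold,min_module_size,cut_height module detection.
#' @param ces_threshold CES cut for Bayesian-network inputs.
#' @param n_boot,aggregate_threshold,strength_floor,bn_restarts bootstrap BN.
#' @param n_trees,top_k,nes_floor GRN and consensus settings.
#' @param gsea_n_perm GSEA permutations.
#' @param overlap_frac,n_decoys synthetic gene-set settings.
#' @param drug_n_per_class,drug_noise_swaps synthetic drug library settings.
#' @param connectivity_threshold drug screen cut.
#' @param min_weight network-export edge threshold.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            power = 6,
                            power_candidates = 1:10, fit_threshold = 0.8,
                            me_diss_threshold = 0.25, min_module_size = 30,
                            cut_height = 0.8,
                            ces_threshold = 3,
                            n_boot = 1000, aggregate_threshold = 0.85,
                            strength_floor = 0.7, bn_restarts = 1,
                            n_trees = 1000, top_k = 100, nes_floor = 3,
                            gsea_n_perm = 1000,
                            overlap_frac = 0.8, n_decoys = 20,
                            drug_n_per_class = 10, drug_noise_swaps = 5,
                            connectivity_threshold = -0.7,
                            min_weight = 0.3, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fit_threshold >= 0, cfg$me_diss_threshold > 0,
            cfg$min_module_size >= 3, cfg$n_boot >= 100,
            cfg$aggregate_threshold > 0, cfg$aggregate_threshold <= 1,
            cfg$top_k >= 1, cfg$gsea_n_perm >= 100)
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config()`: the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  raw$simulation <- unclass(raw$simulation)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$simulation
  sim$factor_dag <- as.data.frame(sim$factor_dag)
  sim$condition_shift <- unlist(sim$condition_shift)
  raw$simulation <- do.call(simulation_config, sim)
  raw$power_candidates <- as.numeric(raw$power_candidates)
  if (is.null(raw$cut_height)) raw$cut_height <- NULL
  do.call(pipeline_config, raw)
}

write_stage_manifest <- function(out_dir, stage, params, seed, inputs, outputs) {
  dir.create(file.path(out_dir, "manifests"), showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("plaquenet")),
    seed = seed,
    params = params,
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_hashes = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  path <- file.path(out_dir, "manifests", paste0(stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline on synthetic (or supplied) data
#'
#' Executes simulate (unless `data` is supplied) -> preprocess ->
#' co-expression -> enrichment/CES -> GSEA -> Bayesian network -> GRN
#' consensus -> proximity -> signature scores -> drug screen, writing TSV
#' outputs and per-stage JSON manifests under `out_dir`. All randomness is
#' derived from `config$seed` through per-stage seeds, so changing one
#' stage's inputs leaves the others' seeds unchanged.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param data optional list with `expr` and `conditions` to use instead of
#'   the synthetic stage (ground-truth-dependent stages are then skipped).
#' @param skip character vector of stage names to skip (e.g. `"bn"`).
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("plaquenet"),
                         data = NULL, skip = character()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = out_dir)
  stage_seed <- function(i) derive_seed(config$seed, i)
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    p
  }

  # -- simulate ------------------------------------------------------------
  if (is.null(data)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(1)
    sim <- simulate_dataset(sim_cfg)
    res$sim <- sim
    expr <- sim$expr; conditions <- sim$conditions
    f_expr <- tsv(expr, "expression.tsv")
    f_cond <- tsv(conditions, "conditions.tsv")
    write_stage_manifest(out_dir, "simulate", unclass(sim_cfg)["n_genes"],
                         sim_cfg$seed, character(0), c(f_expr, f_cond))
  } else {
    expr <- data$expr; conditions <- data$conditions
    f_expr <- tsv(expr, "expression.tsv")
    f_cond <- tsv(conditions, "conditions.tsv")
  }

  # -- preprocess ----------------------------------------------------------
  expr_f <- mad_filter(collapse_transcripts(expr))
  diff <- differential_ranking(expr_f, conditions)
  res$expr_filtered <- expr_f
  res$differential <- diff
  f_diff <- tsv(diff, "differential.tsv")
  write_stage_manifest(out_dir, "preprocess", list(), NA,
                       c(f_expr, f_cond), c(tsv(expr_f, "expression_filtered.tsv"), f_diff))

  # -- co-expression -------------------------------------------------------
  beta <- if (is.null(config$power)) {
    pick_soft_power(expr_f, config$power_candidates, config$fit_threshold)
  } else {
    config$power
  }
  adj <- pearson_adjacency(expr_f, power = as.numeric(beta))
  tom <- tom_similarity(adj)
  part0 <- cluster_modules(tom, config$min_module_size, config$cut_height)
  part <- merge_modules(expr_f, part0, config$me_diss_threshold)
  res$soft_power <- beta
  res$adjacency <- adj
  res$partition <- part
  f_assign <- tsv(part$assignment, "modules.tsv")
  f_me <- tsv(as_expr_tibble(part$eigengenes) |>
                dplyr::rename(module = "gene"), "eigengenes.tsv")
  write_stage_manifest(out_dir, "wgcna",
                       list(power = as.numeric(beta),
                            min_module_size = config$min_module_size,
                            me_diss_threshold = config$me_diss_threshold),
                       NA, f_diff, c(f_assign, f_me))

  # -- enrichment / CES ----------------------------------------------------
  have_truth <- !is.null(res$sim)
  if (have_truth && !"enrich" %in% skip) {
    collection <- simulate_genesets(res$sim$truth, config$overlap_frac,
                                    config$n_decoys, seed = stage_seed(2))
    res$collection <- collection
    universe <- expr_f$gene
    mods <- sort(unique(part$assignment$module[part$assignment$module > 0]))
    enr <- purrr::map_dfr(mods, function(mm) {
      genes <- part$assignment$gene[part$assignment$module == mm]
      dplyr::mutate(gsoa(genes, collection, universe), module = mm, .before = 1)
    })
    ces_tbl <- enr |>
      dplyr::group_by(.data$module) |>
      dplyr::summarise(ces = ces(dplyr::pick(dplyr::everything())))
    res$enrichment <- enr
    res$ces <- ces_tbl
    f_enr <- tsv(enr, "gsoa.tsv")
    f_ces <- tsv(ces_tbl, "ces.tsv")
    write_stage_manifest(out_dir, "enrich", list(overlap_frac = config$overlap_frac),
                         stage_seed(2), f_assign, c(f_enr, f_ces))

    gsea_res <- purrr::map_dfr(mods, function(mm) {
      genes <- part$assignment$gene[part$assignment$module == mm]
      dplyr::mutate(gsea(diff, genes, n_perm = config$gsea_n_perm,
                         seed = stage_seed(3)), module = mm, .before = 1)
    })
    gsea_res$adj_p <- bh_adjust(gsea_res$p_value)
    res$gsea <- gsea_res
    write_stage_manifest(out_dir, "gsea", list(n_perm = config$gsea_n_perm),
                         stage_seed(3), f_diff, tsv(gsea_res, "gsea.tsv"))
  }

  # -- Bayesian network ----------------------------------------------------
  if (have_truth && !any(c("bn", "enrich") %in% skip)) {
    me_sel <- tryCatch(select_bn_inputs(res$ces, part$eigengenes, config$ces_threshold),
                       error = function(e) part$eigengenes)
    bn <- bootstrap_network(t(me_sel), n_boot = config$n_boot,
                            aggregate_threshold = config$aggregate_threshold,
                            strength_floor = config$strength_floor,
                            seed = stage_seed(4), n_restarts = config$bn_restarts)
    res$bn <- bn
    f_bn <- tsv(bn$edges, "bn_edges.tsv")
    if (nrow(bn$retained) > 0) {
      write_graphml(dplyr::rename(bn$retained, weight = "strength"),
                    file.path(out_dir, "bn.graphml"), min_weight = 0, directed = TRUE)
    }
    write_stage_manifest(out_dir, "bn",
                         list(n_boot = config$n_boot,
                              aggregate_threshold = config$aggregate_threshold,
                              strength_floor = config$strength_floor),
                         stage_seed(4), f_me, f_bn)
  }

  # -- GRN consensus -------------------------------------------------------
  if (have_truth && !"grn" %in% skip) {
    truth <- res$sim$truth
    regulators <- intersect(truth$regulators, expr_f$gene)
    module_genes <- part$assignment$gene[part$assignment$module == 1]
    g3 <- genie3_weights(expr_f, regulators, n_trees = config$n_trees,
                         seed = stage_seed(5))
    mi <- mi_matrix(expr_f[expr_f$gene %in% c(regulators, module_genes), ])
    ar <- dpi_prune(mi, regulators = regulators)
    rank_a <- rank_tfs(g3, module_genes, config$top_k)
    rank_b <- rank_tfs(ar, module_genes, config$top_k)
    motif <- simulate_motif_table(truth, seed = stage_seed(6))
    cons <- consensus_tfs(rank_a, rank_b, motif, module_genes, config$nes_floor)
    res$grn <- list(genie3 = g3, aracne = ar, rank_genie3 = rank_a,
                    rank_aracne = rank_b, motif = motif, consensus = cons)
    f_cons <- tsv(cons, "consensus_tfs.tsv")
    if (any(cons$consensus)) {
      reg <- regulon_subnetwork(g3, cons, module_genes, motif, config$nes_floor)
      res$grn$regulon <- reg
      if (nrow(reg) > 0) {
        write_graphml(reg, file.path(out_dir, "regulon.graphml"),
                      min_weight = 0, directed = TRUE)
      }
    }
    write_stage_manifest(out_dir, "grn",
                         list(n_trees = config$n_trees, top_k = config$top_k,
                              nes_floor = config$nes_floor),
                         stage_seed(5), f_assign, f_cons)
  }

  # -- proximity -----------------------------------------------------------
  n_mods <- length(unique(part$assignment$module[part$assignment$module > 0]))
  if (n_mods >= 2 && !"proximity" %in% skip) {
    prox <- module_proximity(adj, part, focal_module = 1)
    res$proximity <- prox
    write_stage_manifest(out_dir, "proximity", list(focal = 1), NA,
                         f_assign, tsv(prox, "proximity.tsv"))
  }

  # -- signature scores ----------------------------------------------------
  if (!"score" %in% skip && n_mods >= 1) {
    sig_genes <- part$assignment$gene[part$assignment$module == 1]
    scores <- signature_score(expr_f, sig_genes, seed = stage_seed(7)) |>
      dplyr::left_join(conditions, by = "sample")
    res$signature_scores <- scores
    write_stage_manifest(out_dir, "score", list(), stage_seed(7),
                         f_expr, tsv(scores, "signature_scores.tsv"))
  }

  # -- drug screen ---------------------------------------------------------
  if (have_truth && !"connect" %in% skip && n_mods >= 1) {
    sig_genes <- part$assignment$gene[part$assignment$module == 1]
    fc <- diff[diff$gene %in% sig_genes, ]
    query_up <- fc$gene[fc$log2fc > 0]
    query_down <- fc$gene[fc$log2fc < 0]
    if (length(query_down) == 0) {
      # unsigned loadings make the shifted module rise as one block; take the
      # weakest risers as the down side so the screen exercises both tails
      n_dn <- max(1L, round(0.1 * length(query_up)))
      query_down <- utils::tail(query_up, n_dn)
      query_up <- setdiff(query_up, query_down)
    }
    drugs <- simulate_drug_profiles(query_up, query_down, universe = expr_f$gene,
                                    n_per_class = config$drug_n_per_class,
                                    noise_swaps = config$drug_noise_swaps,
                                    seed = stage_seed(8))
    screened <- connectivity_screen(drugs$library, query_up, query_down) |>
      normalize_scores() |>
      dplyr::left_join(drugs$classes, by = "drug")
    candidates <- screen_drugs(screened, config$connectivity_threshold)
    res$drug_screen <- screened
    res$drug_candidates <- candidates
    write_stage_manifest(out_dir, "connect",
                         list(threshold = config$connectivity_threshold),
                         stage_seed(8), f_diff,
                         c(tsv(screened, "drug_screen.tsv"),
                           tsv(candidates, "drug_candidates.tsv")))
  }

  invisible(res)
}
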