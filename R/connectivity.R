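# Connectivity-score drug repurposing: weighted running-sum enrichment of a
# query signature in drug-induced rankings, the two-sided weighted
# connectivity score, per-sign normalization to [-1, 1], and the threshold
# screen.

# Order a profile tibble (gene, score) by score descending, gene ascending.
order_profile <- function(profile) {
  stopifnot(all(c("gene", "score") %in% names(profile)))
  if (anyDuplicated(profile$gene)) abort("duplicate genes in profile")
  profile[order(-profile$score, profile$gene), , drop = FALSE]
}

#' Weighted enrichment score of a gene set in a signed ranking
#'
#' Running-sum enrichment of `gene_set` within the profile ordered by
#' decreasing differential score, with hit increments proportional to
#' `|score|` and uniform miss decrements; the ES is the maximum deviation
#' from zero, in `[-1, 1]`.
#'
#' @param profile tibble (`gene`, `score`) of signed differential scores
#'   covering the full gene universe.
#' @param gene_set character vector; must intersect the profile.
#' @return Scalar ES.
#' @export
signature_es <- function(profile, gene_set) {
  prof <- order_profile(profile)
  hits <- prof$gene %in% gene_set
  if (!any(hits)) {
    abort(paste0("gene_set absent from profile: ",
                 paste(utils::head(setdiff(gene_set, prof$gene), 5), collapse = ", ")))
  }
  es_from_running(running_sum(prof$score, hits, weight_p = 1))
}

#' Weighted connectivity score of a query signature against one profile
#'
#' `wtcs = (es_up - es_down) / 2` when the two enrichment scores have
#' opposite signs, and 0 otherwise; a query with only one non-empty side uses
#' that side's ES directly. Negative values indicate signature reversal.
#'
#' @param profile tibble (`gene`, `score`).
#' @param query_up,query_down disjoint gene vectors; not both empty.
#' @return One-row tibble (`es_up`, `es_down`, `wtcs`).
#' @export
wtcs <- function(profile, query_up, query_down) {
  if (length(intersect(query_up, query_down)) > 0) {
    abort("query_up and query_down overlap")
  }
  if (length(query_up) == 0 && length(query_down) == 0) {
    abort("both query sets are empty")
  }
  es_up <- if (length(query_up) > 0) signature_es(profile, query_up) else NA_real_
  es_down <- if (length(query_down) > 0) signature_es(profile, query_down) else NA_real_
  score <- if (is.na(es_up)) {
    -es_down
  } else if (is.na(es_down)) {
    es_up
  } else if (sign(es_up) == sign(es_down)) {
    0
  } else {
    (es_up - es_down) / 2
  }
  tibble(es_up = es_up, es_down = es_down, wtcs = score)
}

#' Screen a drug-signature library against a query signature
#'
#' Computes the weighted connectivity score of every drug profile in the
#' library. Genes of the query absent from the library universe are dropped
#' with a message.
#'
#' @param library long tibble (`drug`, `gene`, `score`).
#' @param query_up,query_down query gene vectors.
#' @return Tibble (`drug`, `es_up`, `es_down`, `wtcs`).
#' @export
connectivity_screen <- function(library, query_up, query_down) {
  universe <- unique(library$gene)
  dropped <- setdiff(c(query_up, query_down), universe)
  if (length(dropped) > 0) {
    rlang::inform(sprintf("%d query gene(s) not in the library universe; dropped",
                          length(dropped)))
  }
  qu <- intersect(query_up, universe)
  qd <- intersect(query_down, universe)
  library |>
    dplyr::group_by(.data$drug) |>
    dplyr::group_modify(function(prof, key) wtcs(prof, qu, qd)) |>
    dplyr::ungroup()
}

#' Normalize connectivity scores to \[-1, 1\]
#'
#' Positive scores are divided by the maximum positive score, negative ones
#' by the absolute minimum; zeros are unchanged. The map is order-preserving
#' within each sign and idempotent.
#'
#' @param results a [connectivity_screen()] tibble with column `wtcs`.
#' @return The tibble with an added `normalized_score` column.
#' @export
normalize_scores <- function(results) {
  stopifnot(nrow(results) >= 1)
  s <- results$wtcs
  if (all(s == 0)) {
    warn("all connectivity scores are zero; normalization unchanged")
    return(dplyr::mutate(results, normalized_score = s))
  }
  mx <- if (any(s > 0)) max(s[s > 0]) else 1
  mn <- if (any(s < 0)) abs(min(s[s < 0])) else 1
  dplyr::mutate(results, normalized_score = dplyr::case_when(
    s > 0 ~ s / mx,
    s < 0 ~ s / mn,
    TRUE ~ 0))
}

#' Threshold screen for signature-reversing drugs
#'
#' Retains drugs whose normalized connectivity score is strictly below
#' `threshold` (default -0.7), sorted ascending, with the per-side enrichment
#' scores kept for audit.
#'
#' @param results a [normalize_scores()] tibble.
#' @param threshold strict upper bound on the normalized score.
#' @return Candidate tibble sorted by `normalized_score`.
#' @export
screen_drugs <- function(results, threshold = -0.7) {
  stopifnot("normalized_score" %in% names(results))
  results |>
    dplyr::filter(.data$normalized_score < threshold) |>
    dplyr::arrange(.data$normalized_score, .data$drug)
}
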