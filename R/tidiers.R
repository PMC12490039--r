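# broom-style tidiers for the pipeline's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a module partition into a gene-module tibble
#' @param x a `module_partition`.
#' @param ... unused.
#' @return Tibble (`gene`, `module`).
#' @export
tidy.module_partition <- function(x, ...) {
  x$assignment
}

#' One-row summary of a module partition
#' @param x a `module_partition`.
#' @param ... unused.
#' @return Tibble with gene/module counts and mean variance explained.
#' @export
glance.module_partition <- function(x, ...) {
  mods <- x$assignment$module
  tibble(n_genes = length(mods),
         n_modules = length(unique(mods[mods > 0])),
         n_unassigned = sum(mods == 0),
         largest_module = if (any(mods > 0)) max(table(mods[mods > 0])) else 0L,
         mean_variance_explained =
           if (is.null(x$variance_explained)) NA_real_
           else mean(x$variance_explained$variance_explained))
}

#' Tidy a hill-climbing DAG into an edge tibble
#' @param x a `dag_structure`.
#' @param ... unused.
#' @return Tibble (`from`, `to`).
#' @export
tidy.dag_structure <- function(x, ...) {
  x$edges
}

#' One-row summary of a learned DAG
#' @param x a `dag_structure`.
#' @param ... unused.
#' @return Tibble (`n_nodes`, `n_edges`, `bic`).
#' @export
glance.dag_structure <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges), bic = x$score)
}

#' Tidy a bootstrap network into its arc table
#' @param x a `bootstrap_network`.
#' @param retained_only keep only arcs of the averaged network.
#' @param ... unused.
#' @return Tibble (`from`, `to`, `strength`, `direction`, `support`,
#'   `retained`).
#' @export
tidy.bootstrap_network <- function(x, retained_only = FALSE, ...) {
  if (retained_only) x$retained else x$edges
}

#' One-row summary of a bootstrap network
#' @param x a `bootstrap_network`.
#' @param ... unused.
#' @return Tibble with arc counts and the thresholds applied.
#' @export
glance.bootstrap_network <- function(x, ...) {
  tibble(n_arcs_observed = nrow(x$edges), n_arcs_retained = nrow(x$retained),
         n_boot = x$n_boot, aggregate_threshold = x$aggregate_threshold,
         strength_floor = x$strength_floor)
}

#' Tidy a GRN weight matrix into a long edge tibble
#' @param x a `grn_weights` matrix.
#' @param min_weight drop edges below this weight (default: keep nonzero).
#' @param ... unused.
#' @return Tibble (`tf`, `target`, `weight`, `method`).
#' @export
tidy.grn_weights <- function(x, min_weight = .Machine$double.eps, ...) {
  idx <- which(unclass(x) >= min_weight, arr.ind = TRUE)
  tibble(tf = rownames(x)[idx[, 1]], target = colnames(x)[idx[, 2]],
         weight = x[idx], method = attr(x, "method") %||% "unknown") |>
    dplyr::arrange(dplyr::desc(.data$weight))
}

#' One-row summary of a GRN weight matrix
#' @param x a `grn_weights` matrix.
#' @param ... unused.
#' @return Tibble (`method`, `n_regulators`, `n_targets`, `n_edges`).
#' @export
glance.grn_weights <- function(x, ...) {
  tibble(method = attr(x, "method") %||% "unknown",
         n_regulators = nrow(x), n_targets = ncol(x),
         n_edges = sum(unclass(x) > 0))
}
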