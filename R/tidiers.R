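# broom-style tidiers and re-exports ------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a composite network into a long edge table
#'
#' @param x A `composite_network`.
#' @param ... Unused.
#' @return A tibble with columns `block`, `source`, `target`, `weight`.
#' @method tidy composite_network
#' @export
tidy.composite_network <- function(x, ...) {
  purrr::map(.blocks, function(b) {
    tab <- tibble::as_tibble(.block_edges(x, b))
    if (nrow(tab)) dplyr::mutate(tab, block = b, .before = 1) else NULL
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a composite network
#'
#' @param x A `composite_network`.
#' @param ... Unused.
#' @method glance composite_network
#' @export
glance.composite_network <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_phenotypes = length(x$phenotype_ids),
    n_lncrnas = length(x$lncrna_ids),
    n_edges = nrow(tidy(x))
  )
}

#' Tidy a stationary distribution into per-node scores
#'
#' @param x A `stationary_distribution`.
#' @param ... Unused.
#' @return A tibble with columns `node_id`, `layer`, `score`.
#' @method tidy stationary_distribution
#' @export
tidy.stationary_distribution <- function(x, ...) {
  tibble::tibble(
    node_id = names(x$scores),
    layer = unname(x$layers[names(x$scores)]),
    score = unname(x$scores)
  )
}

#' One-row convergence summary of a propagation run
#'
#' @param x A `stationary_distribution`.
#' @param ... Unused.
#' @method glance stationary_distribution
#' @export
glance.stationary_distribution <- function(x, ...) {
  tibble::tibble(
    delta = x$delta,
    iterations = x$iterations,
    residual = x$residual,
    total_score = sum(x$scores)
  )
}

#' Per-fold records of a cross-validation run
#'
#' @param x An `lnc_cv`.
#' @param ... Unused.
#' @method tidy lnc_cv
#' @export
tidy.lnc_cv <- function(x, ...) {
  x$folds
}

#' One-row summary of a cross-validation run
#'
#' @param x An `lnc_cv`.
#' @param ... Unused.
#' @method glance lnc_cv
#' @export
glance.lnc_cv <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    n_folds = nrow(x$folds),
    n_phenotypes = length(unique(x$folds$phenotype_id)),
    mean_percentile = mean(x$folds$percentile),
    scenario = x$scenario,
    layers = paste(x$keep_layers, collapse = "+")
  )
}

#' Long view of a score landscape
#'
#' @param x An `lnc_landscape`.
#' @param ... Unused.
#' @return A tibble with columns `phenotype_id`, `lncrna_id`, `score`.
#' @method tidy lnc_landscape
#' @export
tidy.lnc_landscape <- function(x, ...) {
  tibble::tibble(
    phenotype_id = rep(x$phenotype_ids, times = length(x$lncrna_ids)),
    lncrna_id = rep(x$lncrna_ids, each = length(x$phenotype_ids)),
    score = as.vector(x$scores)
  )
}
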