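# Expression matrices and co-expression edges -------------------------------

#' Construct an expression matrix with a layer assignment
#'
#' Holds FPKM-like non-negative expression values for genes and/or lncRNAs
#' across samples, together with the layer each entity belongs to.  At least
#' three samples are required so that Pearson correlations are defined.
#'
#' @param values Numeric matrix, entities in rows (rownames are entity ids),
#'   samples in columns.
#' @param layer Named character vector mapping every entity id to its layer
#'   (`"gene"` or `"lncrna"`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, layer) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have entity rownames",
                                      call. = FALSE)
  if (anyNA(values)) stop("expression values contain missing entries",
                          call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative",
                            call. = FALSE)
  if (ncol(values) < 3) {
    stop("at least 3 samples are required", call. = FALSE)
  }
  layer <- layer[rownames(values)]
  if (anyNA(layer)) {
    stop("layer assignment missing for: ",
         paste(rownames(values)[is.na(layer)], collapse = ", "),
         call. = FALSE)
  }
  if (!all(layer %in% c("gene", "lncrna"))) {
    stop("expression layers must be 'gene' or 'lncrna'", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  structure(
    list(
      values = values,
      layer = layer,
      entity_ids = rownames(values),
      sample_ids = colnames(values)
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$values), " entities (",
      sum(x$layer == "gene"), " genes, ", sum(x$layer == "lncrna"),
      " lncRNAs) x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its entity-to-layer map from TSV files
#'
#' @param path Expression TSV: first column entity id, remaining columns
#'   samples, with a header row.
#' @param layer_path Two-column TSV (no header) mapping entity id to layer.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, layer_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  lay <- readr::read_tsv(layer_path, col_names = c("entity", "layer"),
                         show_col_types = FALSE)
  layer <- stats::setNames(lay$layer, lay$entity)
  expression_matrix(values, layer)
}

#' Predicted edges from pairwise Pearson co-expression
#'
#' Computes Pearson correlations between the expression profiles of entities
#' in `source_layer` and `target_layer`, and emits a predicted-evidence edge
#' for each pair that passes the threshold.  Under the `"absolute"` policy a
#' pair passes when |r| >= threshold and the edge weight is |r|; under
#' `"signed_positive"` it passes when r >= threshold and the weight is r.
#' Entities with constant profiles (zero variance) cannot be correlated and
#' are skipped with a warning.  Intra-layer output excludes self-pairs.
#'
#' @param expr An [expression_matrix()].
#' @param source_layer,target_layer Layers to correlate (`"gene"` or
#'   `"lncrna"`); equal layers give intra-layer edges.
#' @param threshold Correlation cutoff in \[0, 1\].
#' @param policy `"absolute"` (default) or `"signed_positive"`.
#' @return An [edge_table()] for the corresponding block.
#' @examples
#' v <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
#' em <- expression_matrix(v, c(a = "gene", b = "lncrna"))
#' coexpression_edges(em, "gene", "lncrna", threshold = 0.6)
#' @export
coexpression_edges <- function(expr, source_layer, target_layer,
                               threshold = 0.6,
                               policy = c("absolute", "signed_positive")) {
  stopifnot(inherits(expr, "expression_matrix"))
  policy <- match.arg(policy)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  canon <- .block_for_layers(source_layer, target_layer)
  intra <- source_layer == target_layer

  sds <- apply(expr$values, 1, stats::sd)
  constant <- expr$entity_ids[sds == 0]
  if (length(constant)) {
    warning("skipping constant expression profile(s): ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  usable <- expr$entity_ids[sds > 0]
  src <- sort(usable[expr$layer[usable] == source_layer])
  tgt <- sort(usable[expr$layer[usable] == target_layer])
  if (!length(src) || !length(tgt)) {
    return(new_edge_table(
      tibble::tibble(source = character(), target = character(),
                     weight = numeric(), evidence = character()),
      canon$block
    ))
  }
  r <- stats::cor(t(expr$values[src, , drop = FALSE]),
                  t(expr$values[tgt, , drop = FALSE]))
  long <- tibble::tibble(
    source = rep(src, times = length(tgt)),
    target = rep(tgt, each = length(src)),
    r = as.vector(r)
  )
  if (intra) long <- long[long$source < long$target, ]
  pass <- if (policy == "absolute") abs(long$r) >= threshold else
    long$r >= threshold
  long <- long[pass, ]
  long$weight <- if (policy == "absolute") abs(long$r) else long$r
  # weight 0 (r exactly 0 under threshold 0) is not a representable edge
  long <- long[long$weight > 0, ]
  # guard against floating overshoot of perfectly correlated profiles
  long$weight <- pmin(long$weight, 1)
  out <- tibble::tibble(
    source = if (canon$flip) long$target else long$source,
    target = if (canon$flip) long$source else long$target,
    weight = long$weight,
    evidence = "predicted"
  )
  out <- dplyr::arrange(out, .data$source, .data$target)
  new_edge_table(out, canon$block)
}
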