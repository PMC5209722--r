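# Layer and block vocabulary ------------------------------------------------

.layers <- c("gene", "phenotype", "lncrna")

.blocks <- c(
  "gene_gene", "phenotype_phenotype", "lncrna_lncrna",
  "gene_phenotype", "gene_lncrna", "phenotype_lncrna"
)

#' Layer pair of an association block
#'
#' @param block One of the six block names: `"gene_gene"`,
#'   `"phenotype_phenotype"`, `"lncrna_lncrna"`, `"gene_phenotype"`,
#'   `"gene_lncrna"`, `"phenotype_lncrna"`.
#' @return Character vector of length two: the source layer and target layer.
#' @keywords internal
block_layers <- function(block) {
  switch(block,
    gene_gene = c("gene", "gene"),
    phenotype_phenotype = c("phenotype", "phenotype"),
    lncrna_lncrna = c("lncrna", "lncrna"),
    gene_phenotype = c("gene", "phenotype"),
    gene_lncrna = c("gene", "lncrna"),
    phenotype_lncrna = c("phenotype", "lncrna"),
    stop("unknown block: ", block, call. = FALSE)
  )
}

is_intra_block <- function(block) {
  lay <- block_layers(block)
  lay[1] == lay[2]
}

# canonical block name for an (unordered) pair of layers, plus whether the
# given orientation must be flipped to match it
.block_for_layers <- function(source_layer, target_layer) {
  source_layer <- match.arg(source_layer, .layers)
  target_layer <- match.arg(target_layer, .layers)
  for (b in .blocks) {
    lay <- block_layers(b)
    if (lay[1] == source_layer && lay[2] == target_layer) {
      return(list(block = b, flip = FALSE))
    }
    if (lay[1] == target_layer && lay[2] == source_layer) {
      return(list(block = b, flip = TRUE))
    }
  }
  stop("no block for layers ", source_layer, "/", target_layer, call. = FALSE)
}

# Edge tables ----------------------------------------------------------------

#' Construct a validated edge table for one association block
#'
#' An edge table is a tibble of weighted associations belonging to a single
#' block of the composite network.  Weights lie in (0, 1]; experimentally
#' validated associations carry weight 1, computationally predicted ones carry
#' a correlation-valued weight.  Self-loops are rejected.
#'
#' @param x A data frame with columns `source`, `target` and optionally
#'   `weight` (default 1) and `evidence` (`"experimental"` or `"predicted"`;
#'   defaults to `"experimental"` when the weight is 1, `"predicted"`
#'   otherwise).
#' @param block The association block the records belong to (see
#'   [block_layers()]).
#' @return A tibble of class `edge_table` with columns `source`, `target`,
#'   `weight`, `evidence` and a `block` attribute.
#' @examples
#' edge_table(data.frame(source = "g1", target = "g2", weight = 0.8),
#'            block = "gene_gene")
#' @export
edge_table <- function(x, block) {
  block <- match.arg(block, .blocks)
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c("source", "target"), names(x))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$source <- as.character(x$source)
  x$target <- as.character(x$target)
  if (!"weight" %in% names(x)) x$weight <- 1
  x$weight <- as.numeric(x$weight)
  if (!"evidence" %in% names(x)) {
    x$evidence <- ifelse(!is.na(x$weight) & x$weight == 1,
                         "experimental", "predicted")
  }
  x$evidence <- as.character(x$evidence)
  x <- x[, c("source", "target", "weight", "evidence")]
  .validate_edges(x)
  new_edge_table(x, block)
}

new_edge_table <- function(x, block) {
  structure(
    tibble::as_tibble(x),
    block = block,
    class = c("edge_table", class(tibble::tibble()))
  )
}

#' @export
print.edge_table <- function(x, ...) {
  cat("# Edge table <", attr(x, "block"), ">\n", sep = "")
  NextMethod()
}

# Validate edge records; `where` labels rows (e.g. file line numbers) in
# error messages.
.validate_edges <- function(x, where = seq_len(nrow(x)), what = "row") {
  problems <- character()
  bad_w <- which(!is.finite(x$weight) | x$weight <= 0 | x$weight > 1)
  if (length(bad_w)) {
    problems <- c(problems, paste0(
      what, " ", where[bad_w], ": weight ", x$weight[bad_w],
      " outside (0, 1]"
    ))
  }
  loops <- which(x$source == x$target)
  if (length(loops)) {
    problems <- c(problems, paste0(
      what, " ", where[loops], ": self-loop on '", x$source[loops], "'"
    ))
  }
  bad_e <- which(!x$evidence %in% c("experimental", "predicted"))
  if (length(bad_e)) {
    problems <- c(problems, paste0(
      what, " ", where[bad_e], ": evidence '", x$evidence[bad_e],
      "' not 'experimental' or 'predicted'"
    ))
  }
  if (length(problems)) {
    stop("invalid edge record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

# canonicalize record orientation: intra-layer pairs are unordered, stored
# with the lexicographically smaller id first; cross-layer pairs keep the
# block's source->target orientation.
.canonicalize_pairs <- function(x, block) {
  if (is_intra_block(block)) {
    s <- pmin(x$source, x$target)
    t <- pmax(x$source, x$target)
    x$source <- s
    x$target <- t
  }
  x
}

#' Read an edge list from a tab-separated file
#'
#' The format is TSV with no header (lines starting with `#` are skipped):
#' `source<TAB>target[<TAB>weight[<TAB>evidence]]`.  A missing weight defaults
#' to 1; a missing evidence field defaults to `"experimental"` when the weight
#' is 1 and `"predicted"` otherwise.  Rows violating the edge invariants
#' (weight outside (0, 1], self-loops) are reported with their line numbers.
#'
#' @param path Path to the TSV file.
#' @inheritParams edge_table
#' @return An [edge_table()].
#' @export
read_edge_list <- function(path, block) {
  block <- match.arg(block, .blocks)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 4)
  if (length(bad)) {
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(keep[bad], collapse = ", "),
         " (expected 2-4 tab-separated fields)", call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  weight_chr <- get(3)
  weight <- suppressWarnings(as.numeric(weight_chr))
  unparsed <- which(!is.na(weight_chr) & is.na(weight))
  if (length(unparsed)) {
    stop("unparsable weight in ", path, " at line(s) ",
         paste(keep[unparsed], collapse = ", "), call. = FALSE)
  }
  weight[is.na(weight)] <- 1
  evidence <- get(4)
  evidence[is.na(evidence)] <- ifelse(weight[is.na(evidence)] == 1,
                                      "experimental", "predicted")
  x <- tibble::tibble(
    source = get(1), target = get(2),
    weight = weight, evidence = evidence
  )
  .validate_edges(x, where = keep, what = "line")
  new_edge_table(x, block)
}

#' Write an edge table to a tab-separated file
#'
#' Inverse of [read_edge_list()]; weights are written with full precision so
#' the round trip reproduces the table record for record.
#'
#' @param x An [edge_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "edge_table"))
  lines <- sprintf("%s\t%s\t%s\t%s", x$source, x$target,
                   sprintf("%.17g", x$weight), x$evidence)
  writeLines(c(paste0("# source\ttarget\tweight\tevidence"), lines), path)
  invisible(path)
}

#' Merge duplicate associations, letting experimental evidence win
#'
#' Collapses one or more edge tables for the same block to a single record per
#' node pair.  Experimental evidence (weight 1) takes precedence over
#' predicted; among duplicates of equal evidence the maximum weight is kept.
#' Intra-layer pairs are compared without regard to orientation.  The
#' operation is idempotent.
#'
#' @param ... Edge tables for the same block (or a single list of them).
#' @return A merged, canonically ordered [edge_table()].
#' @export
merge_edge_evidence <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && !inherits(tabs[[1]], "edge_table")) {
    tabs <- tabs[[1]]
  }
  if (!length(tabs)) stop("no edge tables supplied", call. = FALSE)
  if (!all(vapply(tabs, inherits, logical(1), "edge_table"))) {
    stop("all inputs must be edge tables", call. = FALSE)
  }
  blocks <- unique(vapply(tabs, attr, character(1), "block"))
  if (length(blocks) != 1) {
    stop("cannot merge edge tables from different blocks: ",
         paste(blocks, collapse = ", "), call. = FALSE)
  }
  block <- blocks
  x <- dplyr::bind_rows(lapply(tabs, function(t) tibble::as_tibble(t)))
  x <- .canonicalize_pairs(x, block)
  out <- x |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      weight = if (any(.data$evidence == "experimental")) {
        max(.data$weight[.data$evidence == "experimental"])
      } else {
        max(.data$weight)
      },
      evidence = if (any(.data$evidence == "experimental")) {
        "experimental"
      } else {
        "predicted"
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target)
  new_edge_table(out, block)
}

#' Keep each phenotype's k most similar neighbours
#'
#' Sparsifies a phenotype similarity table by retaining, for every phenotype,
#' its `k` highest-weight neighbours.  The result is symmetrized by union: an
#' edge survives if it is in the top-k list of either endpoint.  Ties at the
#' k-th weight are broken by lexicographic node id.
#'
#' @param similarity A `phenotype_phenotype` [edge_table()].
#' @param k Number of neighbours to retain per phenotype (positive integer).
#' @return A sparsified [edge_table()].
#' @export
top_k_phenotype_edges <- function(similarity, k) {
  stopifnot(inherits(similarity, "edge_table"))
  if (attr(similarity, "block") != "phenotype_phenotype") {
    stop("top_k_phenotype_edges expects a phenotype_phenotype table",
         call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  x <- .canonicalize_pairs(tibble::as_tibble(similarity),
                           "phenotype_phenotype") |>
    dplyr::distinct(.data$source, .data$target, .keep_all = TRUE)
  # both orientations, then per-node top-k
  directed <- dplyr::bind_rows(
    x,
    dplyr::mutate(x, tmp = .data$source, source = .data$target,
                  target = .data$tmp, tmp = NULL)
  )
  kept <- directed |>
    dplyr::group_by(.data$source) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$target,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
  kept_pairs <- unique(paste(pmin(kept$source, kept$target),
                             pmax(kept$source, kept$target), sep = "\r"))
  out <- x[paste(x$source, x$target, sep = "\r") %in% kept_pairs, ]
  out <- dplyr::arrange(out, .data$source, .data$target)
  new_edge_table(out, "phenotype_phenotype")
}
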