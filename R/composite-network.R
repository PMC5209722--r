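# The multi-level composite network ------------------------------------------

#' Assemble the weighted multi-level composite network
#'
#' Builds the three-layer composite network (genes, phenotypes, lncRNAs) from
#' one edge table per association block.  The six weighted adjacency blocks
#' W_G, W_P, W_L (intra-layer, symmetric, zero diagonal) and W_GP, W_GL, W_PL
#' (cross-layer) are assembled over the union of the node ids observed in the
#' tables plus any caller-supplied universes, so isolated nodes (e.g.
#' never-connected candidate lncRNAs) are representable.  Node ids must be
#' unique within a layer and may not appear in two layers.  If a pair is
#' recorded in both orientations with different weights, the maximum is kept.
#'
#' @param tables Named list of [edge_table()]s; names are block names and
#'   must match each table's own block.  Missing blocks are treated as empty.
#' @param node_universes Optional named list with entries `gene`, `phenotype`,
#'   `lncrna` of ids to include even when unconnected.
#' @return An object of class `composite_network` with fields `gene_ids`,
#'   `phenotype_ids`, `lncrna_ids` and the six matrices `W_G`, `W_P`, `W_L`,
#'   `W_GP`, `W_GL`, `W_PL`.
#' @examples
#' gg <- edge_table(data.frame(source = "g1", target = "g2"), "gene_gene")
#' gp <- edge_table(data.frame(source = "g1", target = "p1"), "gene_phenotype")
#' build_composite(list(gene_gene = gg, gene_phenotype = gp))
#' @export
build_composite <- function(tables, node_universes = NULL) {
  if (!is.list(tables)) stop("tables must be a list of edge tables",
                             call. = FALSE)
  if (is.null(names(tables)) && length(tables)) {
    names(tables) <- vapply(tables, attr, character(1), "block")
  }
  bad <- setdiff(names(tables), .blocks)
  if (length(bad)) stop("unknown block name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (b in names(tables)) {
    if (!inherits(tables[[b]], "edge_table")) {
      stop("tables$", b, " is not an edge_table", call. = FALSE)
    }
    if (attr(tables[[b]], "block") != b) {
      stop("tables$", b, " is an edge table for block '",
           attr(tables[[b]], "block"), "'", call. = FALSE)
    }
  }

  ids <- list(gene = character(), phenotype = character(),
              lncrna = character())
  for (b in names(tables)) {
    lay <- block_layers(b)
    ids[[lay[1]]] <- c(ids[[lay[1]]], tables[[b]]$source)
    ids[[lay[2]]] <- c(ids[[lay[2]]], tables[[b]]$target)
  }
  if (!is.null(node_universes)) {
    for (lay in intersect(names(node_universes), .layers)) {
      ids[[lay]] <- c(ids[[lay]], as.character(node_universes[[lay]]))
    }
  }
  ids <- lapply(ids, function(v) sort(unique(v)))

  # an id may not denote nodes in two layers
  for (pair in list(c("gene", "phenotype"), c("gene", "lncrna"),
                    c("phenotype", "lncrna"))) {
    clash <- intersect(ids[[pair[1]]], ids[[pair[2]]])
    if (length(clash)) {
      stop("id(s) assigned to both ", pair[1], " and ", pair[2],
           " layers: ", paste(clash, collapse = ", "), call. = FALSE)
    }
  }

  block_matrix <- function(b, rows, cols, symmetric) {
    W <- matrix(0, length(rows), length(cols),
                dimnames = list(rows, cols))
    tab <- tables[[b]]
    if (!is.null(tab) && nrow(tab)) {
      agg <- tibble::as_tibble(tab) |>
        dplyr::group_by(.data$source, .data$target) |>
        dplyr::summarise(weight = max(.data$weight), .groups = "drop")
      W[cbind(match(agg$source, rows), match(agg$target, cols))] <- agg$weight
    }
    if (symmetric) {
      W <- pmax(W, t(W))
      diag(W) <- 0
    }
    W
  }

  net <- structure(
    list(
      gene_ids = ids$gene,
      phenotype_ids = ids$phenotype,
      lncrna_ids = ids$lncrna,
      W_G = block_matrix("gene_gene", ids$gene, ids$gene, TRUE),
      W_P = block_matrix("phenotype_phenotype", ids$phenotype,
                         ids$phenotype, TRUE),
      W_L = block_matrix("lncrna_lncrna", ids$lncrna, ids$lncrna, TRUE),
      W_GP = block_matrix("gene_phenotype", ids$gene, ids$phenotype, FALSE),
      W_GL = block_matrix("gene_lncrna", ids$gene, ids$lncrna, FALSE),
      W_PL = block_matrix("phenotype_lncrna", ids$phenotype, ids$lncrna,
                          FALSE)
    ),
    class = "composite_network"
  )
  validate_composite_network(net)
}

#' Validate the invariants of a composite network
#'
#' Checks symmetry and zero diagonals of the intra-layer blocks, the \[0, 1\]
#' range of all entries, duplicate-free node registries and the disjointness
#' of layers.  Returns the network invisibly when valid, errors otherwise.
#'
#' @param net A `composite_network`.
#' @export
validate_composite_network <- function(net) {
  stopifnot(inherits(net, "composite_network"))
  for (lay in .layers) {
    v <- layer_ids(net, lay)
    if (anyDuplicated(v)) stop("duplicate ", lay, " ids", call. = FALSE)
  }
  all_ids <- c(net$gene_ids, net$phenotype_ids, net$lncrna_ids)
  if (anyDuplicated(all_ids)) {
    stop("id(s) shared between layers: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  for (b in c("W_G", "W_P", "W_L", "W_GP", "W_GL", "W_PL")) {
    W <- net[[b]]
    if (any(W < 0) || any(W > 1)) {
      stop(b, " has entries outside [0, 1]", call. = FALSE)
    }
  }
  for (b in c("W_G", "W_P", "W_L")) {
    W <- net[[b]]
    if (nrow(W) && !isTRUE(all.equal(W, t(W), tolerance = 0))) {
      stop(b, " is not exactly symmetric", call. = FALSE)
    }
    if (nrow(W) && any(diag(W) != 0)) {
      stop(b, " has a nonzero diagonal", call. = FALSE)
    }
  }
  dims <- c(
    nrow(net$W_G) == length(net$gene_ids),
    nrow(net$W_P) == length(net$phenotype_ids),
    nrow(net$W_L) == length(net$lncrna_ids),
    all(dim(net$W_GP) == c(length(net$gene_ids), length(net$phenotype_ids))),
    all(dim(net$W_GL) == c(length(net$gene_ids), length(net$lncrna_ids))),
    all(dim(net$W_PL) == c(length(net$phenotype_ids), length(net$lncrna_ids)))
  )
  if (!all(dims)) stop("block dimensions inconsistent with registries",
                       call. = FALSE)
  invisible(net)
}

layer_ids <- function(net, layer) {
  switch(layer,
    gene = net$gene_ids,
    phenotype = net$phenotype_ids,
    lncrna = net$lncrna_ids,
    stop("unknown layer: ", layer, call. = FALSE)
  )
}

#' Node order of a composite network
#'
#' Nodes are ordered genes, then phenotypes, then lncRNAs, each layer sorted
#' lexicographically; the transition model and all probability vectors use
#' this order.
#'
#' @param net A `composite_network`.
#' @return Character vector of node ids.
#' @export
node_order <- function(net) {
  c(net$gene_ids, net$phenotype_ids, net$lncrna_ids)
}

node_layers <- function(net) {
  stats::setNames(
    rep(.layers, c(length(net$gene_ids), length(net$phenotype_ids),
                   length(net$lncrna_ids))),
    node_order(net)
  )
}

#' @export
print.composite_network <- function(x, ...) {
  nz <- function(W, sym) if (sym) sum(W != 0) / 2 else sum(W != 0)
  cat("Composite network: ", length(x$gene_ids), " genes, ",
      length(x$phenotype_ids), " phenotypes, ", length(x$lncrna_ids),
      " lncRNAs\n", sep = "")
  cat("  associations: gene-gene ", nz(x$W_G, TRUE),
      ", phen-phen ", nz(x$W_P, TRUE),
      ", lnc-lnc ", nz(x$W_L, TRUE),
      ", gene-phen ", nz(x$W_GP, FALSE),
      ", gene-lnc ", nz(x$W_GL, FALSE),
      ", phen-lnc ", nz(x$W_PL, FALSE), "\n", sep = "")
  invisible(x)
}

#' Restrict a composite network to a subset of layers
#'
#' Drops the node registries of excluded layers and every block touching
#' them, enabling ablation baselines within the same propagation engine:
#' `keep = c("phenotype", "lncrna")` reproduces a phenotype-lncRNA-only
#' design, `keep = "lncrna"` a lncRNA-network-only design.  The lncRNA layer
#' must be kept (there would otherwise be nothing to rank).
#'
#' @param net A `composite_network`.
#' @param keep Character subset of `c("gene", "phenotype", "lncrna")`.
#' @return A `composite_network` over the kept layers.
#' @export
restrict_layers <- function(net, keep) {
  stopifnot(inherits(net, "composite_network"))
  keep <- match.arg(keep, .layers, several.ok = TRUE)
  if (!"lncrna" %in% keep) {
    stop("keep must include the lncrna layer (nothing to rank otherwise)",
         call. = FALSE)
  }
  g <- if ("gene" %in% keep) net$gene_ids else character()
  p <- if ("phenotype" %in% keep) net$phenotype_ids else character()
  l <- net$lncrna_ids
  out <- structure(
    list(
      gene_ids = g, phenotype_ids = p, lncrna_ids = l,
      W_G = net$W_G[g, g, drop = FALSE],
      W_P = net$W_P[p, p, drop = FALSE],
      W_L = net$W_L[l, l, drop = FALSE],
      W_GP = net$W_GP[g, p, drop = FALSE],
      W_GL = net$W_GL[g, l, drop = FALSE],
      W_PL = net$W_PL[p, l, drop = FALSE]
    ),
    class = "composite_network"
  )
  validate_composite_network(out)
}

# Serialization ---------------------------------------------------------------

.block_matrix_name <- c(
  gene_gene = "W_G", phenotype_phenotype = "W_P", lncrna_lncrna = "W_L",
  gene_phenotype = "W_GP", gene_lncrna = "W_GL", phenotype_lncrna = "W_PL"
)

# edge table view of one block; evidence is inferred as experimental iff the
# weight is exactly 1 (the weighting convention of the network)
.block_edges <- function(net, block) {
  W <- net[[.block_matrix_name[[block]]]]
  idx <- which(W != 0, arr.ind = TRUE)
  if (is_intra_block(block)) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  w <- W[idx]
  out <- tibble::tibble(
    source = as.character(rownames(W)[idx[, 1]]),
    target = as.character(colnames(W)[idx[, 2]]),
    weight = w,
    evidence = ifelse(w == 1, "experimental", "predicted")
  )
  out <- dplyr::arrange(out, .data$source, .data$target)
  new_edge_table(out, block)
}

#' Serialize a composite network to a directory
#'
#' Writes the six canonical edge-list TSVs plus a JSON manifest recording the
#' node registries of every layer (so isolated nodes survive the round trip),
#' layer sizes and per-file MD5 checksums.
#'
#' @param net A `composite_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  validate_composite_network(net)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (b in .blocks) {
    f <- file.path(dir, paste0(b, ".tsv"))
    write_edge_list(.block_edges(net, b), f)
    files[b] <- f
  }
  manifest <- list(
    format = "lncprior-network/1",
    layers = list(
      gene = as.list(net$gene_ids),
      phenotype = as.list(net$phenotype_ids),
      lncrna = as.list(net$lncrna_ids)
    ),
    layer_sizes = list(
      gene = length(net$gene_ids),
      phenotype = length(net$phenotype_ids),
      lncrna = length(net$lncrna_ids)
    ),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a serialized composite network
#'
#' @param dir Directory written by [write_network()].
#' @return A `composite_network`.
#' @export
read_network <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a serialized network (no manifest.json in ", dir, ")",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  tables <- list()
  for (b in .blocks) {
    f <- file.path(dir, paste0(b, ".tsv"))
    if (file.exists(f)) tables[[b]] <- read_edge_list(f, b)
  }
  universes <- lapply(manifest$layers, function(v) unlist(v, use.names = FALSE))
  build_composite(tables, node_universes = universes)
}
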