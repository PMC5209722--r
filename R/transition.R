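# Block-structured row-stochastic transition model ---------------------------

.check_jump_params <- function(x, y, z) {
  for (nm in c("x", "y", "z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop("jump parameter ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (x + y > 1 || x + z > 1 || y + z > 1) {
    stop("jump parameters must satisfy x+y <= 1, x+z <= 1, y+z <= 1 ",
         "(intra-layer mass would go negative)", call. = FALSE)
  }
  invisible(c(x = x, y = y, z = z))
}

# rows of W scaled so each nonzero row sums to its entry of `mass`
.scale_rows <- function(W, mass) {
  if (!nrow(W) || !ncol(W)) return(W)
  s <- rowSums(W)
  nz <- s > 0
  out <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  if (any(nz)) {
    out[nz, ] <- W[nz, , drop = FALSE] * (mass[nz] / s[nz])
  }
  out
}

#' Build the composite transition matrix
#'
#' Constructs the row-stochastic transition matrix M of the random walk on
#' the composite network, with block structure (M_G, M_GP, M_GL / M_PG, M_P,
#' M_PL / M_LG, M_LP, M_L).  For a node in one layer, each cross-layer block
#' row with at least one edge receives total mass equal to the jumping
#' probability of that layer pair (`x` gene-phenotype, `y` gene-lncRNA, `z`
#' phenotype-lncRNA), distributed proportionally to the edge weights; the
#' intra-layer row, if nonzero, receives the remaining mass, distributed
#' proportionally to the intra-layer weights.  When a row ends up with
#' positive but sub-unit mass (e.g. a node with bridges but no intra-layer
#' edges), it is rescaled to sum exactly 1 so that M stays a proper Markov
#' kernel; `rescale = FALSE` leaves such rows sub-stochastic for sensitivity
#' checks.  Edge-free nodes keep an all-zero row and are recorded as
#' dangling.
#'
#' @param net A `composite_network`.
#' @param x,y,z Jumping probabilities between the gene and phenotype, gene
#'   and lncRNA, and phenotype and lncRNA layers; each in \[0, 1\] with
#'   pairwise sums at most 1.  Defaults 1/3.
#' @param rescale Rescale sub-unit rows to sum 1 (default `TRUE`).
#' @return An object of class `transition_model` with fields `node_order`,
#'   `M`, `dangling` (ids of edge-free nodes), `layers` and `params`.
#' @examples
#' gg <- edge_table(data.frame(source = "g1", target = "g2"), "gene_gene")
#' net <- build_composite(list(gene_gene = gg))
#' build_transition(net)$M
#' @export
build_transition <- function(net, x = 1 / 3, y = 1 / 3, z = 1 / 3,
                             rescale = TRUE) {
  validate_composite_network(net)
  .check_jump_params(x, y, z)
  ids <- node_order(net)
  layers <- node_layers(net)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))

  plan <- list(
    gene = list(
      intra = net$W_G,
      bridges = list(
        list(cols = net$phenotype_ids, W = net$W_GP, j = x),
        list(cols = net$lncrna_ids, W = net$W_GL, j = y)
      )
    ),
    phenotype = list(
      intra = net$W_P,
      bridges = list(
        list(cols = net$gene_ids, W = t(net$W_GP), j = x),
        list(cols = net$lncrna_ids, W = net$W_PL, j = z)
      )
    ),
    lncrna = list(
      intra = net$W_L,
      bridges = list(
        list(cols = net$gene_ids, W = t(net$W_GL), j = y),
        list(cols = net$phenotype_ids, W = t(net$W_PL), j = z)
      )
    )
  )

  for (lay in .layers) {
    rows <- layer_ids(net, lay)
    if (!length(rows)) next
    pl <- plan[[lay]]
    jump_present <- rep(0, length(rows))
    for (br in pl$bridges) {
      if (!length(br$cols)) next
      s <- rowSums(br$W)
      jump_present <- jump_present + br$j * (s > 0)
      M[rows, br$cols] <- .scale_rows(br$W, rep(br$j, length(rows)))
    }
    intra_mass <- 1 - jump_present
    M[rows, rows] <- .scale_rows(pl$intra, intra_mass)
  }

  tot <- rowSums(M)
  dangling <- ids[tot == 0]
  if (rescale) {
    fix <- tot > 0 & abs(tot - 1) > .Machine$double.eps * 4
    if (any(fix)) M[fix, ] <- M[fix, , drop = FALSE] / tot[fix]
  }

  structure(
    list(
      node_order = ids,
      M = M,
      dangling = dangling,
      layers = layers,
      params = c(x = x, y = y, z = z),
      rescaled = rescale
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition model over ", length(x$node_order), " nodes (",
      length(x$dangling), " dangling); x=", signif(x$params["x"], 4),
      " y=", signif(x$params["y"], 4), " z=", signif(x$params["z"], 4),
      "\n", sep = "")
  invisible(x)
}

#' Total outgoing probability mass of a node
#'
#' Diagnostic: 1 for any connected node of a rescaled model, 0 for dangling
#' nodes.
#'
#' @param model A `transition_model`.
#' @param node_id A node id present in the model.
#' @return The row sum of M at the node.
#' @export
row_mass <- function(model, node_id) {
  stopifnot(inherits(model, "transition_model"))
  if (!node_id %in% model$node_order) {
    stop("unknown node id: ", node_id, call. = FALSE)
  }
  sum(model$M[node_id, ])
}
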