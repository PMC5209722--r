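# Seed vectors, propagation, ranking -----------------------------------------

#' Define the seed set of a prioritization run
#'
#' The seeds of one query are the disease phenotype of interest together with
#' its known disease genes and known disease lncRNAs.  Any of the three sets
#' may be empty, but at least one must map to the network.
#'
#' @param phenotypes,genes,lncrnas Character vectors of node ids.
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(phenotypes = character(), genes = character(),
                     lncrnas = character()) {
  structure(
    list(
      phenotypes = unique(as.character(phenotypes)),
      genes = unique(as.character(genes)),
      lncrnas = unique(as.character(lncrnas))
    ),
    class = "seed_set"
  )
}

#' Read a seed file
#'
#' Two-column TSV (no header, `#` comments allowed): `type<TAB>id` with type
#' in `phenotype`, `gene`, `lncrna`.
#'
#' @param path Path to the seed TSV.
#' @return A [seed_set()].
#' @export
read_seed_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("seed file rows must be 'type<TAB>id'", call. = FALSE)
  }
  type <- vapply(parts, `[`, character(1), 1)
  id <- vapply(parts, `[`, character(1), 2)
  if (!all(type %in% c("phenotype", "gene", "lncrna"))) {
    stop("seed types must be phenotype, gene or lncrna", call. = FALSE)
  }
  seed_set(
    phenotypes = id[type == "phenotype"],
    genes = id[type == "gene"],
    lncrnas = id[type == "lncrna"]
  )
}

#' Build the mixed initial probability vector
#'
#' Within each layer, seed nodes share that layer's probability uniformly
#' (each layer's component sums to 1), and the layers are then weighted by
#' `alpha` (gene), `beta` (phenotype) and `1 - alpha - beta` (lncRNA).  When
#' a layer has no seeds its weight is redistributed proportionally over the
#' weights of the nonempty layers, so the vector always sums to 1.  Seed ids
#' absent from the network are dropped with a warning; if all seeds drop the
#' call fails.
#'
#' @param seeds A [seed_set()].
#' @param net A `composite_network`.
#' @param alpha,beta Importance of the gene and phenotype layers, each in
#'   \[0, 1\] with `alpha + beta <= 1`.  Defaults 1/3.
#' @return A named numeric vector over [node_order()] of class
#'   `probability_vector`, summing to 1.
#' @examples
#' gg <- edge_table(data.frame(source = "g1", target = "g2"), "gene_gene")
#' pl <- edge_table(data.frame(source = "p1", target = "l1"),
#'                  "phenotype_lncrna")
#' net <- build_composite(list(gene_gene = gg, phenotype_lncrna = pl))
#' build_seed_vector(seed_set(phenotypes = "p1", genes = c("g1", "g2"),
#'                            lncrnas = "l1"), net)
#' @export
build_seed_vector <- function(seeds, net, alpha = 1 / 3, beta = 1 / 3) {
  stopifnot(inherits(seeds, "seed_set"))
  validate_composite_network(net)
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (alpha + beta > 1) stop("alpha + beta must be at most 1", call. = FALSE)

  kept <- list(
    gene = intersect(seeds$genes, net$gene_ids),
    phenotype = intersect(seeds$phenotypes, net$phenotype_ids),
    lncrna = intersect(seeds$lncrnas, net$lncrna_ids)
  )
  dropped <- setdiff(
    c(seeds$genes, seeds$phenotypes, seeds$lncrnas),
    unlist(kept, use.names = FALSE)
  )
  if (!any(lengths(kept) > 0)) {
    stop("no seed id maps to the network", call. = FALSE)
  }
  if (length(dropped)) {
    warning("seed id(s) not in the network, dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }

  w <- c(gene = alpha, phenotype = beta, lncrna = 1 - alpha - beta)
  present <- lengths(kept) > 0
  wp <- w[present]
  wp <- if (sum(wp) > 0) wp / sum(wp) else
    stats::setNames(rep(1 / length(wp), length(wp)), names(wp))

  ids <- node_order(net)
  p0 <- stats::setNames(numeric(length(ids)), ids)
  for (lay in names(wp)) {
    p0[kept[[lay]]] <- wp[[lay]] / length(kept[[lay]])
  }
  structure(p0, class = "probability_vector")
}

# Stationary distributions ----------------------------------------------------

new_stationary <- function(scores, iterations, residual, delta, layers) {
  structure(
    list(
      scores = scores,
      iterations = iterations,
      residual = residual,
      delta = delta,
      layers = layers
    ),
    class = "stationary_distribution"
  )
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("Stationary distribution over ", length(x$scores), " nodes; delta=",
      x$delta, ", ", x$iterations, " iteration(s), final L1 residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Propagate a seed vector to its stationary distribution
#'
#' Iterates the random walk with restart
#' \deqn{p^{t+1} = (1-\delta)\, M^T p^t + \delta\, p^0}
#' until the L1 norm of successive iterates falls below `tol`.  Because
#' dangling rows of M are zero, the walker mass they absorb is recovered only
#' through the restart term, so the stationary scores may sum to slightly
#' less than 1 when dangling nodes exist; ranking is unaffected.
#'
#' @param model A `transition_model`.
#' @param p0 A probability vector over the model's node order (as built by
#'   [build_seed_vector()]).
#' @param delta Restart probability in (0, 1]; default 0.7.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error reporting the last
#'   residual.
#' @return A `stationary_distribution` with the converged scores, the
#'   iteration count and the final residual.
#' @export
propagate <- function(model, p0, delta = 0.7, tol = 1e-10,
                      max_iter = 10000) {
  stopifnot(inherits(model, "transition_model"))
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]", call. = FALSE)
  }
  p0 <- .align_p0(p0, model)
  Mt <- t(model$M)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - delta) * as.vector(Mt %*% p) + delta * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      names(p) <- model$node_order
      return(new_stationary(p, it, res, delta, model$layers))
    }
  }
  stop("propagation did not converge within ", max_iter,
       " iterations (last L1 residual ", format(res, digits = 6), ")",
       call. = FALSE)
}

#' Closed-form fixed point of the propagation update
#'
#' Solves \eqn{p = \delta (I - (1-\delta) M^T)^{-1} p^0} by a dense linear
#' solve — the exact fixed point of [propagate()], used as a verification
#' oracle.  Refuses networks above 2000 nodes, where the dense solve is no
#' longer appropriate.
#'
#' @inheritParams propagate
#' @return A `stationary_distribution` (iteration count 0).
#' @export
closed_form_stationary <- function(model, p0, delta = 0.7) {
  stopifnot(inherits(model, "transition_model"))
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]", call. = FALSE)
  }
  n <- length(model$node_order)
  if (n > 2000) {
    stop("closed_form_stationary is a dense oracle and refuses networks ",
         "above 2000 nodes (got ", n, "); use propagate()", call. = FALSE)
  }
  p0 <- .align_p0(p0, model)
  A <- diag(n) - (1 - delta) * t(model$M)
  p <- as.vector(solve(A, delta * p0))
  names(p) <- model$node_order
  new_stationary(p, 0L, 0, delta, model$layers)
}

.align_p0 <- function(p0, model) {
  p0 <- unclass(p0)
  if (!is.null(names(p0))) {
    if (!setequal(names(p0), model$node_order)) {
      stop("p0 is not defined over the model's node order", call. = FALSE)
    }
    p0 <- p0[model$node_order]
  } else if (length(p0) != length(model$node_order)) {
    stop("p0 has length ", length(p0), ", model has ",
         length(model$node_order), " nodes", call. = FALSE)
  }
  if (any(p0 < 0)) stop("p0 must be non-negative", call. = FALSE)
  if (abs(sum(p0) - 1) > 1e-9) {
    stop("p0 must sum to 1 (got ", sum(p0), ")", call. = FALSE)
  }
  as.numeric(p0)
}

#' Rank candidate lncRNAs by stationary score
#'
#' Sorts the candidates by their stationary scores, descending, with ties
#' broken by lexicographic id so rankings are deterministic.  Isolated
#' (dangling) candidates carry score 0 and rank last.  Seed lncRNAs are
#' excluded from candidacy by the caller ([loocv()] and the `rank` entry
#' point do this).
#'
#' @param stat A `stationary_distribution`.
#' @param candidates Character vector of candidate lncRNA ids; ids outside
#'   the lncRNA registry are reported with a warning and dropped.
#' @return A tibble of class `ranked_lncrnas` with columns `lncrna_id`,
#'   `score`, `rank`.
#' @export
rank_candidates <- function(stat, candidates) {
  stopifnot(inherits(stat, "stationary_distribution"))
  candidates <- unique(as.character(candidates))
  lnc_ids <- names(stat$layers)[stat$layers == "lncrna"]
  unknown <- setdiff(candidates, lnc_ids)
  if (length(unknown)) {
    warning("candidate id(s) not in the lncRNA registry, dropped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    candidates <- setdiff(candidates, unknown)
  }
  if (!length(candidates)) {
    stop("empty candidate set", call. = FALSE)
  }
  out <- tibble::tibble(
    lncrna_id = candidates,
    score = unname(stat$scores[candidates])
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lncrna_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("ranked_lncrnas", class(tibble::tibble()))
  out
}

#' Score and rank a candidate list for one query
#'
#' Convenience wrapper chaining [build_transition()], [build_seed_vector()],
#' [propagate()] and [rank_candidates()].  Seed lncRNAs are excluded from the
#' candidate set.
#'
#' @param net A `composite_network`.
#' @param seeds A [seed_set()].
#' @param candidates Candidate lncRNA ids; default all non-seed lncRNAs.
#' @param delta Restart probability.
#' @param x,y,z Jumping probabilities (see [build_transition()]).
#' @param alpha,beta Layer mix weights (see [build_seed_vector()]).
#' @param tol,max_iter Convergence controls for [propagate()].
#' @param normalize Divide scores by their sum for reporting (ranking
#'   invariant); default `FALSE`.
#' @return A `ranked_lncrnas` tibble.
#' @export
rank_lncrnas <- function(net, seeds, candidates = NULL, delta = 0.7,
                         x = 1 / 3, y = 1 / 3, z = 1 / 3,
                         alpha = 1 / 3, beta = 1 / 3,
                         tol = 1e-10, max_iter = 10000, normalize = FALSE) {
  model <- build_transition(net, x = x, y = y, z = z)
  p0 <- build_seed_vector(seeds, net, alpha = alpha, beta = beta)
  stat <- propagate(model, p0, delta = delta, tol = tol,
                    max_iter = max_iter)
  if (is.null(candidates)) {
    candidates <- setdiff(net$lncrna_ids, seeds$lncrnas)
  } else {
    candidates <- setdiff(candidates, seeds$lncrnas)
  }
  out <- rank_candidates(stat, candidates)
  if (normalize && sum(out$score) > 0) {
    out$score <- out$score / sum(out$score)
  }
  out
}
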