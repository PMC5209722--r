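# Synthetic benchmark networks with planted disease modules -------------------

#' Configuration of the synthetic network generator
#'
#' The generator is a layered stochastic block model emulating the
#' statistical shape of a real composite network: modular intra-layer
#' structure, dense gene-lncRNA bridges within a disease module, sparse
#' background edges elsewhere, experimental (weight 1) links from each
#' disease phenotype to its designated known genes and lncRNAs, and
#' correlation-valued weights on predicted edges.
#'
#' @param n_genes,n_phenotypes,n_lncrnas Layer sizes.
#' @param n_diseases Number of planted diseases; each claims one phenotype.
#' @param module_size_genes,module_size_lncrnas Members per disease module.
#' @param p_in,p_out Intra-layer edge probabilities inside / outside modules
#'   (`0 <= p_out < p_in <= 1`).
#' @param q_bridge,bg_bridge Cross-layer gene-lncRNA edge probability within
#'   a module / in the background (`0 <= bg_bridge < q_bridge <= 1`).  The
#'   background rate also drives sparse background phenotype-gene and
#'   phenotype-lncRNA edges.
#' @param predicted_weight_range Interval within (0, 1\] from which predicted
#'   edge weights are drawn uniformly.
#' @param known_genes_per_disease,known_lncrnas_per_disease Module members
#'   designated as known disease genes / lncRNAs (weight-1 experimental links
#'   from the phenotype).
#' @param shared_module_pairs Optional list of integer pairs of disease
#'   indices that share one module (their phenotypes are then also linked by
#'   a phenotype-phenotype edge).
#' @param n_samples Samples in the companion expression matrix (>= 3).
#' @param target_cor Within-module Pearson correlation the expression
#'   generator aims at, in (0, 1\].
#' @param rng_seed Integer seed; all randomness flows through it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 50, n_phenotypes = 10, n_lncrnas = 40,
                         n_diseases = 5, module_size_genes = 6,
                         module_size_lncrnas = 5, p_in = 0.6, p_out = 0.02,
                         q_bridge = 0.5, bg_bridge = 0.01,
                         predicted_weight_range = c(0.4, 0.9),
                         known_genes_per_disease = 3,
                         known_lncrnas_per_disease = 3,
                         shared_module_pairs = NULL,
                         n_samples = 20, target_cor = 0.8,
                         rng_seed = 42) {
  cfg <- list(
    n_genes = n_genes, n_phenotypes = n_phenotypes, n_lncrnas = n_lncrnas,
    n_diseases = n_diseases, module_size_genes = module_size_genes,
    module_size_lncrnas = module_size_lncrnas, p_in = p_in, p_out = p_out,
    q_bridge = q_bridge, bg_bridge = bg_bridge,
    predicted_weight_range = predicted_weight_range,
    known_genes_per_disease = known_genes_per_disease,
    known_lncrnas_per_disease = known_lncrnas_per_disease,
    shared_module_pairs = shared_module_pairs,
    n_samples = n_samples, target_cor = target_cor,
    rng_seed = as.integer(rng_seed)
  )
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (!(bg_bridge >= 0 && bg_bridge < q_bridge && q_bridge <= 1)) {
    stop("need 0 <= bg_bridge < q_bridge <= 1", call. = FALSE)
  }
  r <- predicted_weight_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 1 || r[1] > r[2]) {
    stop("predicted_weight_range must be an interval within (0, 1]",
         call. = FALSE)
  }
  if (n_diseases > n_phenotypes) {
    stop("more diseases than phenotypes", call. = FALSE)
  }
  plan <- .plan_modules(cfg)
  if (plan$n_modules * module_size_genes > n_genes) {
    stop("gene modules larger than the gene layer", call. = FALSE)
  }
  if (plan$n_modules * module_size_lncrnas > n_lncrnas) {
    stop("lncRNA modules larger than the lncRNA layer", call. = FALSE)
  }
  if (known_genes_per_disease > module_size_genes ||
      known_lncrnas_per_disease > module_size_lncrnas) {
    stop("known members per disease exceed the module size", call. = FALSE)
  }
  if (target_cor <= 0 || target_cor > 1) {
    stop("target_cor must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic network config: ", x$n_genes, " genes, ", x$n_phenotypes,
      " phenotypes, ", x$n_lncrnas, " lncRNAs; ", x$n_diseases,
      " planted diseases (modules ", x$module_size_genes, " genes / ",
      x$module_size_lncrnas, " lncRNAs); seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

# deterministic module plan: disease d -> module index (shared pairs collapse
# to the lower index's module); module m claims a contiguous id block
.plan_modules <- function(cfg) {
  module_of_disease <- seq_len(cfg$n_diseases)
  for (pair in cfg$shared_module_pairs) {
    pair <- sort(as.integer(pair))
    if (any(pair < 1) || any(pair > cfg$n_diseases)) {
      stop("shared_module_pairs indices out of range", call. = FALSE)
    }
    module_of_disease[pair[2]] <- module_of_disease[pair[1]]
  }
  used <- sort(unique(module_of_disease))
  module_of_disease <- match(module_of_disease, used)
  list(module_of_disease = module_of_disease, n_modules = length(used))
}

.synth_ids <- function(cfg) {
  list(
    gene = sprintf("g%03d", seq_len(cfg$n_genes)),
    phenotype = sprintf("p%03d", seq_len(cfg$n_phenotypes)),
    lncrna = sprintf("l%03d", seq_len(cfg$n_lncrnas))
  )
}

# module index (0 = background) per entity of one layer
.module_assignment <- function(n, module_size, n_modules) {
  m <- integer(n)
  for (k in seq_len(n_modules)) {
    m[((k - 1) * module_size + 1):(k * module_size)] <- k
  }
  m
}

# Bernoulli edges over candidate pairs, with uniform predicted weights
.draw_edges <- function(pairs, prob, wrange) {
  if (!nrow(pairs)) {
    return(tibble::tibble(source = character(), target = character(),
                          weight = numeric(), evidence = character()))
  }
  hit <- stats::runif(nrow(pairs)) < prob
  pairs <- pairs[hit, , drop = FALSE]
  tibble::tibble(
    source = pairs$source,
    target = pairs$target,
    weight = stats::runif(nrow(pairs), wrange[1], wrange[2]),
    evidence = "predicted"
  )
}

#' Generate a synthetic composite network with planted disease structure
#'
#' Deterministic given `rng_seed`.  Each planted disease owns one phenotype,
#' a gene module and a lncRNA module: module pairs are joined with
#' probability `p_in` inside the layer and `q_bridge` across the gene-lncRNA
#' bridge (predicted weights drawn from `predicted_weight_range`), while
#' background pairs use `p_out` and `bg_bridge`.  The phenotype is linked by
#' weight-1 experimental edges to its designated known genes and lncRNAs,
#' which form the association catalog; phenotypes sharing a module are
#' linked by a phenotype-phenotype edge.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `network` (a `composite_network`), `catalog`
#'   (an [association_catalog()]) and `truth` (per-disease module membership
#'   and designated known members).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  plan <- .plan_modules(cfg)
  ids <- .synth_ids(cfg)
  gene_mod <- .module_assignment(cfg$n_genes, cfg$module_size_genes,
                                 plan$n_modules)
  lnc_mod <- .module_assignment(cfg$n_lncrnas, cfg$module_size_lncrnas,
                                plan$n_modules)
  wr <- cfg$predicted_weight_range

  withr::with_seed(cfg$rng_seed, {
    intra_pairs <- function(id, mod) {
      idx <- utils::combn(seq_along(id), 2)
      tibble::tibble(
        source = id[idx[1, ]], target = id[idx[2, ]],
        same = mod[idx[1, ]] > 0 & mod[idx[1, ]] == mod[idx[2, ]]
      )
    }
    gg_pairs <- intra_pairs(ids$gene, gene_mod)
    gg <- .draw_edges(gg_pairs,
                      ifelse(gg_pairs$same, cfg$p_in, cfg$p_out), wr)
    ll_pairs <- intra_pairs(ids$lncrna, lnc_mod)
    ll <- .draw_edges(ll_pairs,
                      ifelse(ll_pairs$same, cfg$p_in, cfg$p_out), wr)

    gl_pairs <- tibble::tibble(
      source = rep(ids$gene, times = cfg$n_lncrnas),
      target = rep(ids$lncrna, each = cfg$n_genes),
      same = rep(gene_mod, times = cfg$n_lncrnas) > 0 &
        rep(gene_mod, times = cfg$n_lncrnas) ==
          rep(lnc_mod, each = cfg$n_genes)
    )
    gl <- .draw_edges(gl_pairs,
                      ifelse(gl_pairs$same, cfg$q_bridge, cfg$bg_bridge), wr)

    # planted diseases: phenotype d, known members, experimental links
    truth <- vector("list", cfg$n_diseases)
    gp_known <- list()
    pl_known <- list()
    for (d in seq_len(cfg$n_diseases)) {
      m <- plan$module_of_disease[d]
      mg <- ids$gene[gene_mod == m]
      ml <- ids$lncrna[lnc_mod == m]
      kg <- sort(sample(mg, cfg$known_genes_per_disease))
      kl <- sort(sample(ml, cfg$known_lncrnas_per_disease))
      p <- ids$phenotype[d]
      gp_known[[d]] <- tibble::tibble(source = kg, target = p,
                                      weight = 1, evidence = "experimental")
      pl_known[[d]] <- tibble::tibble(source = p, target = kl,
                                      weight = 1, evidence = "experimental")
      truth[[d]] <- list(
        phenotype_id = p, module = m,
        member_genes = mg, member_lncrnas = ml,
        known_genes = kg, known_lncrnas = kl
      )
    }

    # background cross-layer noise touching the phenotype layer
    gp_bg_pairs <- tibble::tibble(
      source = rep(ids$gene, times = cfg$n_phenotypes),
      target = rep(ids$phenotype, each = cfg$n_genes)
    )
    gp_bg <- .draw_edges(gp_bg_pairs, cfg$bg_bridge, wr)
    pl_bg_pairs <- tibble::tibble(
      source = rep(ids$phenotype, times = cfg$n_lncrnas),
      target = rep(ids$lncrna, each = cfg$n_phenotypes)
    )
    pl_bg <- .draw_edges(pl_bg_pairs, cfg$bg_bridge, wr)

    # phenotypes sharing a module are similar diseases
    pp <- tibble::tibble(source = character(), target = character(),
                         weight = numeric(), evidence = character())
    md <- plan$module_of_disease
    for (d1 in seq_len(cfg$n_diseases)) {
      for (d2 in seq_len(cfg$n_diseases)) {
        if (d1 < d2 && md[d1] == md[d2]) {
          pp <- dplyr::bind_rows(pp, tibble::tibble(
            source = ids$phenotype[d1], target = ids$phenotype[d2],
            weight = stats::runif(1, wr[1], wr[2]), evidence = "predicted"
          ))
        }
      }
    }

    tab <- function(df, block) {
      if (!nrow(df)) NULL else
        merge_edge_evidence(edge_table(df, block))
    }
    tables <- Filter(Negate(is.null), list(
      gene_gene = tab(gg, "gene_gene"),
      lncrna_lncrna = tab(ll, "lncrna_lncrna"),
      phenotype_phenotype = tab(pp, "phenotype_phenotype"),
      gene_lncrna = tab(gl, "gene_lncrna"),
      gene_phenotype = tab(
        dplyr::bind_rows(dplyr::bind_rows(gp_known), gp_bg),
        "gene_phenotype"
      ),
      phenotype_lncrna = tab(
        dplyr::bind_rows(dplyr::bind_rows(pl_known), pl_bg),
        "phenotype_lncrna"
      )
    ))
    net <- build_composite(tables, node_universes = ids)

    catalog <- association_catalog(
      lncrna_associations = dplyr::bind_rows(lapply(truth, function(t) {
        tibble::tibble(phenotype_id = t$phenotype_id,
                       lncrna_id = t$known_lncrnas)
      })),
      gene_associations = dplyr::bind_rows(lapply(truth, function(t) {
        tibble::tibble(phenotype_id = t$phenotype_id,
                       gene_id = t$known_genes)
      }))
    )
    list(network = net, catalog = catalog, truth = truth)
  })
}

#' Generate a companion expression matrix with module-correlated profiles
#'
#' Members of a disease module share a latent per-sample profile plus
#' independent noise calibrated so that within-module Pearson correlations
#' concentrate near `target_cor`; background entities are independent.
#' Values are FPKM-like (non-negative, arbitrary scale).  Deterministic
#' given `rng_seed`.
#'
#' @param cfg A [synth_config()].
#' @return An [expression_matrix()] over all genes and lncRNAs.
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  plan <- .plan_modules(cfg)
  ids <- .synth_ids(cfg)
  gene_mod <- .module_assignment(cfg$n_genes, cfg$module_size_genes,
                                 plan$n_modules)
  lnc_mod <- .module_assignment(cfg$n_lncrnas, cfg$module_size_lncrnas,
                                plan$n_modules)
  entity_ids <- c(ids$gene, ids$lncrna)
  mod <- c(gene_mod, lnc_mod)
  layer <- stats::setNames(
    rep(c("gene", "lncrna"), c(cfg$n_genes, cfg$n_lncrnas)), entity_ids
  )
  noise_sd <- sqrt(1 / cfg$target_cor - 1)

  withr::with_seed(cfg$rng_seed, {
    latent <- matrix(stats::rnorm(plan$n_modules * cfg$n_samples),
                     plan$n_modules, cfg$n_samples)
    baseline <- stats::runif(length(entity_ids), 6, 12)
    values <- matrix(0, length(entity_ids), cfg$n_samples,
                     dimnames = list(entity_ids,
                                     sprintf("s%03d", seq_len(cfg$n_samples))))
    for (i in seq_along(entity_ids)) {
      shared <- if (mod[i] > 0) latent[mod[i], ] else
        stats::rnorm(cfg$n_samples)
      eps <- if (noise_sd > 0) stats::rnorm(cfg$n_samples, sd = noise_sd)
        else 0
      values[i, ] <- baseline[i] + shared + eps
    }
    # baselines sit far above zero, so truncation is a formality
    values <- pmax(values, 0)
    expression_matrix(values, layer)
  })
}

#' Serialize a synthetic benchmark to a directory
#'
#' Writes the network (via [write_network()]), the association catalog TSV
#' and a ground-truth JSON.
#'
#' @param sim Result of [generate_network()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(sim$network, file.path(dir, "network"))
  la <- sim$catalog$lncrna_associations
  ga <- sim$catalog$gene_associations
  lines <- c(
    "# phenotype\tpartner\ttype",
    sprintf("%s\t%s\tlncrna", la$phenotype_id, la$lncrna_id),
    sprintf("%s\t%s\tgene", ga$phenotype_id, ga$gene_id)
  )
  writeLines(lines, file.path(dir, "associations.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
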