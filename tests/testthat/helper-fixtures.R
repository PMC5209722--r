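# Shared fixtures -------------------------------------------------------------

# the worked four-node network: genes g1,g2; phenotype p1; lncRNA l1
t1_network <- function() {
  build_composite(list(
    gene_gene = edge_table(
      data.frame(source = "g1", target = "g2", weight = 1), "gene_gene"),
    gene_phenotype = edge_table(
      data.frame(source = "g1", target = "p1", weight = 1),
      "gene_phenotype"),
    gene_lncrna = edge_table(
      data.frame(source = "g2", target = "l1", weight = 0.5),
      "gene_lncrna"),
    phenotype_lncrna = edge_table(
      data.frame(source = "p1", target = "l1", weight = 1),
      "phenotype_lncrna")
  ))
}

prob_vec <- function(x) {
  structure(x, class = "probability_vector")
}

# random composite network built directly from random blocks (independent of
# the synthetic-fixtures generator); may contain isolated nodes and empty
# blocks
random_network <- function(seed, max_per_layer = 10, density = 0.3) {
  withr::with_seed(seed, {
    ng <- sample(0:max_per_layer, 1)
    np <- sample(0:max_per_layer, 1)
    nl <- sample(1:max_per_layer, 1)
    ids <- list(
      gene = if (ng) sprintf("g%02d", seq_len(ng)) else character(),
      phenotype = if (np) sprintf("p%02d", seq_len(np)) else character(),
      lncrna = sprintf("l%02d", seq_len(nl))
    )
    rand_tab <- function(a, b, block) {
      if (!length(a) || !length(b)) return(NULL)
      intra <- identical(a, b)
      pairs <- expand.grid(source = a, target = b,
                           stringsAsFactors = FALSE)
      if (intra) pairs <- pairs[pairs$source < pairs$target, ]
      pairs <- pairs[runif(nrow(pairs)) < density, , drop = FALSE]
      if (!nrow(pairs)) return(NULL)
      pairs$weight <- runif(nrow(pairs), 0.1, 1)
      edge_table(pairs, block)
    }
    tables <- Filter(Negate(is.null), list(
      gene_gene = rand_tab(ids$gene, ids$gene, "gene_gene"),
      phenotype_phenotype = rand_tab(ids$phenotype, ids$phenotype,
                                     "phenotype_phenotype"),
      lncrna_lncrna = rand_tab(ids$lncrna, ids$lncrna, "lncrna_lncrna"),
      gene_phenotype = rand_tab(ids$gene, ids$phenotype, "gene_phenotype"),
      gene_lncrna = rand_tab(ids$gene, ids$lncrna, "gene_lncrna"),
      phenotype_lncrna = rand_tab(ids$phenotype, ids$lncrna,
                                  "phenotype_lncrna")
    ))
    build_composite(tables, node_universes = ids)
  })
}

# random probability vector over a network's nodes
random_p0 <- function(net, seed) {
  withr::with_seed(seed, {
    ids <- node_order(net)
    v <- runif(length(ids))
    prob_vec(stats::setNames(v / sum(v), ids))
  })
}
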