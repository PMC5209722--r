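# Independent oracles ---------------------------------------------------------

# Naive per-row transition construction: for every node, enumerate the
# present blocks explicitly, allocate jump mass, and rescale.  Written as
# scalar case analysis, deliberately sharing no code with build_transition().
naive_transition <- function(net, x = 1 / 3, y = 1 / 3, z = 1 / 3) {
  ids <- c(net$gene_ids, net$phenotype_ids, net$lncrna_ids)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  layer_of <- function(id) {
    if (id %in% net$gene_ids) "gene"
    else if (id %in% net$phenotype_ids) "phenotype"
    else "lncrna"
  }
  # weight from node i to node j looked up in whichever stored block holds it
  w_between <- function(i, j) {
    li <- layer_of(i); lj <- layer_of(j)
    key <- paste(sort(c(li, lj)), collapse = "-")
    switch(key,
      "gene-gene" = net$W_G[i, j],
      "phenotype-phenotype" = net$W_P[i, j],
      "lncrna-lncrna" = net$W_L[i, j],
      "gene-phenotype" = if (li == "gene") net$W_GP[i, j] else
        net$W_GP[j, i],
      "gene-lncrna" = if (li == "gene") net$W_GL[i, j] else net$W_GL[j, i],
      "lncrna-phenotype" = if (li == "phenotype") net$W_PL[i, j] else
        net$W_PL[j, i]
    )
  }
  jump_of <- function(la, lb) {
    key <- paste(sort(c(la, lb)), collapse = "-")
    switch(key,
      "gene-phenotype" = x,
      "gene-lncrna" = y,
      "lncrna-phenotype" = z
    )
  }
  for (i in ids) {
    li <- layer_of(i)
    others <- setdiff(c("gene", "phenotype", "lncrna"), li)
    per_layer_ids <- list(
      gene = net$gene_ids, phenotype = net$phenotype_ids,
      lncrna = net$lncrna_ids
    )
    sums <- sapply(c(li, others), function(lay) {
      s <- 0
      for (j in per_layer_ids[[lay]]) if (j != i) s <- s + w_between(i, j)
      s
    })
    jump_used <- 0
    for (lb in others) {
      if (sums[[lb]] > 0) {
        jb <- jump_of(li, lb)
        jump_used <- jump_used + jb
        for (j in per_layer_ids[[lb]]) {
          M[i, j] <- jb * w_between(i, j) / sums[[lb]]
        }
      }
    }
    if (sums[[li]] > 0) {
      for (j in per_layer_ids[[li]]) {
        if (j != i) M[i, j] <- (1 - jump_used) * w_between(i, j) / sums[[li]]
      }
    }
    tot <- sum(M[i, ])
    if (tot > 0 && abs(tot - 1) > 1e-15) M[i, ] <- M[i, ] / tot
  }
  M
}

# Brute-force pairwise Mann-Whitney AUC over pooled percentile positions:
# each fold contributes its positive at (r-1)/(n-1) and its negatives on the
# remaining grid slots; ties count half.
pairwise_auc <- function(positives, n_negatives_per_fold) {
  n_neg <- rep_len(n_negatives_per_fold, length(positives))
  negs <- numeric()
  for (i in seq_along(positives)) {
    grid <- seq(0, 1, length.out = n_neg[i] + 1)
    slot <- which.min(abs(grid - positives[i]))
    negs <- c(negs, grid[-slot])
  }
  total <- 0
  for (p in positives) {
    for (q in negs) {
      total <- total + (p < q) + 0.5 * (p == q)
    }
  }
  total / (length(positives) * length(negs))
}
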