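# Seed vectors, propagation, the closed-form oracle and ranking

test_that("seed vectors mix layers by alpha, beta, 1-alpha-beta", {
  net <- t1_network()
  p0 <- build_seed_vector(
    seed_set(phenotypes = "p1", genes = c("g1", "g2"), lncrnas = "l1"),
    net, alpha = 1 / 3, beta = 1 / 3
  )
  expect_equal(unclass(p0),
               c(g1 = 1 / 6, g2 = 1 / 6, p1 = 1 / 3, l1 = 1 / 3))
  expect_equal(sum(p0), 1)
})

test_that("an empty seed layer redistributes its weight proportionally", {
  net <- t1_network()
  p0 <- build_seed_vector(seed_set(phenotypes = "p1", genes = "g1"), net)
  expect_equal(unclass(p0), c(g1 = 0.5, g2 = 0, p1 = 0.5, l1 = 0))
})

test_that("unknown seeds warn and all-unknown seeds fail", {
  net <- t1_network()
  expect_warning(
    p0 <- build_seed_vector(seed_set(phenotypes = "p1", genes = "gX"), net),
    "gX"
  )
  expect_equal(unname(p0["p1"]), 1)
  expect_error(
    suppressWarnings(build_seed_vector(seed_set(genes = "gX"), net)),
    "no seed"
  )
  expect_error(build_seed_vector(seed_set(), net), "no seed")
})

test_that("the two-gene walk hits its closed-form fixed point", {
  gg <- edge_table(data.frame(source = "a", target = "b"), "gene_gene")
  net <- build_composite(list(gene_gene = gg))
  m <- build_transition(net)
  p0 <- prob_vec(c(a = 1, b = 0))
  st <- propagate(m, p0, delta = 0.7)
  expect_equal(unname(st$scores), c(10 / 13, 3 / 13), tolerance = 1e-10)
  cf <- closed_form_stationary(m, p0, delta = 0.7)
  expect_equal(unname(cf$scores), c(10 / 13, 3 / 13), tolerance = 1e-12)
})

test_that("delta = 1 returns the seed vector after one iteration", {
  net <- t1_network()
  m <- build_transition(net)
  p0 <- build_seed_vector(seed_set(phenotypes = "p1"), net)
  st <- propagate(m, p0, delta = 1)
  expect_identical(st$iterations, 1L)
  expect_equal(st$scores, unclass(p0)[node_order(net)])
  cf <- closed_form_stationary(m, p0, delta = 1)
  expect_equal(cf$scores, unclass(p0)[node_order(net)])
})

test_that("a symmetric cycle with uniform seeds stays uniform", {
  gg <- edge_table(data.frame(
    source = c("a", "b", "c", "a"), target = c("b", "c", "d", "d")
  ), "gene_gene")
  net <- build_composite(list(gene_gene = gg))
  m <- build_transition(net)
  p0 <- prob_vec(c(a = .25, b = .25, c = .25, d = .25))
  st <- propagate(m, p0, delta = 0.7)
  expect_equal(unname(st$scores), rep(0.25, 4))
})

test_that("propagation matches the closed form on random fixtures", {
  for (seed in 1:8) {
    net <- random_network(seed + 50, max_per_layer = 15)
    m <- build_transition(net)
    p0 <- random_p0(net, seed)
    delta <- withr::with_seed(seed, runif(1, 0.3, 0.9))
    st <- propagate(m, p0, delta = delta)
    cf <- closed_form_stationary(m, p0, delta = delta)
    expect_lt(sum(abs(st$scores - cf$scores)), 1e-8)
  }
})

test_that("scores are conserved when no node is dangling", {
  gg <- edge_table(data.frame(
    source = c("a", "b", "c"), target = c("b", "c", "a")
  ), "gene_gene")
  net <- build_composite(list(gene_gene = gg))
  m <- build_transition(net)
  st <- propagate(m, prob_vec(c(a = 1, b = 0, c = 0)), delta = 0.5)
  expect_equal(sum(st$scores), 1, tolerance = 1e-9)
})

test_that("direct neighbours of the seed outrank second neighbours", {
  # path seed - a - b with unit weights
  ll <- edge_table(data.frame(
    source = c("seed", "la"), target = c("la", "lb")
  ), "lncrna_lncrna")
  net <- build_composite(list(lncrna_lncrna = ll))
  m <- build_transition(net)
  p0 <- build_seed_vector(seed_set(lncrnas = "seed"), net,
                          alpha = 0, beta = 0)
  for (delta in c(0.1, 0.5, 0.9)) {
    st <- propagate(m, p0, delta = delta)
    expect_gt(st$scores["la"], st$scores["lb"])
  }
})

test_that("scores approach the seed vector as delta approaches 1", {
  net <- random_network(77, max_per_layer = 10)
  m <- build_transition(net)
  p0 <- random_p0(net, 77)
  d1 <- sum(abs(propagate(m, p0, delta = 0.99)$scores - unclass(p0)))
  d2 <- sum(abs(propagate(m, p0, delta = 0.999)$scores - unclass(p0)))
  expect_lt(d2, d1)
})

test_that("relabeling nodes permutes scores exactly", {
  net <- random_network(31, max_per_layer = 8)
  m <- build_transition(net)
  p0 <- random_p0(net, 31)
  st <- propagate(m, p0, delta = 0.7)
  # rename every node with a prefix that reverses lexicographic order
  relabel <- stats::setNames(
    paste0("z", rev(seq_along(node_order(net))), "_", node_order(net)),
    node_order(net)
  )
  rename_tab <- function(tab) {
    tab$source <- unname(relabel[tab$source])
    tab$target <- unname(relabel[tab$target])
    tab
  }
  long <- tidy(net)
  tables <- lapply(split(long, long$block), function(df) {
    edge_table(rename_tab(df[, -1]), df$block[1])
  })
  uni <- list(
    gene = unname(relabel[net$gene_ids]),
    phenotype = unname(relabel[net$phenotype_ids]),
    lncrna = unname(relabel[net$lncrna_ids])
  )
  net2 <- build_composite(tables, node_universes = uni)
  m2 <- build_transition(net2)
  p02 <- unclass(p0)
  names(p02) <- unname(relabel[names(p02)])
  st2 <- propagate(m2, prob_vec(p02), delta = 0.7)
  expect_equal(unname(st2$scores[unname(relabel[node_order(net)])]),
               unname(st$scores[node_order(net)]))
})

test_that("the dense oracle refuses oversized networks", {
  fake <- structure(list(node_order = sprintf("n%d", 1:2001), M = NULL),
                    class = "transition_model")
  expect_error(closed_form_stationary(fake, NULL), "2000")
})

test_that("non-convergence within the iteration cap is an error", {
  gg <- edge_table(data.frame(source = "a", target = "b"), "gene_gene")
  net <- build_composite(list(gene_gene = gg))
  m <- build_transition(net)
  expect_error(
    propagate(m, prob_vec(c(a = 1, b = 0)), delta = 0.1, tol = 1e-16,
              max_iter = 3),
    "did not converge"
  )
})

test_that("candidates are ranked by score with lexicographic tie-break", {
  st <- structure(list(
    scores = c(l1 = 0.3, l2 = 0.1, l3 = 0.1, l4 = 0),
    layers = c(l1 = "lncrna", l2 = "lncrna", l3 = "lncrna", l4 = "lncrna"),
    iterations = 1L, residual = 0, delta = 0.7
  ), class = "stationary_distribution")
  r <- rank_candidates(st, c("l4", "l3", "l2", "l1"))
  expect_equal(r$lncrna_id, c("l1", "l2", "l3", "l4"))
  expect_equal(r$rank, 1:4)
  expect_warning(r2 <- rank_candidates(st, c("l1", "bogus")), "bogus")
  expect_equal(nrow(r2), 1)
  expect_error(suppressWarnings(rank_candidates(st, "bogus")), "empty")
})

test_that("an isolated candidate scores zero and ranks last", {
  pl <- edge_table(data.frame(source = "p1", target = "l1"),
                   "phenotype_lncrna")
  net <- build_composite(list(phenotype_lncrna = pl),
                         node_universes = list(lncrna = c("l1", "l9")))
  r <- rank_lncrnas(net, seed_set(phenotypes = "p1"))
  expect_equal(r$lncrna_id[nrow(r)], "l9")
  expect_equal(r$score[nrow(r)], 0)
})
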