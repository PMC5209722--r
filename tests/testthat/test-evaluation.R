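# ROC/AUC, LOOCV, ablation, sweeps, landscape and hotspots

test_that("single-positive ROCs hit the perfect and worst corners", {
  roc1 <- roc_points(0, n_negatives_per_fold = 4)
  expect_equal(roc1$fpr[1:2], c(0, 0))
  expect_equal(roc1$tpr[2], 1)
  expect_equal(auc_trapezoid(roc1), 1)
  roc0 <- roc_points(1, n_negatives_per_fold = 4)
  expect_equal(auc_trapezoid(roc0), 0)
})

test_that("uniformly spread positives give AUC one half", {
  roc <- roc_points(c(0.25, 0.5, 0.75), n_negatives_per_fold = 4)
  expect_equal(auc_trapezoid(roc), 0.5)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  for (seed in 1:5) {
    pos <- withr::with_seed(seed, {
      n <- sample(3:12, 1)
      sizes <- sample(4:30, n, replace = TRUE)
      r <- vapply(sizes, function(s) sample(s, 1), integer(1))
      list(p = (r - 1) / sizes, n_neg = sizes)
    })
    roc <- roc_points(pos$p, pos$n_neg)
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(utils::tail(roc$fpr, 1), 1)
    expect_equal(utils::tail(roc$tpr, 1), 1)
    expect_false(is.unsorted(roc$fpr))
    expect_false(is.unsorted(roc$tpr))
  }
})

test_that("trapezoidal AUC equals brute-force pairwise Mann-Whitney", {
  for (seed in 1:10) {
    case <- withr::with_seed(seed, {
      n <- sample(2:20, 1)
      sizes <- sample(3:40, n, replace = TRUE)
      r <- vapply(sizes + 1, function(s) sample(s, 1), integer(1))
      list(p = (r - 1) / sizes, n_neg = sizes)
    })
    got <- auc_trapezoid(roc_points(case$p, case$n_neg))
    want <- pairwise_auc(case$p, case$n_neg)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a held-out rank 3 of 5 candidates scores percentile one half", {
  # single-fold bookkeeping: percentile (r-1)/(n-1), fold AUC (n-r)/(n-1)
  roc <- roc_points((3 - 1) / (5 - 1), n_negatives_per_fold = 4)
  expect_equal(auc_trapezoid(roc), (5 - 3) / (5 - 1))
})

test_that("an oracle ranking the positive first in every fold has AUC 1", {
  roc <- roc_points(rep(0, 10), n_negatives_per_fold = 20)
  expect_equal(auc_trapezoid(roc), 1)
})

test_that("top-k recall counts folds within fractional and absolute cutoffs", {
  cv <- structure(list(folds = tibble::tibble(
    rank = c(1, 5, 200), n_candidates = 1000
  )), class = "lnc_cv")
  expect_equal(topk_recall(cv, fraction = 0.10), 2 / 3)
  expect_equal(topk_recall(cv, fraction = 1), 1)
  expect_equal(topk_recall(cv, k = 1), 1 / 3)
  cv2 <- structure(list(folds = tibble::tibble(
    rank = c(1, 1), n_candidates = 10
  )), class = "lnc_cv")
  expect_equal(topk_recall(cv2, k = 1), 1)
  expect_error(topk_recall(cv, fraction = 0.1, k = 2), "exactly one")
})

sim <- generate_network(synth_config())

test_that("LOOCV recovers planted associations on the default fixture", {
  cv <- loocv(sim$network, sim$catalog)
  expect_s3_class(cv, "lnc_cv")
  expect_equal(nrow(cv$folds), nrow(sim$catalog$lncrna_associations))
  expect_true(all(cv$folds$rank >= 1 &
                    cv$folds$rank <= cv$folds$n_candidates))
  expect_gte(cv$auc, 0.9)
  expect_lte(mean(cv$folds$percentile), 0.1)
  # seed lncRNAs are excluded from candidacy: 40 lncRNAs, 2 remaining seeds
  expect_true(all(cv$folds$n_candidates == 38))
})

test_that("LOOCV is deterministic", {
  a <- loocv(sim$network, sim$catalog)
  b <- loocv(generate_network(synth_config())$network, sim$catalog)
  expect_identical(a, b)
})

test_that("per-class AUC tables follow the phenotype class map", {
  classes <- tibble::tibble(
    phenotype_id = sprintf("p%03d", 1:5),
    class = c("cancer", "cancer", "metabolic", "metabolic", "cardio")
  )
  cat2 <- association_catalog(sim$catalog$lncrna_associations,
                              sim$catalog$gene_associations, classes)
  cv <- loocv(sim$network, cat2)
  expect_equal(sort(cv$class_auc$class),
               c("cancer", "cardio", "metabolic"))
  expect_true(all(cv$class_auc$auc >= 0 & cv$class_auc$auc <= 1))
  expect_equal(sum(cv$class_auc$n_folds), nrow(cv$folds))
})

test_that("the gene layer carries signal the ablation cannot see", {
  full <- loocv(sim$network, sim$catalog, scenario = "no_known_lncrnas")
  abl <- loocv(sim$network, sim$catalog, scenario = "no_known_lncrnas",
               keep_layers = c("phenotype", "lncrna"))
  expect_gt(full$auc, abl$auc)
  expect_gte(full$auc, 0.8)
})

test_that("a singleton sweep reproduces a direct LOOCV call", {
  sw <- parameter_sweep(sim$network, sim$catalog,
                        grid = data.frame(delta = 0.7))
  direct <- loocv(sim$network, sim$catalog, delta = 0.7)
  expect_equal(sw$auc, direct$auc)
  expect_equal(sw$n_folds, nrow(direct$folds))
})

test_that("invalid sweep points are skipped with a reason", {
  sw <- parameter_sweep(sim$network, sim$catalog,
                        grid = data.frame(x = c(1 / 3, 0.8),
                                          y = c(1 / 3, 0.8)))
  expect_true(is.na(sw$auc[2]))
  expect_match(sw$note[2], "pairwise sum")
  expect_false(is.na(sw$auc[1]))
  expect_error(parameter_sweep(sim$network, sim$catalog,
                               grid = data.frame()), "empty")
})

test_that("restart-probability sweeps stay accurate on the planted fixture", {
  sw <- parameter_sweep(sim$network, sim$catalog,
                        grid = data.frame(delta = c(0.5, 0.7, 0.9)))
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$auc >= 0.85))
})

test_that("the landscape row of a phenotype matches its direct ranking", {
  ls <- score_landscape(sim$network, sim$catalog)
  expect_equal(dim(ls$scores),
               c(5, length(sim$network$lncrna_ids)))
  expect_true(all(ls$scores >= 0))
  p <- "p001"
  known_l <- sim$catalog$lncrna_associations$lncrna_id[
    sim$catalog$lncrna_associations$phenotype_id == p]
  known_g <- sim$catalog$gene_associations$gene_id[
    sim$catalog$gene_associations$phenotype_id == p]
  direct <- rank_lncrnas(sim$network, seed_set(p, known_g, known_l),
                         candidates = sim$network$lncrna_ids)
  # same scores, same order, for the non-seed candidates
  row <- ls$scores[p, ]
  cand <- setdiff(sim$network$lncrna_ids, known_l)
  ord <- order(-row[cand], cand)
  expect_equal(cand[ord], direct$lncrna_id)
  expect_equal(unname(row[direct$lncrna_id]), direct$score)
})

test_that("phenotypes sharing a module score more similarly than strangers", {
  shared <- generate_network(synth_config(shared_module_pairs = list(c(1, 2))))
  ls <- score_landscape(shared$network, shared$catalog)
  cor_pair <- function(i, j) {
    stats::cor(ls$scores[i, ], ls$scores[j, ], method = "spearman")
  }
  expect_gt(cor_pair("p001", "p002"), cor_pair("p001", "p003"))
  expect_gt(cor_pair("p001", "p002"), cor_pair("p001", "p004"))
})

test_that("hotspot counts follow the rank cutoffs and are monotone in k", {
  S <- rbind(
    p1 = c(l1 = 0.9, l2 = 0.1, l3 = 0.05, l4 = 0, l5 = 0),
    p2 = c(l1 = 0.8, l2 = 0.7, l3 = 0, l4 = 0.1, l5 = 0),
    p3 = c(l1 = 0.1, l2 = 0.9, l3 = 0.2, l4 = 0, l5 = 0)
  )
  ls <- structure(list(scores = S, phenotype_ids = rownames(S),
                       lncrna_ids = colnames(S)), class = "lnc_landscape")
  hc <- hotspot_counts(ls, cutoffs = c(1, 2, 5))
  at <- function(l, k) hc$n_phenotypes[hc$lncrna_id == l & hc$cutoff == k]
  expect_equal(at("l1", 1), 2)
  expect_equal(at("l2", 1), 1)
  # k covering every lncRNA saturates at the phenotype count
  expect_true(all(hc$n_phenotypes[hc$cutoff == 5] == 3))
  wide <- tidyr::pivot_wider(hc, names_from = "cutoff",
                             values_from = "n_phenotypes")
  expect_true(all(wide$`1` <= wide$`2` & wide$`2` <= wide$`5`))
  expect_error(hotspot_counts(ls, cutoffs = 0), "positive")
})

test_that("cv tidiers expose folds and a one-row summary", {
  cv <- loocv(sim$network, sim$catalog)
  expect_identical(tidy(cv), cv$folds)
  g <- glance(cv)
  expect_equal(g$auc, cv$auc)
  expect_equal(g$n_phenotypes, 5)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
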