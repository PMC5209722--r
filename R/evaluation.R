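# LOOCV, ROC/AUC, ablations, sweeps, landscape -------------------------------

#' Catalog of known disease associations
#'
#' Collects the known phenotype-lncRNA and phenotype-gene associations used
#' for seeding and cross-validation, plus an optional phenotype-to-class map
#' for per-disease-class evaluation.  Duplicate records are collapsed.
#'
#' @param lncrna_associations Data frame with columns `phenotype_id`,
#'   `lncrna_id`.
#' @param gene_associations Optional data frame with columns `phenotype_id`,
#'   `gene_id`.
#' @param classes Optional data frame with columns `phenotype_id`, `class`.
#' @return An object of class `association_catalog`.
#' @export
association_catalog <- function(lncrna_associations,
                                gene_associations = NULL,
                                classes = NULL) {
  la <- tibble::as_tibble(lncrna_associations)
  stopifnot(all(c("phenotype_id", "lncrna_id") %in% names(la)))
  la <- dplyr::distinct(la, phenotype_id = as.character(.data$phenotype_id),
                        lncrna_id = as.character(.data$lncrna_id))
  if (is.null(gene_associations)) {
    ga <- tibble::tibble(phenotype_id = character(), gene_id = character())
  } else {
    ga <- tibble::as_tibble(gene_associations)
    stopifnot(all(c("phenotype_id", "gene_id") %in% names(ga)))
    ga <- dplyr::distinct(ga, phenotype_id = as.character(.data$phenotype_id),
                          gene_id = as.character(.data$gene_id))
  }
  if (!is.null(classes)) {
    classes <- tibble::as_tibble(classes)
    stopifnot(all(c("phenotype_id", "class") %in% names(classes)))
    classes <- dplyr::distinct(
      classes, phenotype_id = as.character(.data$phenotype_id),
      class = as.character(.data$class)
    )
  }
  structure(
    list(lncrna_associations = la, gene_associations = ga,
         classes = classes),
    class = "association_catalog"
  )
}

#' @export
print.association_catalog <- function(x, ...) {
  cat("Association catalog: ", nrow(x$lncrna_associations),
      " phenotype-lncRNA, ", nrow(x$gene_associations),
      " phenotype-gene associations over ",
      length(unique(c(x$lncrna_associations$phenotype_id,
                      x$gene_associations$phenotype_id))),
      " phenotypes\n", sep = "")
  invisible(x)
}

#' Read an association catalog from a TSV file
#'
#' Three-column TSV (no header, `#` comments allowed):
#' `phenotype<TAB>partner<TAB>type` with type `gene` or `lncrna`.
#'
#' @param path Association TSV.
#' @param classes_path Optional two-column TSV `phenotype<TAB>class`.
#' @return An [association_catalog()].
#' @export
read_association_catalog <- function(path, classes_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("association rows must be 'phenotype<TAB>partner<TAB>type'",
         call. = FALSE)
  }
  phen <- vapply(parts, `[`, character(1), 1)
  partner <- vapply(parts, `[`, character(1), 2)
  type <- vapply(parts, `[`, character(1), 3)
  if (!all(type %in% c("gene", "lncrna"))) {
    stop("association types must be gene or lncrna", call. = FALSE)
  }
  classes <- NULL
  if (!is.null(classes_path)) {
    cl <- readr::read_tsv(classes_path, col_names = c("phenotype_id", "class"),
                          comment = "#", show_col_types = FALSE)
    classes <- cl
  }
  association_catalog(
    lncrna_associations = tibble::tibble(
      phenotype_id = phen[type == "lncrna"],
      lncrna_id = partner[type == "lncrna"]
    ),
    gene_associations = tibble::tibble(
      phenotype_id = phen[type == "gene"],
      gene_id = partner[type == "gene"]
    ),
    classes = classes
  )
}

# ROC machinery ---------------------------------------------------------------

#' Pooled ROC curve from held-out rank percentiles
#'
#' Folds have different candidate counts, so positives are placed on a
#' common \[0, 1\] percentile axis: a held-out lncRNA ranked `r` of `n`
#' candidates sits at percentile `(r - 1) / (n - 1)`, and the fold's `n - 1`
#' negatives occupy the remaining grid positions `(j - 1) / (n - 1)`.  The
#' pooled stepwise ROC sweeps a threshold over these positions (smaller is
#' better); it starts at (0, 0), ends at (1, 1), and its trapezoidal area
#' equals the pairwise Mann-Whitney statistic of positives versus negatives
#' (ties counted half).
#'
#' @param positives Numeric vector of held-out percentiles in \[0, 1\], one
#'   per fold.
#' @param n_negatives_per_fold Integer vector (recycled) of the number of
#'   negatives in each fold.
#' @return A tibble with columns `fpr`, `tpr`.
#' @export
roc_points <- function(positives, n_negatives_per_fold) {
  if (!length(positives)) stop("no positives supplied", call. = FALSE)
  if (any(positives < 0 | positives > 1)) {
    stop("percentiles must lie in [0, 1]", call. = FALSE)
  }
  n_neg <- rep_len(as.integer(n_negatives_per_fold), length(positives))
  if (any(n_neg < 1)) stop("each fold needs at least one negative",
                           call. = FALSE)
  pos <- positives
  neg <- unlist(lapply(seq_along(pos), function(i) {
    grid <- seq(0, 1, length.out = n_neg[i] + 1L)
    # the positive occupies one grid slot; negatives fill the rest
    d <- abs(grid - pos[i])
    grid[-which.min(d)]
  }), use.names = FALSE)

  positions <- c(pos, neg)
  is_pos <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  thresholds <- sort(unique(positions))
  tpr <- c(0, vapply(thresholds, function(t) mean(pos <= t), numeric(1)))
  fpr <- c(0, vapply(thresholds, function(t) mean(neg <= t), numeric(1)))
  out <- tibble::tibble(fpr = fpr, tpr = tpr)
  if (utils::tail(out$fpr, 1) < 1 || utils::tail(out$tpr, 1) < 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(fpr = 1, tpr = 1))
  }
  dplyr::distinct(out)
}

#' Area under a ROC curve
#'
#' Trapezoidal area of a stepwise ROC; equals the Mann-Whitney statistic of
#' positives versus negatives.
#'
#' @param roc A tibble of `fpr`, `tpr` points as from [roc_points()].
#' @return The AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  f <- roc$fpr
  t <- roc$tpr
  if (is.unsorted(f) || is.unsorted(t)) {
    stop("ROC points must be monotone nondecreasing", call. = FALSE)
  }
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

# LOOCV ------------------------------------------------------------------------

#' Leave-one-out cross-validation over known phenotype-lncRNA associations
#'
#' For each known association of an eligible phenotype (one with at least
#' `min_known_lncrnas` known lncRNAs), the link between the held-out lncRNA
#' and the phenotype is removed from W_PL, the walk is seeded with the
#' phenotype, its remaining known lncRNAs and all of its known genes, and
#' the rank of the held-out lncRNA among all non-seed lncRNAs is recorded.
#' Under `scenario = "no_known_lncrnas"` all of the phenotype's known lncRNA
#' links are removed and the walk is seeded by the phenotype and its genes
#' only, emulating a disease without any known lncRNA.  `keep_layers`
#' restricts the walk to a subset of layers for ablation baselines.
#'
#' @param net A `composite_network`.
#' @param catalog An [association_catalog()].
#' @param delta,x,y,z,alpha,beta Walk parameters (defaults 0.7 and 1/3).
#' @param min_known_lncrnas Minimum known lncRNAs per eligible phenotype
#'   (default 2).
#' @param scenario `"full"` (default) or `"no_known_lncrnas"`.
#' @param keep_layers Layers kept in the walk; default all three.
#' @param tol,max_iter Convergence controls.
#' @return An object of class `lnc_cv` with per-fold records, the pooled ROC
#'   and AUC, and a per-class AUC table when the catalog carries classes.
#' @export
loocv <- function(net, catalog, delta = 0.7, x = 1 / 3, y = 1 / 3,
                  z = 1 / 3, alpha = 1 / 3, beta = 1 / 3,
                  min_known_lncrnas = 2,
                  scenario = c("full", "no_known_lncrnas"),
                  keep_layers = c("gene", "phenotype", "lncrna"),
                  tol = 1e-10, max_iter = 10000) {
  validate_composite_network(net)
  stopifnot(inherits(catalog, "association_catalog"))
  scenario <- match.arg(scenario)
  keep_layers <- match.arg(keep_layers, .layers, several.ok = TRUE)

  la <- catalog$lncrna_associations
  la <- la[la$phenotype_id %in% net$phenotype_ids &
             la$lncrna_id %in% net$lncrna_ids, ]
  if (nrow(la) < nrow(catalog$lncrna_associations)) {
    warning("dropped ", nrow(catalog$lncrna_associations) - nrow(la),
            " association(s) with ids not in the network", call. = FALSE)
  }
  if (!nrow(la)) stop("no resolvable associations in the catalog",
                      call. = FALSE)
  ga <- catalog$gene_associations
  ga <- ga[ga$phenotype_id %in% net$phenotype_ids &
             ga$gene_id %in% net$gene_ids, ]

  counts <- dplyr::count(la, .data$phenotype_id)
  eligible <- counts$phenotype_id[counts$n >= min_known_lncrnas]
  folds_in <- la[la$phenotype_id %in% eligible, ]
  if (!nrow(folds_in)) {
    stop("no phenotype has at least ", min_known_lncrnas,
         " known lncRNAs", call. = FALSE)
  }

  ablate <- !setequal(keep_layers, .layers)
  fold_rows <- vector("list", nrow(folds_in))
  for (i in seq_len(nrow(folds_in))) {
    p <- folds_in$phenotype_id[i]
    l <- folds_in$lncrna_id[i]
    known_l <- la$lncrna_id[la$phenotype_id == p]
    known_g <- ga$gene_id[ga$phenotype_id == p]

    net_f <- net
    if (scenario == "full") {
      net_f$W_PL[p, l] <- 0
      seed_l <- setdiff(known_l, l)
    } else {
      net_f$W_PL[p, known_l] <- 0
      seed_l <- character()
    }
    if (ablate) net_f <- restrict_layers(net_f, keep_layers)

    sp <- intersect(p, net_f$phenotype_ids)
    sg <- intersect(known_g, net_f$gene_ids)
    sl <- intersect(seed_l, net_f$lncrna_ids)
    if (!length(sp) && !length(sg) && !length(sl)) {
      warning("fold (", p, ", ", l, ") skipped: no seeds remain",
              call. = FALSE)
      next
    }

    model <- build_transition(net_f, x = x, y = y, z = z)
    p0 <- build_seed_vector(seed_set(sp, sg, sl), net_f,
                            alpha = alpha, beta = beta)
    stat <- propagate(model, p0, delta = delta, tol = tol,
                      max_iter = max_iter)
    candidates <- setdiff(net_f$lncrna_ids, sl)
    ranked <- rank_candidates(stat, candidates)
    r <- ranked$rank[ranked$lncrna_id == l]
    n_cand <- nrow(ranked)
    fold_rows[[i]] <- tibble::tibble(
      phenotype_id = p, held_out_lncrna = l, rank = r,
      n_candidates = n_cand,
      percentile = if (n_cand > 1) (r - 1) / (n_cand - 1) else 0
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  if (!nrow(folds)) stop("every fold was skipped", call. = FALSE)

  roc <- roc_points(folds$percentile, folds$n_candidates - 1L)
  auc <- auc_trapezoid(roc)

  class_auc <- NULL
  if (!is.null(catalog$classes)) {
    joined <- dplyr::inner_join(folds, catalog$classes, by = "phenotype_id")
    class_auc <- joined |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        n_folds = dplyr::n(),
        auc = auc_trapezoid(roc_points(.data$percentile,
                                       .data$n_candidates - 1L)),
        .groups = "drop"
      )
  }

  structure(
    list(
      folds = folds, roc = roc, auc = auc, class_auc = class_auc,
      scenario = scenario, keep_layers = keep_layers,
      params = list(delta = delta, x = x, y = y, z = z,
                    alpha = alpha, beta = beta,
                    min_known_lncrnas = min_known_lncrnas)
    ),
    class = "lnc_cv"
  )
}

#' @export
print.lnc_cv <- function(x, ...) {
  cat("LOOCV (", x$scenario, ", layers: ",
      paste(x$keep_layers, collapse = "+"), "): ", nrow(x$folds),
      " folds over ", length(unique(x$folds$phenotype_id)),
      " phenotypes\n", sep = "")
  cat("  pooled AUC ", round(x$auc, 4), "; mean held-out percentile ",
      round(mean(x$folds$percentile), 4), "\n", sep = "")
  invisible(x)
}

#' Share of held-out lncRNAs recovered within a rank cutoff
#'
#' @param cv An `lnc_cv` result.
#' @param fraction Fractional cutoff: a fold counts when its held-out rank is
#'   at most `ceiling(fraction * n_candidates)`.
#' @param k Absolute cutoff: rank at most `k`.  Exactly one of `fraction`
#'   and `k` must be given.
#' @return The recall as a value in \[0, 1\].
#' @export
topk_recall <- function(cv, fraction = NULL, k = NULL) {
  stopifnot(inherits(cv, "lnc_cv"))
  if (is.null(fraction) == is.null(k)) {
    stop("give exactly one of fraction or k", call. = FALSE)
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]",
                                            call. = FALSE)
    mean(cv$folds$rank <= ceiling(fraction * cv$folds$n_candidates))
  } else {
    if (k < 1) stop("k must be positive", call. = FALSE)
    mean(cv$folds$rank <= k)
  }
}

#' LOOCV over a parameter grid
#'
#' Runs [loocv()] at every row of a parameter grid.  Grid rows violating the
#' parameter invariants (pairwise jump sums above 1, `alpha + beta > 1`,
#' `delta` outside (0, 1\]) are skipped with a reason rather than failing the
#' sweep.
#'
#' @param net A `composite_network`.
#' @param catalog An [association_catalog()].
#' @param grid Data frame whose columns are a subset of `delta`, `x`, `y`,
#'   `z`, `alpha`, `beta`; absent parameters take the defaults.
#' @param ... Further arguments passed to [loocv()].
#' @return A tibble with one row per grid point: the parameters, `auc`,
#'   `mean_percentile`, `n_folds` and a `note` for skipped points.
#' @export
parameter_sweep <- function(net, catalog, grid, ...) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) stop("empty parameter grid", call. = FALSE)
  allowed <- c("delta", "x", "y", "z", "alpha", "beta")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  defaults <- list(delta = 0.7, x = 1 / 3, y = 1 / 3, z = 1 / 3,
                   alpha = 1 / 3, beta = 1 / 3)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    pars <- utils::modifyList(defaults, as.list(grid[i, ]))
    note <- NA_character_
    if (pars$delta <= 0 || pars$delta > 1) {
      note <- "delta outside (0, 1]"
    } else if (pars$x + pars$y > 1 || pars$x + pars$z > 1 ||
               pars$y + pars$z > 1) {
      note <- "jump parameters violate pairwise sum constraint"
    } else if (pars$alpha + pars$beta > 1 ||
               pars$alpha < 0 || pars$beta < 0) {
      note <- "mix weights violate alpha + beta <= 1"
    }
    if (!is.na(note)) {
      return(tibble::tibble(!!!pars, auc = NA_real_,
                            mean_percentile = NA_real_,
                            n_folds = NA_integer_, note = note))
    }
    cv <- loocv(net, catalog, delta = pars$delta, x = pars$x, y = pars$y,
                z = pars$z, alpha = pars$alpha, beta = pars$beta, ...)
    tibble::tibble(!!!pars, auc = cv$auc,
                   mean_percentile = mean(cv$folds$percentile),
                   n_folds = nrow(cv$folds), note = NA_character_)
  })
  dplyr::bind_rows(rows)
}

# Landscape --------------------------------------------------------------------

#' Phenotype-by-lncRNA score landscape
#'
#' Runs one propagation per phenotype, seeded with the phenotype and its full
#' known gene and lncRNA sets, and collects the stationary lncRNA scores into
#' a phenotype x lncRNA matrix.  Phenotypes without known lncRNAs still get a
#' row (seeded by phenotype and genes); a phenotype that cannot be resolved
#' in the network yields a zero row with a warning.
#'
#' @param net A `composite_network`.
#' @param catalog An [association_catalog()].
#' @param phenotypes Phenotypes to score; default all phenotypes appearing
#'   in the catalog.
#' @param delta,x,y,z,alpha,beta Walk parameters.
#' @param tol,max_iter Convergence controls.
#' @return An object of class `lnc_landscape` holding the score matrix and
#'   the row/column id lists.
#' @export
score_landscape <- function(net, catalog, phenotypes = NULL, delta = 0.7,
                            x = 1 / 3, y = 1 / 3, z = 1 / 3,
                            alpha = 1 / 3, beta = 1 / 3,
                            tol = 1e-10, max_iter = 10000) {
  validate_composite_network(net)
  stopifnot(inherits(catalog, "association_catalog"))
  if (is.null(phenotypes)) {
    phenotypes <- sort(unique(c(catalog$lncrna_associations$phenotype_id,
                                catalog$gene_associations$phenotype_id)))
  }
  model <- build_transition(net, x = x, y = y, z = z)
  S <- matrix(0, length(phenotypes), length(net$lncrna_ids),
              dimnames = list(phenotypes, net$lncrna_ids))
  for (p in phenotypes) {
    known_l <- catalog$lncrna_associations$lncrna_id[
      catalog$lncrna_associations$phenotype_id == p]
    known_g <- catalog$gene_associations$gene_id[
      catalog$gene_associations$phenotype_id == p]
    sp <- intersect(p, net$phenotype_ids)
    sg <- intersect(known_g, net$gene_ids)
    sl <- intersect(known_l, net$lncrna_ids)
    if (!length(sp) && !length(sg) && !length(sl)) {
      warning("phenotype ", p, " has no resolvable seeds; zero row",
              call. = FALSE)
      next
    }
    p0 <- build_seed_vector(seed_set(sp, sg, sl), net,
                            alpha = alpha, beta = beta)
    stat <- propagate(model, p0, delta = delta, tol = tol,
                      max_iter = max_iter)
    S[p, ] <- stat$scores[net$lncrna_ids]
  }
  structure(
    list(scores = S, phenotype_ids = phenotypes,
         lncrna_ids = net$lncrna_ids),
    class = "lnc_landscape"
  )
}

#' @export
print.lnc_landscape <- function(x, ...) {
  cat("Score landscape: ", length(x$phenotype_ids), " phenotypes x ",
      length(x$lncrna_ids), " lncRNAs\n", sep = "")
  invisible(x)
}

#' Count the diseases in which each lncRNA is a top-ranked hotspot
#'
#' For each rank cutoff `k`, counts per lncRNA the phenotypes in whose
#' ranking it falls within the top `k` (ties broken by lexicographic id, as
#' in [rank_candidates()]).  Counts are monotone nondecreasing in `k`.
#'
#' @param landscape An `lnc_landscape`.
#' @param cutoffs Positive integer rank cutoffs; default `c(10, 50, 100)`.
#' @return A tibble with columns `lncrna_id`, `cutoff`, `n_phenotypes`.
#' @export
hotspot_counts <- function(landscape, cutoffs = c(10, 50, 100)) {
  stopifnot(inherits(landscape, "lnc_landscape"))
  if (any(cutoffs < 1)) stop("cutoffs must be positive", call. = FALSE)
  cutoffs <- sort(unique(as.integer(cutoffs)))
  S <- landscape$scores
  ids <- landscape$lncrna_ids
  ranks <- t(apply(S, 1, function(row) {
    ord <- order(-row, ids)
    r <- integer(length(row))
    r[ord] <- seq_along(row)
    r
  }))
  if (length(landscape$phenotype_ids) == 1) ranks <- matrix(ranks, nrow = 1)
  out <- purrr::map(cutoffs, function(k) {
    tibble::tibble(
      lncrna_id = ids,
      cutoff = k,
      n_phenotypes = colSums(ranks <= k)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$cutoff, dplyr::desc(.data$n_phenotypes),
                   .data$lncrna_id)
}
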