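#' Per-gene differential expression with kinship and permutation FDR
#'
#' Fits the kinship mixed model gene by gene (fixed diet effect, polygenic
#' random effect), computes permutation p-values (the same shuffled diet
#' vector applied to every gene within a permutation), converts them to an
#' empirical FDR, and labels directions. Positive `beta_diet` means higher
#' expression in Western-fed animals.
#'
#' @param resid a [residualize_covariates()] result or samples x genes matrix.
#' @param diet diet labels (`"Western"`/`"Mediterranean"` or 0/1 indicator).
#' @param K kinship matrix.
#' @param n_perm number of diet permutations (default 100).
#' @param fdr_threshold empirical FDR threshold for direction labels.
#' @param seed integer seed for the permutations.
#' @param unit,groups permutation unit, see [permutation_pvalues()].
#' @return a tibble of class `de_result`: `gene`, `beta_diet`, `se`,
#'   `statistic`, `p`, `fdr`, `direction` (`Western`/`Mediterranean`/`NS`).
#' @export
run_de <- function(resid, diet, K, n_perm = 100, fdr_threshold = 0.05, seed = 1,
                   unit = "animal", groups = NULL) {
  Y <- resid_matrix(resid)
  d01 <- diet_to_indicator(diet)
  if (length(d01) != nrow(Y)) abort("diet labels must align with samples")
  X <- cbind(`(Intercept)` = 1, diet = d01)
  eig <- lmm_eigen(K)
  core <- lmm_core(Y, X, eig, refine = TRUE)
  perms <- permutation_pvalues(Y, X, K, n_perm = n_perm, seed = seed,
                               unit = unit, groups = groups)
  fdr <- empirical_fdr(core$p["diet", ], perms)
  out <- tibble(
    gene = colnames(Y) %||% paste0("gene", seq_len(ncol(Y))),
    beta_diet = core$beta["diet", ],
    se = core$se["diet", ],
    statistic = core$t["diet", ],
    p = core$p["diet", ],
    fdr = fdr,
    direction = dplyr::case_when(
      fdr < fdr_threshold & core$beta["diet", ] > 0 ~ "Western",
      fdr < fdr_threshold & core$beta["diet", ] < 0 ~ "Mediterranean",
      TRUE ~ "NS"
    )
  )
  counts <- table(factor(out$direction, levels = c("Western", "Mediterranean", "NS")))
  inform(sprintf("run_de: %d Western, %d Mediterranean, %d NS of %d genes (FDR < %g, %d permutations)",
                 counts[["Western"]], counts[["Mediterranean"]], counts[["NS"]],
                 nrow(out), fdr_threshold, n_perm))
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("de_result", class(out))
  out
}

#' Principal component analysis of the sample correlation matrix
#'
#' Builds the sample-by-sample Pearson correlation matrix of residual
#' expression and eigendecomposes it. Scores are eigenvectors scaled by the
#' square root of their eigenvalues; variance explained is eigenvalue over
#' trace. Each component's sign is fixed so its largest-magnitude sample
#' loading is positive. If diet labels are given, each component is tested
#' against diet with Welch's t.
#'
#' @param resid residual expression (object or samples x genes matrix).
#' @param diet optional diet labels for per-component Welch tests.
#' @return an object of class `expression_pca`: `scores` (samples x
#'   components), `variance_explained`, `component_diet_tests` (tibble or
#'   `NULL`).
#' @export
sample_correlation_pca <- function(resid, diet = NULL) {
  Y <- resid_matrix(resid)
  if (nrow(Y) < 3) abort("need at least 3 samples")
  sds <- apply(Y, 1, sd)
  if (any(sds == 0)) abort("constant sample: correlation undefined")
  C <- cor(t(Y))
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  scores <- e$vectors %*% diag(sqrt(ev), nrow = length(ev))
  for (j in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(Y), paste0("PC", seq_len(ncol(scores))))
  tests <- NULL
  if (!is.null(diet)) {
    d01 <- diet_to_indicator(diet)
    tests <- purrr::map_dfr(seq_len(min(10, ncol(scores))), function(j) {
      wt <- welch_t_test(scores[d01 == 1, j], scores[d01 == 0, j])
      mutate(wt, component = paste0("PC", j), .before = 1)
    })
  }
  structure(list(scores = scores, variance_explained = ev / sum(ev),
                 component_diet_tests = tests),
            class = "expression_pca")
}

#' @export
print.expression_pca <- function(x, ...) {
  cat(sprintf("<expression_pca> %d components; PC1 explains %.1f%% of variance\n",
              ncol(x$scores), 100 * x$variance_explained[1]))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided. The
#' degenerate case of zero variance in both groups with equal means returns
#' `statistic = 0`, `p = 1`.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return one-row tibble: `statistic`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(tibble(statistic = 0, df = length(x) + length(y) - 2, p = 1))
    return(tibble(statistic = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0))
  }
  ht <- t.test(x, y)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Permutation enrichment of a gene set in one DE direction
#'
#' Fold enrichment is the proportion of direction-labelled genes inside the
#' set divided by the proportion expected when direction labels are randomly
#' reassigned across the background preserving counts. The permutation p is
#' the add-one-corrected two-sided tail probability; the 95% CI is a
#' percentile bootstrap over genes.
#'
#' @param de a [run_de()] result (or tibble with `gene` and `direction`).
#' @param gene_set character vector of member gene ids (subset of background).
#' @param direction `"Western"` or `"Mediterranean"`.
#' @param n_perm label permutations (default 1e5).
#' @param n_boot gene-bootstrap resamples for the CI (default 1e4).
#' @param seed integer seed.
#' @param set_name label used in the output.
#' @return one-row tibble of class `enrichment_result`: `set_name`,
#'   `fold_enrichment`, `ci_low`, `ci_high`, `p`, `method`, `n_set`,
#'   `n_direction`.
#' @export
set_enrichment_permutation <- function(de, gene_set, direction = c("Western", "Mediterranean"),
                                       n_perm = 1e5, n_boot = 1e4, seed = 1,
                                       set_name = "set") {
  direction <- match.arg(direction)
  if (length(gene_set) == 0) abort("empty gene set")
  bad <- setdiff(gene_set, de$gene)
  if (length(bad) > 0) abort(sprintf("%d gene-set members missing from the background", length(bad)))
  G <- nrow(de)
  in_set <- de$gene %in% gene_set
  in_dir <- de$direction == direction
  nS <- sum(in_set); nD <- sum(in_dir); k <- sum(in_set & in_dir)
  fold_of <- function(k, nS, nD) (k / nS) / (nD / G)
  obs <- fold_of(k, nS, nD)
  set.seed(seed)
  # random direction reassignment preserving counts makes the overlap
  # hypergeometric; drawn directly for speed
  k_perm <- rhyper(n_perm, nD, G - nD, nS)
  p_hi <- (1 + sum(k_perm >= k)) / (n_perm + 1)
  p_lo <- (1 + sum(k_perm <= k)) / (n_perm + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  # gene bootstrap via multinomial over the four (set x direction) cells
  cells <- c(k, nS - k, nD - k, G - nS - nD + k)
  bs <- rmultinom(n_boot, G, cells / G)
  fold_bs <- (bs[1, ] / (bs[1, ] + bs[2, ])) / ((bs[1, ] + bs[3, ]) / G)
  ci <- quantile(fold_bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  out <- tibble(set_name = set_name, fold_enrichment = obs,
                ci_low = ci[1], ci_high = ci[2], p = p,
                method = "permutation", n_set = nS, n_direction = nD)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Fisher's exact test for gene-set enrichment
#'
#' Two-by-two exact test of hit membership against set membership over a
#' background, two-sided p by hypergeometric enumeration (probabilities at or
#' below the observed table's), with the conditional odds ratio and its 95%
#' CI. Degenerate margins give `p = 1` and an undefined odds ratio.
#'
#' @param hits character vector of significant genes (subset of background).
#' @param background character vector of all tested genes.
#' @param gene_set character vector of set members.
#' @param set_name label for the output row.
#' @return one-row tibble of class `enrichment_result` with `odds_ratio`.
#' @export
fisher_set_enrichment <- function(hits, background, gene_set, set_name = "set") {
  if (length(setdiff(hits, background)) > 0) abort("hits must be a subset of background")
  in_hit <- background %in% hits
  in_set <- background %in% gene_set
  tab <- table(factor(in_set, c(TRUE, FALSE)), factor(in_hit, c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    out <- tibble(set_name = set_name, fold_enrichment = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, p = 1,
                  method = "fisher", odds_ratio = NA_real_,
                  n_set = sum(in_set), n_direction = sum(in_hit))
  } else {
    ft <- fisher.test(tab)
    fold <- (tab[1, 1] / sum(in_hit)) / (sum(in_set) / length(background))
    out <- tibble(set_name = set_name, fold_enrichment = fold,
                  ci_low = ft$conf.int[1], ci_high = ft$conf.int[2], p = ft$p.value,
                  method = "fisher", odds_ratio = unname(ft$estimate),
                  n_set = sum(in_set), n_direction = sum(in_hit))
  }
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Compare per-animal CTRA category scores between diets
#'
#' The conserved transcriptional response to adversity (CTRA) is scored per
#' animal as the mean residual expression over each category's genes
#' (configurable to the median); categories are compared between diets with
#' the Mann-Whitney U test and Holm-adjusted across categories. The U
#' statistic is oriented as U of the Western group.
#'
#' @param resid residual expression (object or samples x genes matrix).
#' @param ctra_sets named list of gene-id vectors (e.g. pro-inflammatory and
#'   antiviral/antibody categories), or a GMT path.
#' @param diet diet labels.
#' @param aggregate `"mean"` (default) or `"median"` per-animal aggregation.
#' @return tibble: `category`, `n_genes`, `statistic` (Mann-Whitney U of the
#'   Western group), `p`, `p_adjusted`, plus per-diet mean scores.
#' @export
ctra_score_compare <- function(resid, ctra_sets, diet, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  Y <- resid_matrix(resid)
  if (is.character(ctra_sets) && length(ctra_sets) == 1) ctra_sets <- read_gmt(ctra_sets)
  d01 <- diet_to_indicator(diet)
  agg <- if (aggregate == "mean") rowMeans else function(m) apply(m, 1, median)
  out <- purrr::map_dfr(names(ctra_sets), function(nm) {
    genes <- intersect(ctra_sets[[nm]], colnames(Y))
    if (length(genes) == 0) abort(paste0("no ", nm, " genes present in the expression matrix"))
    score <- agg(Y[, genes, drop = FALSE])
    mw <- mann_whitney_u(score[d01 == 1], score[d01 == 0])
    tibble(category = nm, n_genes = length(genes),
           statistic = mw$statistic, p = mw$p,
           mean_western = mean(score[d01 == 1]),
           mean_mediterranean = mean(score[d01 == 0]))
  })
  mutate(out, p_adjusted = holm_bonferroni(out$p))
}
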