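#' Select the top differentially expressed genes and enumerate their pairs
#'
#' Ranks significant genes by empirical FDR (ascending), breaking ties by
#' |beta_diet| (descending) then gene id, keeps the top `k`, and enumerates
#' all `k (k - 1) / 2` unordered pairs with stable indexing. For `k = 140`
#' this yields 9,730 pairs.
#'
#' @param de a [run_de()] result.
#' @param k number of genes to keep (default 140).
#' @param fdr_threshold significance threshold applied before ranking.
#' @return an object of class `gene_pair_set`: `genes` (ordered ids) and
#'   `pairs` (tibble `pair_id`, `gene_i`, `gene_j`).
#' @export
select_top_degs <- function(de, k = 140, fdr_threshold = 0.05) {
  k <- assert_count(k, "k")
  sig <- filter(de, .data$fdr < fdr_threshold)
  if (nrow(sig) < k) {
    abort(sprintf("only %d genes at FDR < %g; cannot select %d", nrow(sig), fdr_threshold, k))
  }
  ranked <- arrange(sig, .data$fdr, desc(abs(.data$beta_diet)), .data$gene)
  genes <- ranked$gene[seq_len(k)]
  idx <- utils::combn(k, 2)
  pairs <- tibble(
    pair_id = sprintf("pair%05d", seq_len(ncol(idx))),
    gene_i = genes[idx[1, ]],
    gene_j = genes[idx[2, ]]
  )
  structure(list(genes = genes, pairs = pairs), class = "gene_pair_set")
}

#' @export
print.gene_pair_set <- function(x, ...) {
  cat(sprintf("<gene_pair_set> %d genes, %d pairs\n", length(x$genes), nrow(x$pairs)))
  invisible(x)
}

#' Individual-level products for differential co-expression (CILP)
#'
#' Standardizes each gene to mean 0 and unit variance within each diet group
#' separately (sd with the n - 1 denominator), then forms, per gene pair, the
#' per-sample product of the two z-scores. The within-group mean of these
#' products (n - 1 denominator) equals the within-group Pearson correlation,
#' so modeling the products against diet tests for differential correlation.
#' Pairs containing a gene with zero within-group variance are flagged and
#' excluded.
#'
#' @param resid residual expression (object or samples x genes matrix).
#' @param pairset a [select_top_degs()] result.
#' @param diet diet labels.
#' @return an object of class `product_matrix`: `products` (samples x pairs),
#'   `group_means_r` (tibble `pair_id`, `gene_i`, `gene_j`, `r_western`,
#'   `r_mediterranean`), `dropped_pairs`.
#' @export
cilp_products <- function(resid, pairset, diet) {
  Y <- resid_matrix(resid)
  d01 <- diet_to_indicator(diet)
  if (min(sum(d01 == 1), sum(d01 == 0)) < 3) abort("each diet group needs n >= 3")
  genes <- pairset$genes
  missing <- setdiff(genes, colnames(Y))
  if (length(missing) > 0) abort(sprintf("%d pair-set genes missing from expression", length(missing)))
  Z <- Y[, genes, drop = FALSE]
  ok <- rep(TRUE, length(genes))
  for (g in c(0, 1)) {
    rows <- d01 == g
    sub <- Z[rows, , drop = FALSE]
    s <- apply(sub, 2, sd)
    ok <- ok & s > 0
    Z[rows, ] <- scale(sub)
  }
  names(ok) <- genes
  keep <- pairset$pairs$gene_i %in% genes[ok] & pairset$pairs$gene_j %in% genes[ok]
  dropped <- pairset$pairs$pair_id[!keep]
  if (length(dropped) > 0) {
    warn(sprintf("cilp_products: dropped %d pair(s) with zero within-group variance", length(dropped)))
  }
  pairs <- pairset$pairs[keep, , drop = FALSE]
  Zi <- Z[, pairs$gene_i, drop = FALSE]
  Zj <- Z[, pairs$gene_j, drop = FALSE]
  P <- Zi * Zj
  colnames(P) <- pairs$pair_id
  nw <- sum(d01 == 1); nm <- sum(d01 == 0)
  r_w <- colSums(P[d01 == 1, , drop = FALSE]) / (nw - 1)
  r_m <- colSums(P[d01 == 0, , drop = FALSE]) / (nm - 1)
  structure(list(
    products = P,
    group_means_r = mutate(pairs, r_western = unname(r_w), r_mediterranean = unname(r_m)),
    dropped_pairs = dropped
  ), class = "product_matrix")
}

#' Mixed-model test for differential co-expression
#'
#' Models each pair's product vector with a fixed diet effect and a kinship
#' random effect (the same machinery as the differential-expression stage),
#' computes permutation p-values with a shared shuffle across pairs, and an
#' empirical FDR with significance called at `fdr_threshold` (default 0.2).
#'
#' @param products a [cilp_products()] result.
#' @param diet diet labels.
#' @param K kinship matrix.
#' @param n_perm diet permutations (default 100).
#' @param fdr_threshold empirical FDR cutoff for the significant set.
#' @param seed integer seed.
#' @return a tibble of class `cilp_result`: per pair `pair_id`, `gene_i`,
#'   `gene_j`, `beta_diet_product`, `se`, `p`, `fdr`, `r_western`,
#'   `r_mediterranean`, `significant`.
#' @export
cilp_test <- function(products, diet, K, n_perm = 100, fdr_threshold = 0.2, seed = 1) {
  stopifnot(inherits(products, "product_matrix"))
  d01 <- diet_to_indicator(diet)
  P <- products$products
  X <- cbind(`(Intercept)` = 1, diet = d01)
  eig <- lmm_eigen(K)
  core <- lmm_core(P, X, eig, refine = TRUE)
  perms <- permutation_pvalues(P, X, K, n_perm = n_perm, seed = seed)
  fdr <- empirical_fdr(core$p["diet", ], perms)
  out <- mutate(products$group_means_r,
                beta_diet_product = core$beta["diet", ],
                se = core$se["diet", ],
                p = core$p["diet", ],
                fdr = fdr,
                significant = fdr < fdr_threshold)
  out <- select(out, "pair_id", "gene_i", "gene_j", "beta_diet_product",
                "se", "p", "fdr", "r_western", "r_mediterranean", "significant")
  inform(sprintf("cilp_test: %d of %d pairs significant at empirical FDR < %g",
                 sum(out$significant), nrow(out), fdr_threshold))
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("cilp_result", class(out))
  out
}

#' Hub genes against a pair-resampling null
#'
#' A hub is a gene participating in more significantly differentially
#' correlated pairs than expected by chance. The null draws `|sig_pairs|`
#' pairs uniformly without replacement from all tested pairs `n_resample`
#' times, records per-gene partner counts for every draw, pools them, and
#' takes the stated percentile; the threshold is the ceiling of that
#' percentile (floored at 1) and hubs are genes whose observed partner count
#' reaches it.
#'
#' @param sig_pairs character vector of significant `pair_id`s (or a
#'   [cilp_test()] result, from which the significant set is taken).
#' @param pairset the [select_top_degs()] pair set that was tested.
#' @param n_resample null draws (default 1000).
#' @param percentile percentile of the pooled null distribution (default 95).
#' @param seed integer seed.
#' @return an object of class `hub_result`: `partner_counts` (tibble `gene`,
#'   `observed`), `threshold`, `hub_genes`.
#' @export
detect_hubs <- function(sig_pairs, pairset, n_resample = 1000, percentile = 95, seed = 1) {
  if (inherits(sig_pairs, "cilp_result")) sig_pairs <- sig_pairs$pair_id[sig_pairs$significant]
  pairs <- pairset$pairs
  if (length(setdiff(sig_pairs, pairs$pair_id)) > 0) abort("sig_pairs must be a subset of the tested pairs")
  n_sig <- length(sig_pairs)
  if (n_sig > nrow(pairs)) abort("more significant pairs than tested pairs")
  genes <- pairset$genes
  gi <- match(pairs$gene_i, genes)
  gj <- match(pairs$gene_j, genes)
  count_partners <- function(pair_rows) {
    tabulate(c(gi[pair_rows], gj[pair_rows]), nbins = length(genes))
  }
  observed <- count_partners(match(sig_pairs, pairs$pair_id))
  if (n_sig == 0) {
    return(structure(list(
      partner_counts = tibble(gene = genes, observed = observed),
      threshold = Inf, hub_genes = character(0),
      null_quantile = NA_real_
    ), class = "hub_result"))
  }
  set.seed(seed)
  pooled <- matrix(0L, length(genes), n_resample)
  for (b in seq_len(n_resample)) {
    pooled[, b] <- count_partners(sample(nrow(pairs), n_sig))
  }
  qv <- quantile(as.vector(pooled), percentile / 100, type = 1, names = FALSE)
  threshold <- max(1, ceiling(qv))
  hubs <- genes[observed >= threshold]
  structure(list(
    partner_counts = tibble(gene = genes, observed = observed),
    threshold = threshold, hub_genes = hubs, null_quantile = qv
  ), class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("<hub_result> threshold = %s partners; %d hub gene(s)\n",
              format(x$threshold), length(x$hub_genes)))
  invisible(x)
}

#' Hypergeometric enrichment of transcription factors among hub genes
#'
#' Upper-tail hypergeometric test of the transcription-factor count among hub
#' genes against the background of all tested genes, with the sample odds
#' ratio.
#'
#' @param hub_genes character vector (subset of background).
#' @param background character vector of tested genes.
#' @param tf_list character vector of transcription-factor gene ids.
#' @return one-row tibble of class `enrichment_result`.
#' @export
hypergeom_tf_enrichment <- function(hub_genes, background, tf_list) {
  if (length(setdiff(hub_genes, background)) > 0) abort("hub_genes must be a subset of background")
  tf_bg <- intersect(tf_list, background)
  if (length(tf_bg) == 0) abort("tf_list has no overlap with the background")
  N <- length(background); K <- length(tf_bg); n <- length(hub_genes)
  q <- length(intersect(hub_genes, tf_bg))
  p <- phyper(q - 1, K, N - K, n, lower.tail = FALSE)
  or <- (q * (N - K - n + q)) / ((n - q) * (K - q))
  fold <- if (n > 0) (q / n) / (K / N) else NA_real_
  out <- tibble(set_name = "TF", fold_enrichment = fold,
                ci_low = NA_real_, ci_high = NA_real_, p = p,
                method = "hypergeometric", odds_ratio = or,
                n_set = K, n_direction = n)
  class(out) <- c("enrichment_result", class(out))
  out
}
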