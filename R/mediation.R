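#' Bootstrap specification for mediation analysis
#'
#' @param n_boot bootstrap iterations (default 10,000; >= 100).
#' @param ci_level confidence level in percent (default 90).
#' @param seed integer seed.
#' @param stratified resample within diet groups instead of rejecting
#'   one-diet resamples (default `FALSE`).
#' @return list of class `boot_spec`.
#' @export
boot_spec <- function(n_boot = 10000, ci_level = 90, seed = 1, stratified = FALSE) {
  n_boot <- assert_count(n_boot, "n_boot")
  if (n_boot < 100) abort("n_boot must be at least 100")
  if (ci_level <= 0 || ci_level >= 100) abort("ci_level must lie in (0, 100)")
  structure(list(n_boot = n_boot, ci_level = as.numeric(ci_level),
                 seed = assert_count(seed, "seed", positive = FALSE),
                 stratified = isTRUE(stratified)),
            class = "boot_spec")
}

#' Gate genes on univariate association with the DAB score
#'
#' Fits, per gene, the kinship mixed model of residual expression on the DAB
#' score, computes permutation p-values by permuting DAB across animals (the
#' same shuffle for every gene), and returns the genes passing the empirical
#' FDR threshold.
#'
#' @param resid residual expression (object or samples x genes matrix).
#' @param dab a [behavior_pca_dab()] result or numeric DAB vector aligned
#'   with samples.
#' @param K kinship matrix.
#' @param n_perm permutations (default 100).
#' @param fdr_threshold empirical FDR cutoff (default 0.05).
#' @param seed integer seed.
#' @return tibble: `gene`, `beta_dab`, `p`, `fdr`, `significant`; the gated
#'   gene ids are `gene[significant]`.
#' @export
gate_univariate_association <- function(resid, dab, K, n_perm = 100,
                                        fdr_threshold = 0.05, seed = 1) {
  Y <- resid_matrix(resid)
  dab <- dab_vector(dab, rownames(Y), nrow(Y))
  X <- cbind(`(Intercept)` = 1, dab = dab)
  eig <- lmm_eigen(K)
  core <- lmm_core(Y, X, eig, refine = TRUE)
  perms <- permutation_pvalues(Y, X, K, n_perm = n_perm, seed = seed, diet_col = 2)
  fdr <- empirical_fdr(core$p["dab", ], perms)
  tibble(gene = colnames(Y) %||% paste0("gene", seq_len(ncol(Y))),
         beta_dab = core$beta["dab", ], p = core$p["dab", ], fdr = fdr,
         significant = fdr < fdr_threshold)
}

#' @keywords internal
dab_vector <- function(dab, sample_ids, n) {
  if (inherits(dab, "dab_scores")) dab <- dab$dab
  if (is.data.frame(dab)) {
    if (!is.null(sample_ids)) {
      idx <- match(sample_ids, dab$animal_id)
      if (anyNA(idx)) abort("DAB animals do not cover the expression samples")
      return(dab$dab[idx])
    }
    return(dab$dab)
  }
  if (length(dab) != n) abort("DAB vector must align with samples")
  as.numeric(dab)
}

# closed-form OLS slopes for the two mediation models over many resamples:
# Model A: outcome ~ diet           -> beta_total
# Model B: outcome ~ diet + mediator -> beta_direct
# all inputs are n x B matrices (columns are resamples)
#' @keywords internal
mediation_betas <- function(Yb, Db, Mb) {
  n <- nrow(Yb)
  cY <- Yb - matrix(colMeans(Yb), n, ncol(Yb), byrow = TRUE)
  cD <- Db - matrix(colMeans(Db), n, ncol(Db), byrow = TRUE)
  cM <- Mb - matrix(colMeans(Mb), n, ncol(Mb), byrow = TRUE)
  s_dd <- colSums(cD^2); s_mm <- colSums(cM^2)
  s_dm <- colSums(cD * cM); s_dy <- colSums(cD * cY); s_my <- colSums(cM * cY)
  beta_total <- s_dy / s_dd
  det <- s_dd * s_mm - s_dm^2
  beta_direct <- (s_dy * s_mm - s_my * s_dm) / det
  list(beta_total = beta_total, beta_direct = beta_direct,
       degenerate = s_dd < 1e-12 | det < 1e-12 * pmax(s_dd * s_mm, 1e-300))
}

#' Bootstrap mediation for one outcome
#'
#' Point estimates come from ordinary least squares on the full sample:
#' Model A (`outcome ~ diet`) gives the total effect `beta_total`; Model B
#' (`outcome ~ diet + mediator`) gives the direct effect `beta_direct`; the
#' indirect effect is their difference (identical to the product of path
#' coefficients for linear models). Animals are resampled with replacement
#' (resamples containing a single diet, or giving singular fits, are redrawn
#' and counted); the CI is the percentile interval of the bootstrapped
#' difference, and mediation is called when it excludes zero.
#'
#' @param outcome numeric vector (gene expression, or DAB for the reverse
#'   direction).
#' @param diet diet labels.
#' @param mediator numeric vector (DAB score, or gene expression).
#' @param spec a [boot_spec()].
#' @return one-row tibble of class `mediation_fit`: `beta_total`,
#'   `beta_direct`, `indirect`, `ci_low`, `ci_high`, `significant`,
#'   `proportion_mediated`, `indirect_boot_mean`, `n_boot`, `n_redraws`.
#' @export
bootstrap_mediation <- function(outcome, diet, mediator, spec = boot_spec()) {
  stopifnot(inherits(spec, "boot_spec"))
  d01 <- diet_to_indicator(diet)
  n <- length(outcome)
  if (n < 10) abort("need n >= 10")
  if (length(unique(d01)) < 2) abort("both diet groups must be present")
  set.seed(spec$seed)
  res <- mediation_point(outcome, d01, mediator)
  boot <- mediation_bootstrap(outcome, d01, as.numeric(mediator), spec)
  alpha <- (100 - spec$ci_level) / 200
  ci <- quantile(boot$indirect, c(alpha, 1 - alpha), names = FALSE)
  out <- tibble(
    beta_total = res$beta_total, beta_direct = res$beta_direct,
    indirect = res$indirect,
    ci_low = ci[1], ci_high = ci[2],
    significant = ci[1] > 0 | ci[2] < 0,
    proportion_mediated = if (abs(res$beta_total) > 1e-10) res$indirect / res$beta_total else NA_real_,
    indirect_boot_mean = mean(boot$indirect),
    n_boot = spec$n_boot, n_redraws = boot$n_redraws
  )
  class(out) <- c("mediation_fit", class(out))
  out
}

#' @keywords internal
mediation_point <- function(outcome, d01, mediator) {
  b <- mediation_betas(matrix(outcome), matrix(d01), matrix(as.numeric(mediator)))
  list(beta_total = b$beta_total, beta_direct = b$beta_direct,
       indirect = b$beta_total - b$beta_direct)
}

#' @keywords internal
mediation_bootstrap <- function(outcome, d01, mediator, spec) {
  n <- length(outcome)
  B <- spec$n_boot
  draw <- function(k) {
    if (spec$stratified) {
      w <- which(d01 == 1); m <- which(d01 == 0)
      rbind(matrix(sample(w, length(w) * k, replace = TRUE), ncol = k),
            matrix(sample(m, length(m) * k, replace = TRUE), ncol = k))
    } else {
      matrix(sample.int(n, n * k, replace = TRUE), ncol = k)
    }
  }
  idx <- draw(B)
  indirect <- rep(NA_real_, B)
  n_redraws <- 0L
  todo <- seq_len(B)
  for (iter in 1:50) {
    Db <- matrix(d01[idx[, todo]], n, length(todo))
    bad_diet <- colSums(Db) %in% c(0, n)
    Yb <- matrix(outcome[idx[, todo]], n, length(todo))
    Mb <- matrix(mediator[idx[, todo]], n, length(todo))
    b <- mediation_betas(Yb, Db, Mb)
    bad <- bad_diet | b$degenerate | !is.finite(b$beta_total) | !is.finite(b$beta_direct)
    indirect[todo[!bad]] <- (b$beta_total - b$beta_direct)[!bad]
    todo <- todo[bad]
    if (length(todo) == 0) break
    n_redraws <- n_redraws + length(todo)
    idx[, todo] <- draw(length(todo))
  }
  if (length(todo) > 0) abort("bootstrap could not obtain valid resamples")
  if (n_redraws > 0.1 * B) warn(sprintf("%d of %d bootstrap resamples redrawn", n_redraws, B))
  list(indirect = indirect, n_redraws = n_redraws)
}

#' Bidirectional mediation scan over gated genes
#'
#' Forward direction: DAB mediating diet -> expression (outcome = gene,
#' mediator = DAB; Models 1-2). Reverse direction: expression mediating
#' diet -> DAB (outcome = DAB, mediator = gene; Models 3-4). One bootstrap
#' mediation fit per gated gene; per-gene seeds derive from `spec$seed` so
#' genes are reproducible in isolation.
#'
#' @param resid residual expression (object or samples x genes matrix).
#' @param diet diet labels.
#' @param dab DAB scores ([behavior_pca_dab()] result, tibble or vector).
#' @param gated_genes character vector of gene ids to scan (typically from
#'   [gate_univariate_association()]).
#' @param direction `"forward"` or `"reverse"`.
#' @param spec a [boot_spec()].
#' @param de optional [run_de()] result; when given, the summary reports the
#'   mean and sd of |proportion mediated| by gene direction label.
#' @return tibble of class `mediation_scan`: one row per gene with the
#'   [bootstrap_mediation()] fields plus `gene` and `direction`.
#' @export
mediation_scan <- function(resid, diet, dab, gated_genes,
                           direction = c("forward", "reverse"),
                           spec = boot_spec(), de = NULL) {
  direction <- match.arg(direction)
  Y <- resid_matrix(resid)
  if (length(gated_genes) == 0) abort("gated_genes must be non-empty")
  missing <- setdiff(gated_genes, colnames(Y))
  if (length(missing) > 0) abort(sprintf("%d gated genes missing from expression", length(missing)))
  d01 <- diet_to_indicator(diet)
  dabv <- dab_vector(dab, rownames(Y), nrow(Y))
  out <- purrr::map_dfr(seq_along(gated_genes), function(i) {
    g <- gated_genes[i]
    sp <- boot_spec(spec$n_boot, spec$ci_level, seed = child_seed(spec$seed, i),
                    stratified = spec$stratified)
    fit <- if (direction == "forward") {
      bootstrap_mediation(Y[, g], d01, dabv, sp)
    } else {
      bootstrap_mediation(dabv, d01, Y[, g], sp)
    }
    mutate(fit, gene = g, direction = direction, .before = 1)
  })
  n_sig <- sum(out$significant)
  msg <- sprintf("mediation_scan (%s): %d of %d genes with %g%% CI excluding zero",
                 direction, n_sig, nrow(out), spec$ci_level)
  if (!is.null(de)) {
    lab <- de$direction[match(out$gene, de$gene)]
    for (dd in c("Western", "Mediterranean")) {
      pm <- abs(out$proportion_mediated[out$significant & lab == dd])
      if (length(pm) > 0) {
        msg <- paste0(msg, sprintf("; %s genes mean |prop. mediated| = %.1f%% (sd %.1f%%)",
                                   dd, 100 * mean(pm, na.rm = TRUE), 100 * sd(pm, na.rm = TRUE)))
      }
    }
  }
  inform(msg)
  class(out) <- c("mediation_scan", class(out))
  out
}
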