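#' Genomic relationship matrix from genotype dosages
#'
#' Computes `K = Z Z' / m` where `Z` standardizes each SNP's dosages by its
#' sample allele frequency `f`: `z = (g - 2f) / sqrt(2 f (1 - f))`.
#' Monomorphic SNPs are dropped.
#'
#' @param dosages integer matrix (animals x SNPs) with entries in `{0, 1, 2}`.
#' @return a [kinship_matrix()].
#' @export
grm_from_dosages <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% 0:2)) abort("dosages must be 0, 1 or 2")
  f <- colMeans(dosages) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) abort("all SNPs are monomorphic")
  d <- dosages[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(sweep(d, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- rownames(dosages) %||% paste0("animal", seq_len(nrow(K)))
  kinship_matrix(K, tol_psd = 1e-6)
}

# ---- internal REML/ML machinery ---------------------------------------------
#
# Model per gene: y = X beta + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I).
# With K = U S U', rotating by U' gives independent observations with variance
# sg2 (S + delta), delta = se2 / sg2. The (RE)ML criterion is profiled over
# delta on a log10 grid and optionally refined by Brent search; beta by
# generalized least squares at the optimum.

# Moore-Penrose pseudo-inverse of a symmetric matrix (rank-deficient designs)
#' @keywords internal
ginv_sym <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*% ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
}

#' @keywords internal
lmm_eigen <- function(K) {
  e <- eigen(unclass(K), symmetric = TRUE)
  if (min(e$values) < -1e-8) abort("K is not positive semi-definite")
  e$values <- pmax(e$values, 0)
  e
}

# negative restricted/profile log-likelihood pieces for a single delta,
# evaluated for all genes (columns of ys) at once
#' @keywords internal
lmm_eval_delta <- function(delta, S, xs, ys, n, p, reml) {
  w <- 1 / (S + delta)
  xw <- xs * w
  XtWX <- crossprod(xw, xs)
  XtWy <- crossprod(xw, ys)
  A <- tryCatch(solve(XtWX), error = function(e) ginv_sym(XtWX))
  B <- A %*% XtWy
  R <- ys - xs %*% B
  rssw <- colSums(w * R^2)
  rssw <- pmax(rssw, 1e-12 * (if (reml) n - p else n))
  if (reml) {
    ll <- -0.5 * ((n - p) * (log(2 * pi * rssw / (n - p)) + 1) +
                    sum(log(S + delta)) + determinant(XtWX, logarithm = TRUE)$modulus[1])
  } else {
    ll <- -0.5 * (n * (log(2 * pi * rssw / n) + 1) + sum(log(S + delta)))
  }
  list(beta = B, A = A, rssw = rssw, ll = ll)
}

# vectorized fit over all gene columns for one fixed design
#' @keywords internal
lmm_core <- function(Y, X, eig, method = "REML", grid_n = 100, refine = TRUE,
                     grid_range = c(-5, 5)) {
  n <- nrow(Y); G <- ncol(Y); p <- qr(X)$rank
  if (n < p + 1) abort("fewer observations than design rank + 1")
  reml <- identical(method, "REML")
  Ut <- t(eig$vectors); S <- eig$values
  ys <- Ut %*% Y; xs <- Ut %*% X
  grid <- 10^seq(grid_range[1], grid_range[2], length.out = grid_n)
  llmat <- matrix(NA_real_, grid_n, G)
  for (i in seq_len(grid_n)) {
    llmat[i, ] <- lmm_eval_delta(grid[i], S, xs, ys, n, p, reml)$ll
  }
  best <- max.col(t(llmat), ties.method = "first")
  delta <- grid[best]
  boundary <- best == 1L | best == grid_n
  if (refine) {
    for (g in seq_len(G)) {
      lo <- grid[max(best[g] - 1L, 1L)]
      hi <- grid[min(best[g] + 1L, grid_n)]
      if (lo < hi) {
        opt <- optimize(function(d) lmm_eval_delta(d, S, xs, ys[, g, drop = FALSE], n, p, reml)$ll,
                        interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
        if (opt$objective >= llmat[best[g], g]) delta[g] <- opt$maximum
      }
    }
  }
  # final pass at per-gene optimum
  ug <- unique(delta)
  beta <- matrix(NA_real_, ncol(X), G)
  se <- matrix(NA_real_, ncol(X), G)
  sg2 <- numeric(G); ll <- numeric(G)
  for (d in ug) {
    idx <- which(delta == d)
    fit <- lmm_eval_delta(d, S, xs, ys[, idx, drop = FALSE], n, p, reml)
    beta[, idx] <- fit$beta
    s2 <- fit$rssw / (if (reml) n - p else n)
    s2 <- pmax(s2, 1e-12)
    sg2[idx] <- s2
    se[, idx] <- sqrt(pmax(outer(diag(fit$A), s2), 0))
    ll[idx] <- fit$ll[]
  }
  df <- n - p
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  rownames(beta) <- rownames(se) <- rownames(tstat) <- rownames(pval) <- colnames(X)
  list(beta = beta, se = se, t = tstat, p = pval,
       sigma_g2 = sg2, sigma_e2 = delta * sg2, lambda = delta,
       loglik = ll, df = df, boundary = boundary, method = method)
}

#' Fit a kinship linear mixed model for a single response
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by one-time eigendecomposition of `K`, rotation of
#' `y` and `X`, and 1-D optimization of the (RE)ML criterion over
#' `log10(lambda)` (`lambda = sigma_e^2 / sigma_g^2`) on a 100-point grid on
#' `[-5, 5]` refined by bounded Brent search. Fixed effects are estimated by
#' generalized least squares at the optimum; Wald t statistics use
#' `df = n - rank(X)`.
#'
#' @param y numeric response vector (one gene's residual expression).
#' @param X design matrix (first column typically the intercept; name the
#'   diet column `diet` for pretty output).
#' @param K a [kinship_matrix()] (or any symmetric PSD matrix).
#' @param method `"REML"` (default) or `"ML"`.
#' @return an object of class `lmm_fit` with elements `beta`, `se`, `t`, `p`
#'   (named by design column), `sigma_g2`, `sigma_e2`, `lambda`, `loglik`,
#'   `df`, `boundary`, `method`.
#' @examples
#' K <- simulate_kinship(12, 4, seed = 1)
#' X <- cbind(1, diet = rep(0:1, each = 6))
#' y <- X[, 2] * 0.8 + rnorm(12)
#' fit <- fit_lmm(y, X, K)
#' tidy(fit)
#' @export
fit_lmm <- function(y, X, K, method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X) || length(y) != nrow(K)) abort("dimensions of y, X and K must agree")
  if (qr(X)$rank < ncol(X)) warn("design matrix is rank deficient")
  eig <- lmm_eigen(K)
  core <- lmm_core(matrix(as.numeric(y), ncol = 1), X, eig, method = method)
  structure(list(
    beta = core$beta[, 1], se = core$se[, 1], t = core$t[, 1], p = core$p[, 1],
    sigma_g2 = core$sigma_g2[1], sigma_e2 = core$sigma_e2[1],
    lambda = core$lambda[1], loglik = core$loglik[1], df = core$df,
    boundary = core$boundary[1], method = method
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, lambda = %.4g, sigma_g2 = %.4g, sigma_e2 = %.4g, df = %d\n",
              x$method, x$lambda, x$sigma_g2, x$sigma_e2, x$df))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x an `lmm_fit` object.
#' @param ... unused.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta), std.error = unname(x$se),
         statistic = unname(x$t), p.value = unname(x$p))
}

#' @rdname fit_lmm
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, lambda = x$lambda,
         logLik = x$loglik, df.residual = x$df, boundary = x$boundary,
         method = x$method)
}

#' Permutation p-values for the diet effect
#'
#' Repeats the per-gene kinship mixed model after permuting diet labels.
#' Within one permutation the same shuffled diet vector is applied to every
#' gene, preserving inter-gene correlation under the null; with
#' `unit = "group"` diet is shuffled at the social-group level (diet was
#' assigned by pen).
#'
#' @param Y residual expression matrix (samples x genes) or
#'   `residual_expression`.
#' @param X design matrix whose column `diet_col` holds the diet indicator.
#' @param K kinship matrix.
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param unit `"animal"` (default) or `"group"`.
#' @param groups social-group labels, required for `unit = "group"`.
#' @param diet_col index of the permuted design column.
#' @param method,grid_n passed to the mixed-model fitter. Permuted refits use
#'   a coarser variance-ratio grid without Brent refinement; p-values are
#'   insensitive to lambda resolution.
#' @return an object of class `permutation_pvalues`: list with `pmat`
#'   (genes x permutations), `seed`, `unit`.
#' @export
permutation_pvalues <- function(Y, X, K, n_perm = 100, seed = 1,
                                unit = c("animal", "group"), groups = NULL,
                                diet_col = 2, method = "REML", grid_n = 21) {
  unit <- match.arg(unit)
  Y <- resid_matrix(Y)
  n_perm <- assert_count(n_perm, "n_perm")
  if (n_perm < 10) abort("n_perm must be at least 10")
  if (unit == "group") {
    if (is.null(groups)) abort("groups must be supplied when unit = 'group'")
    glev <- unique(groups)
    gdiet <- X[match(glev, groups), diet_col]
    if (length(glev) < 2) abort("need at least 2 groups for group-level permutation")
  }
  eig <- lmm_eigen(K)
  set.seed(seed)
  pmat <- matrix(NA_real_, ncol(Y), n_perm)
  Xb <- X
  for (b in seq_len(n_perm)) {
    if (unit == "animal") {
      Xb[, diet_col] <- sample(X[, diet_col])
    } else {
      Xb[, diet_col] <- sample(gdiet)[match(groups, glev)]
    }
    core <- lmm_core(Y, Xb, eig, method = method, grid_n = grid_n, refine = FALSE)
    pmat[, b] <- core$p[diet_col, ]
  }
  rownames(pmat) <- colnames(Y)
  structure(list(pmat = pmat, seed = seed, unit = unit),
            class = "permutation_pvalues")
}

#' Permutation-based empirical false discovery rate
#'
#' For each observed p-value `p_i`, the empirical FDR is the mean number of
#' permuted p-values (per permutation, pooled over genes) at or below `p_i`,
#' divided by the number of observed p-values at or below `p_i`. Monotonicity
#' is enforced by a cumulative minimum from the largest observed p-value
#' downward; values are clipped to `[0, 1]`.
#'
#' @param p_obs numeric vector of observed p-values (one per gene).
#' @param perms a [permutation_pvalues()] object or a genes x permutations
#'   matrix of permuted p-values.
#' @return numeric vector of empirical FDR values, aligned with `p_obs`.
#' @export
empirical_fdr <- function(p_obs, perms) {
  pmat <- if (inherits(perms, "permutation_pvalues")) perms$pmat else as.matrix(perms)
  if (length(p_obs) == 0) abort("empty p-value vector")
  if (length(p_obs) != nrow(pmat)) abort("p_obs length must equal the permutation gene count")
  n_perm <- ncol(pmat)
  ord <- order(p_obs)
  ps <- p_obs[ord]
  perm_sorted <- sort(as.vector(pmat))
  mean_null <- findInterval(ps, perm_sorted) / n_perm
  fdr <- mean_null / seq_along(ps)
  fdr <- pmin(rev(cummin(rev(fdr))), 1)
  out <- numeric(length(ps))
  out[ord] <- fdr
  out
}
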