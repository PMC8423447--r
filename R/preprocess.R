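#' Remove genes with low expression
#'
#' Retains exactly the genes whose median RPKM across samples is at least 1,
#' where RPKM = count / (gene length in kb x library size in millions) and
#' library sizes are recomputed from the unfiltered matrix. The filter is
#' idempotent.
#'
#' @param counts a [count_matrix()].
#' @param min_median_rpkm retention threshold (default 1).
#' @return the filtered [count_matrix()] with attributes `n_retained` and
#'   `n_removed`.
#' @export
filter_low_expression <- function(counts, min_median_rpkm = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- counts$library_sizes
  if (any(lib <= 0)) abort("all library sizes must be positive (empty sample present)")
  rpkm <- sweep(counts$counts, 2, counts$gene_lengths / 1e3, "/")
  rpkm <- sweep(rpkm, 1, lib / 1e6, "/")
  med <- apply(rpkm, 2, median)
  keep <- med >= min_median_rpkm
  inform(sprintf("filter_low_expression: retained %d genes, removed %d (median RPKM < %g)",
                 sum(keep), sum(!keep), min_median_rpkm))
  out <- count_matrix(counts$counts[, keep, drop = FALSE],
                      gene_lengths = counts$gene_lengths[keep],
                      gene_ids = counts$gene_ids[keep],
                      sample_ids = counts$sample_ids)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Normalize counts to log-CPM with mean-variance precision weights
#'
#' Computes `log2((count + 0.5) / (library size + 1) * 1e6)` together with
#' observation-level precision weights from a lowess fit of the square-root
#' residual standard deviation against mean fitted log-count, inverted to the
#' fourth power and interpolated per observation (limma's voom procedure).
#'
#' @param counts a filtered [count_matrix()].
#' @param span lowess span for the mean-variance trend.
#' @return an object of class `normalized_expression`: list with `logcpm` and
#'   `weights` (both samples x genes), plus ids.
#' @export
normalize_logcpm_weights <- function(counts, span = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  if (ncol(counts$counts) == 0 || nrow(counts$counts) == 0) abort("empty count matrix")
  v <- limma::voom(t(counts$counts), design = NULL,
                   lib.size = unname(counts$library_sizes), span = span)
  w <- t(v$weights)
  dimnames(w) <- list(counts$sample_ids, counts$gene_ids)
  structure(list(
    logcpm = t(v$E),
    weights = w,
    gene_ids = counts$gene_ids,
    sample_ids = counts$sample_ids
  ), class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("<normalized_expression> %d samples x %d genes (log2 CPM + precision weights)\n",
              nrow(x$logcpm), ncol(x$logcpm)))
  invisible(x)
}

#' Flag samples contaminated according to a marker gene
#'
#' Flags samples whose marker-gene log-CPM exceeds the across-sample median by
#' more than `k` raw median absolute deviations (MAD without the normal
#' consistency constant). When the MAD is zero the threshold degenerates to
#' the median and a strict inequality is required, so identical values are
#' never flagged. Used to detect e.g. CD3+ cell contamination of sorted
#' CD14+ monocyte samples.
#'
#' @param norm a [normalize_logcpm_weights()] result.
#' @param marker_gene gene identifier of the contamination marker.
#' @param k multiplier on the MAD (default 5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_marker_contamination <- function(norm, marker_gene, k = 5) {
  stopifnot(inherits(norm, "normalized_expression"))
  if (!marker_gene %in% norm$gene_ids) abort(paste0("marker gene not found: ", marker_gene))
  x <- norm$logcpm[, marker_gene]
  m <- median(x)
  s <- mad(x, constant = 1)
  flagged <- norm$sample_ids[x > m + k * s]
  if (length(flagged) > 0) {
    inform(sprintf("flag_marker_contamination: %d sample(s) exceed %s median + %g MAD",
                   length(flagged), marker_gene, k))
  }
  flagged
}

#' Residualize technical covariates out of normalized expression
#'
#' Fits, per gene, an ordinary least-squares model of log-CPM on the supplied
#' covariates (with intercept) and returns the residuals, which are used for
#' all downstream analyses. Rank-deficient covariate matrices are handled by
#' pivoted QR (aliased columns dropped with a warning).
#'
#' @param norm a [normalize_logcpm_weights()] result.
#' @param covariates data frame of numeric covariates, rows aligned with
#'   samples (typically CD14, CD3, RIN, concentration).
#' @return an object of class `residual_expression`: list with `residuals`
#'   (samples x genes), `covariate_names`, ids.
#' @export
residualize_covariates <- function(norm, covariates) {
  stopifnot(inherits(norm, "normalized_expression"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(norm$logcpm)) abort("covariate rows must align with samples")
  if (anyNA(covariates)) abort("covariates must not contain missing values")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warn(paste0("rank-deficient covariate matrix; dropped: ", paste(dropped, collapse = ", ")))
  }
  res <- qr.resid(qx, norm$logcpm)
  structure(list(
    residuals = res,
    covariate_names = colnames(covariates),
    gene_ids = norm$gene_ids,
    sample_ids = norm$sample_ids
  ), class = "residual_expression")
}

#' @export
print.residual_expression <- function(x, ...) {
  cat(sprintf("<residual_expression> %d samples x %d genes (covariates: %s)\n",
              nrow(x$residuals), ncol(x$residuals),
              paste(x$covariate_names, collapse = ", ")))
  invisible(x)
}

# accept either a residual_expression or a bare samples x genes matrix
#' @keywords internal
resid_matrix <- function(resid) {
  if (inherits(resid, "residual_expression")) return(resid$residuals)
  if (inherits(resid, "normalized_expression")) return(resid$logcpm)
  as.matrix(resid)
}
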