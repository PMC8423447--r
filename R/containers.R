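#' Construct a count matrix container
#'
#' Bundles a samples-by-genes integer count matrix with per-gene transcript
#' lengths. Library sizes are always recomputed from the counts rather than
#' trusted from the caller, since every downstream quantity (RPKM, CPM) is
#' defined in terms of the actual column sums of reads per sample.
#'
#' @param counts integer matrix, samples in rows and genes in columns; must be
#'   non-negative. Row and column names are used as sample/gene identifiers
#'   when `sample_ids`/`gene_ids` are not given.
#' @param gene_lengths positive numeric vector of transcript lengths in base
#'   pairs, one per gene (recycled names checked against `gene_ids`).
#' @param gene_ids,sample_ids optional character identifiers.
#' @return an object of class `count_matrix` with elements `counts`,
#'   `gene_lengths`, `library_sizes`, `gene_ids`, `sample_ids`.
#' @examples
#' cm <- count_matrix(matrix(rpois(6, 10), 2, 3,
#'                    dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))),
#'                    gene_lengths = c(1000, 2000, 1500))
#' cm$library_sizes
#' @export
count_matrix <- function(counts, gene_lengths, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) abort("counts must be finite and non-negative")
  gene_ids <- gene_ids %||% colnames(counts) %||% paste0("gene", seq_len(ncol(counts)))
  sample_ids <- sample_ids %||% rownames(counts) %||% paste0("sample", seq_len(nrow(counts)))
  if (length(gene_ids) != ncol(counts)) abort("gene_ids length must match ncol(counts)")
  if (length(sample_ids) != nrow(counts)) abort("sample_ids length must match nrow(counts)")
  gene_lengths <- as.numeric(gene_lengths)
  if (length(gene_lengths) != ncol(counts)) abort("gene_lengths length must match ncol(counts)")
  if (any(gene_lengths <= 0)) abort("gene_lengths must be positive")
  dimnames(counts) <- list(sample_ids, gene_ids)
  structure(
    list(
      counts = counts,
      gene_lengths = setNames(gene_lengths, gene_ids),
      library_sizes = setNames(rowSums(counts), sample_ids),
      gene_ids = gene_ids,
      sample_ids = sample_ids
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d genes, median library size %s\n",
              nrow(x$counts), ncol(x$counts),
              format(median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a kinship matrix container
#'
#' A kinship matrix is the animal-by-animal relatedness matrix that serves as
#' the covariance of the polygenic random effect in the mixed model. It must
#' be symmetric and positive semi-definite.
#'
#' @param K square numeric matrix of pairwise relatedness.
#' @param animal_ids optional identifiers; defaults to the row names of `K`.
#' @param tol_sym maximum tolerated asymmetry.
#' @param tol_psd smallest eigenvalue allowed below zero.
#' @return an object of class `kinship_matrix` (the validated matrix, with an
#'   `animal_ids` attribute).
#' @export
kinship_matrix <- function(K, animal_ids = NULL, tol_sym = 1e-10, tol_psd = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) abort("K must be square")
  if (max(abs(K - t(K))) > tol_sym) abort("K must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_psd) abort(sprintf("K is not positive semi-definite (min eigenvalue %.3g)", min(ev)))
  animal_ids <- animal_ids %||% rownames(K) %||% paste0("animal", seq_len(nrow(K)))
  dimnames(K) <- list(animal_ids, animal_ids)
  structure(K, animal_ids = animal_ids, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d animals, mean off-diagonal relatedness %.3f\n",
              nrow(x), mean(x[upper.tri(x)])))
  invisible(x)
}
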