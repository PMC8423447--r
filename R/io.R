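#' Read and write the package's tabular interchange formats
#'
#' Counts travel as genes-by-samples TSV (header row of sample ids, first
#' column of gene ids) or as MatrixMarket MTX with row/column name sidecars.
#' Kinship, metadata, behavior and truth tables are plain TSV. Gene sets use
#' the GMT convention (set name, description, then member genes, tab
#' separated). All writers emit deterministic bytes so reruns hash equal.
#'
#' @name dietfx-io
NULL

#' @keywords internal
write_tsv_plain <- function(df, path, comments = character()) {
  if (length(comments) > 0) {
    readr::write_lines(paste0("# ", comments), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' @keywords internal
read_tsv_plain <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write a count matrix to TSV (genes x samples)
#' @param counts a [count_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- tibble(gene_id = counts$gene_ids, length_bp = unname(counts$gene_lengths))
  mat <- as_tibble(t(counts$counts), .name_repair = "minimal")
  write_tsv_plain(dplyr::bind_cols(df, mat), path)
}

#' Read a count matrix from TSV (genes x samples)
#' @param path TSV written by [write_counts_tsv()]: columns `gene_id`,
#'   `length_bp`, then one column per sample.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_plain(path)
  mat <- t(as.matrix(df[, -(1:2)]))
  colnames(mat) <- df$gene_id
  count_matrix(mat, gene_lengths = df$length_bp,
               gene_ids = df$gene_id, sample_ids = rownames(mat))
}

#' Write a count matrix as MatrixMarket MTX with name sidecars
#' @param counts a [count_matrix()].
#' @param stem path stem; writes `<stem>.mtx`, `<stem>.genes.txt`,
#'   `<stem>.samples.txt`, `<stem>.lengths.txt`.
#' @return character vector of files written, invisibly.
#' @export
write_counts_mtx <- function(counts, stem) {
  files <- paste0(stem, c(".mtx", ".genes.txt", ".samples.txt", ".lengths.txt"))
  Matrix::writeMM(Matrix::Matrix(t(counts$counts), sparse = TRUE), files[1])
  readr::write_lines(counts$gene_ids, files[2])
  readr::write_lines(counts$sample_ids, files[3])
  readr::write_lines(format(unname(counts$gene_lengths), scientific = FALSE, trim = TRUE), files[4])
  invisible(files)
}

#' Read a count matrix from MatrixMarket MTX
#' @param stem path stem as used by [write_counts_mtx()].
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  genes <- readr::read_lines(paste0(stem, ".genes.txt"))
  samples <- readr::read_lines(paste0(stem, ".samples.txt"))
  lengths <- as.numeric(readr::read_lines(paste0(stem, ".lengths.txt")))
  count_matrix(t(m), gene_lengths = lengths, gene_ids = genes, sample_ids = samples)
}

#' Write a kinship matrix to TSV
#' @param K a [kinship_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- as_tibble(unclass(K), .name_repair = "minimal")
  write_tsv_plain(dplyr::bind_cols(tibble(animal_id = rownames(K)), df), path)
}

#' Read a kinship matrix from TSV
#' @param path TSV with `animal_id` column then one column per animal.
#' @return a [kinship_matrix()].
#' @export
read_kinship_tsv <- function(path) {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$animal_id
  kinship_matrix(m, animal_ids = df$animal_id)
}

#' Read gene sets from a GMT file
#' @param path GMT file (tab separated: name, description, member genes).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) abort("gene sets must be named")
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
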