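# Readers and writers for the plain-text interchange formats the pipeline
# uses: TSV / MatrixMarket counts, CSV sample sheets and trait tables,
# one-id-per-line gene lists, TSV edge/community tables and a GMT-like
# community file.

#' Read a gene x sample count matrix
#'
#' Tab-separated (first column = gene id; `.tsv`, optionally gzipped) or
#' MatrixMarket (`.mtx`, with `<path>.genes` / `<path>.samples` sidecar files
#' holding one id per line).
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    .assert(requireNamespace("Matrix", quietly = TRUE),
            "reading MatrixMarket counts requires the Matrix package")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".genes"))
    colnames(m) <- readLines(paste0(path, ".samples"))
  } else {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "integer"
  .check_count_matrix(m)
  m
}

#' Write a count matrix as TSV (gzipped when the path ends in .gz)
#' @param counts gene x sample matrix.
#' @param path destination path.
#' @export
write_counts <- function(counts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (CSV with sample_id, subject_id, tissue, timepoint)
#' @param path CSV path.
#' @export
read_sample_sheet <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "subject_id", "tissue", "timepoint") %in% names(ann)),
          "sample sheet needs sample_id, subject_id, tissue, timepoint columns")
  ann
}

#' Read a clinical trait table (CSV with a subject_id column)
#' @param path CSV path.
#' @export
read_traits <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  .assert("subject_id" %in% names(tr), "trait table needs a subject_id column")
  tr
}

#' Read a gene list (one id per line, e.g. protein-evidence ids)
#' @param path text file path.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write the shared network edge table as TSV
#' @param network an `xt_network`.
#' @param path destination path.
#' @export
write_edges <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write community assignments as a two-column TSV and a GMT-like file
#' @param partition an `xt_partition`.
#' @param path TSV destination; a `.gmt` file with the same stem is written
#'   alongside.
#' @export
write_communities <- function(partition, path) {
  memb <- partition$membership
  df <- data.frame(gene_id = names(memb),
                   community = ifelse(memb == 0L, "unassigned", memb))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gmt <- sub("\\.[^.]+$", ".gmt", path)
  lines <- vapply(sort(unique(memb[memb != 0])), function(k) {
    paste(c(sprintf("community_%d", k), sprintf("louvain community %d", k),
            names(memb)[memb == k]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt)
  invisible(path)
}

#' Write an eigengene matrix as CSV (community x sample)
#' @param eig an `xt_eigengenes`.
#' @param path destination path.
#' @export
write_eigengenes <- function(eig, path) {
  df <- data.frame(community = rownames(eig$scores), eig$scores,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
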