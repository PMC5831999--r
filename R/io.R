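#' Write an expression dataset as TSV files
#'
#' Writes `ratios.tsv` (genes x samples, linear scale), `flags.tsv`,
#' `samples.tsv` and `genes.tsv` into `dir`.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(ds$ratios, file.path(dir, "ratios.tsv"))
  write_mat(ds$flags, file.path(dir, "flags.tsv"))
  write.table(ds$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$genes, file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression dataset written by [write_expression_dataset()]
#'
#' @param dir Directory containing `ratios.tsv`, `flags.tsv`, `samples.tsv`
#'   and `genes.tsv`.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(dir) {
  read_mat <- function(path, mode) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    storage.mode(m) <- mode
    m
  }
  ratios <- read_mat(file.path(dir, "ratios.tsv"), "double")
  flags <- read_mat(file.path(dir, "flags.tsv"), "logical")
  samples <- read.delim(file.path(dir, "samples.tsv"))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  expression_dataset(ratios, flags, samples, genes)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param terms Named list of character vectors of gene ids.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions
#'   (defaults to the term names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path, descriptions = names(terms)) {
  stopifnot(!is.null(names(terms)))
  lines <- vapply(seq_along(terms), function(i) {
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
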