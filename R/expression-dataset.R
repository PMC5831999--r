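#' Construct an expression dataset
#'
#' Bundles a genes x samples matrix of linear-scale normalized two-colour
#' ratios (sample/reference), a boolean detection-flag matrix of the same
#' shape (well-above-background calls from the scanner), a sample sheet and a
#' gene table into a validated `ExpressionDataset` object, the substrate of
#' every downstream stage.
#'
#' @param ratios Numeric matrix, genes x samples, strictly positive
#'   linear-scale ratios. Row names are gene ids, column names sample ids.
#' @param flags Logical matrix, same shape and dimnames as `ratios`.
#' @param samples Data frame with columns `sample_id`, `age_group`
#'   (`"adult"`/`"elderly"`) and `status` (`"sepsis"`/`"control"`), one row
#'   per matrix column. All four design cells must be present.
#' @param genes Data frame with columns `gene_id` and `class` (one of
#'   `protein_coding`, `pseudogene`, `lncRNA`, `poorly_annotated`), one row
#'   per matrix row.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `ratios`, `flags`, `samples`, `genes`.
#' @export
expression_dataset <- function(ratios, flags, samples, genes) {
  stopifnot(is.matrix(ratios), is.numeric(ratios))
  if (any(ratios <= 0)) {
    stop("all ratios must be > 0 (linear-scale two-colour ratios)")
  }
  if (is.null(flags)) stop("detection flags are missing")
  stopifnot(is.matrix(flags), is.logical(flags))
  if (!identical(dim(flags), dim(ratios))) {
    stop("flags must have the same shape as ratios")
  }
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "age_group", "status") %in% names(samples)))
  if (!setequal(samples$sample_id, colnames(ratios)) ||
      nrow(samples) != ncol(ratios)) {
    stop("sample sheet must cover every matrix column exactly once")
  }
  samples <- samples[match(colnames(ratios), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$age_group %in% AGE_GROUPS) ||
      !all(samples$status %in% STATUSES)) {
    stop("age_group must be adult/elderly and status sepsis/control")
  }
  cells <- table(samples$age_group, samples$status)
  if (!all(dim(cells) == c(2L, 2L)) || any(cells == 0)) {
    stop("all four design cells (age_group x status) must be present")
  }
  stopifnot(is.data.frame(genes), all(c("gene_id", "class") %in% names(genes)))
  if (nrow(genes) != nrow(ratios) ||
      !identical(as.character(genes$gene_id), rownames(ratios))) {
    stop("gene table must match matrix rows (same ids, same order)")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  structure(list(ratios = ratios, flags = flags, samples = samples,
                 genes = genes),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
              nrow(x$ratios), ncol(x$ratios)))
  cat("  design:",
      paste(sprintf("%s/%s n=%d",
                    rep(AGE_GROUPS, each = 2), rep(STATUSES, 2),
                    as.vector(vapply(AGE_GROUPS, function(a)
                      vapply(STATUSES, function(s)
                        sum(x$samples$age_group == a & x$samples$status == s),
                        0L), integer(2)))),
            collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$genes$class)),
                                  table(x$genes$class)), collapse = ", "), "\n")
  invisible(x)
}

log2_ratios <- function(ds) log2(ds$ratios)

sample_index <- function(ds, age_group = NULL, status = NULL) {
  keep <- rep(TRUE, nrow(ds$samples))
  if (!is.null(age_group)) keep <- keep & ds$samples$age_group %in% age_group
  if (!is.null(status)) keep <- keep & ds$samples$status %in% status
  which(keep)
}

subset_genes <- function(ds, keep) {
  expression_dataset(ds$ratios[keep, , drop = FALSE],
                     ds$flags[keep, , drop = FALSE],
                     ds$samples,
                     ds$genes[keep, , drop = FALSE])
}

#' Well-above-background detection filter
#'
#' Keeps a gene when its detection flag is set in at least `min_detected` of
#' `group_size` subjects in at least one design cell (age group x status).
#' When a cell has a different number of subjects the threshold is rescaled
#' as `ceiling(min_detected / group_size * cell size)`.
#'
#' @param ds An [expression_dataset()].
#' @param min_detected Minimum flagged subjects per cell (default 5).
#' @param group_size Nominal cell size the threshold refers to (default 6).
#' @return The filtered `ExpressionDataset`. Idempotent.
#' @export
detection_filter <- function(ds, min_detected = 5, group_size = 6) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$flags)) stop("detection flags are missing")
  cell <- interaction(ds$samples$age_group, ds$samples$status, drop = TRUE)
  keep <- rep(FALSE, nrow(ds$ratios))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    thr <- if (length(idx) == group_size) min_detected else
      ceiling(min_detected / group_size * length(idx))
    keep <- keep | rowSums(ds$flags[, idx, drop = FALSE]) >= thr
  }
  subset_genes(ds, keep)
}

#' Select the most variable genes by coefficient of variation
#'
#' Ranks genes of the requested classes by their coefficient of variation
#' (sd/mean of the linear-scale ratios over all samples) and returns the top
#' `ceiling(fraction * n)` of the candidate universe, ties broken by gene id.
#'
#' @param ds An [expression_dataset()] (normally detection-filtered).
#' @param classes Character vector of gene classes forming the candidate
#'   universe (default `"lncRNA"`).
#' @param fraction Fraction of candidates to return, in (0, 1] (default 0.05).
#' @return Character vector of selected gene ids.
#' @export
select_most_variable <- function(ds, classes = "lncRNA", fraction = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  cand <- which(ds$genes$class %in% classes)
  if (length(cand) == 0) return(character(0))
  m <- ds$ratios[cand, , drop = FALSE]
  cv <- apply(m, 1, sd) / rowMeans(m)
  ids <- ds$genes$gene_id[cand]
  ord <- order(-cv, ids)
  n_take <- ceiling(fraction * length(cand))
  ids[ord][seq_len(n_take)]
}

#' UPGMA clustering of samples
#'
#' Clusters samples by average-linkage (UPGMA) agglomeration on the distance
#' `1 - Pearson r`, with correlations computed between samples over the given
#' gene set on the log2 ratio scale.
#'
#' @param ds An [expression_dataset()].
#' @param gene_ids Genes over which sample-sample correlation is computed.
#' @return A list with elements `hclust` (the merge tree), `order` (leaf
#'   order, sample ids) and `newick` (the tree serialised as a Newick
#'   string, branch lengths from merge heights).
#' @export
upgma_cluster <- function(ds, gene_ids) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ncol(ds$ratios) < 2) stop("need at least 2 samples")
  idx <- match(gene_ids, ds$genes$gene_id)
  if (anyNA(idx)) stop("unknown gene id: ", gene_ids[which(is.na(idx))[1]])
  m <- log2_ratios(ds)[idx, , drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance sample over the gene set: ",
         colnames(m)[which(sds == 0)[1]])
  }
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  list(hclust = hc,
       order = hc$labels[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Cut a sample dendrogram into k clusters
#'
#' Convenience wrapper around [stats::cutree()] returning cluster labels
#' named by sample id.
#'
#' @param clustering Result of [upgma_cluster()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_sample_tree <- function(clustering, k = 2) {
  stats::cutree(clustering$hclust, k = k)
}
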