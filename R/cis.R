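# Cis-neighbour analysis: nearest protein-coding gene per lncRNA and the
# empirical significance of the pair's expression correlation against the
# all-pair correlation distribution.

#' Nearest protein-coding neighbour of each lncRNA locus
#'
#' For every lncRNA in the catalog, finds the protein-coding gene on the
#' same chromosome minimising the interval gap in either direction
#' (overlap counts as distance 0). Equidistant up/downstream neighbours are
#' resolved to the upstream (lower-coordinate) gene.
#'
#' @param catalog Gene catalog data frame (`gene_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `class`), e.g. from
#'   [generate_gene_catalog()] or a converted GTF/BED.
#' @param lnc_ids lncRNA gene ids to pair (default: all `class == "lncRNA"`
#'   rows).
#' @return Data frame: `lnc_id`, `neighbor_id` (NA when the chromosome has
#'   no protein-coding gene), `distance` (bp).
#' @export
nearest_protein_coding <- function(catalog, lnc_ids = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "class") %in%
                  names(catalog)))
  if (any(catalog$start >= catalog$end)) {
    stop("malformed locus (start >= end) for gene: ",
         catalog$gene_id[which(catalog$start >= catalog$end)[1]])
  }
  if (is.null(lnc_ids)) lnc_ids <- catalog$gene_id[catalog$class == "lncRNA"]
  pc <- catalog[catalog$class == "protein_coding", , drop = FALSE]
  rows <- lapply(lnc_ids, function(lnc) {
    i <- match(lnc, catalog$gene_id)
    if (is.na(i)) stop("unknown lncRNA locus: ", lnc)
    cand <- pc[pc$chrom == catalog$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(lnc_id = lnc, neighbor_id = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    }
    gap <- pmax(0, pmax(catalog$start[i], cand$start) -
                  pmin(catalog$end[i], cand$end))
    # upstream (lower-coordinate) gene wins ties, then gene id
    upstream <- cand$end <= catalog$start[i]
    ord <- order(gap, !upstream, cand$gene_id)
    data.frame(lnc_id = lnc, neighbor_id = cand$gene_id[ord[1]],
               distance = gap[ord[1]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical significance of lncRNA-neighbour expression correlations
#'
#' The absolute Pearson correlation of each pair (log2 ratios over all
#' samples) is compared with the distribution of `|r|` over `n_null_pairs`
#' uniformly sampled detected-gene pairs:
#' `p_empirical = (1 + #null >= |r|) / (1 + n_null_pairs)`. A pair is
#' significant when the Bonferroni-corrected p-value
#' (`p_empirical * #pairs`) is at most `alpha`.
#'
#' @param pairs Data frame with columns `lnc_id`, `neighbor_id` (e.g. from
#'   [nearest_protein_coding()]); rows with a missing neighbour or a member
#'   absent from the dataset are dropped.
#' @param ds An [expression_dataset()] (detection-filtered).
#' @param n_null_pairs Size of the null sample (>= 1000; default 1e6).
#' @param seed Integer seed for the null sampling.
#' @param alpha Bonferroni-corrected significance level (default 0.01).
#' @return The `pairs` data frame with `r`, `p_empirical`, `p_bonferroni`
#'   and `significant` columns added.
#' @export
pair_correlation_significance <- function(pairs, ds, n_null_pairs = 1e6,
                                          seed = 1, alpha = 0.01) {
  if (n_null_pairs < 1000) stop("n_null_pairs must be >= 1000")
  if (ncol(ds$ratios) < 3) stop("need >= 3 samples")
  keep <- !is.na(pairs$neighbor_id) &
    pairs$lnc_id %in% ds$genes$gene_id &
    pairs$neighbor_id %in% ds$genes$gene_id
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(cbind(pairs, r = numeric(0),
                                     p_empirical = numeric(0),
                                     p_bonferroni = numeric(0),
                                     significant = logical(0)))
  X <- log2_ratios(ds)
  Z <- X - rowMeans(X)
  ss <- sqrt(rowSums(Z^2))
  Z <- Z / ss
  pair_r <- rowSums(Z[pairs$lnc_id, , drop = FALSE] *
                      Z[pairs$neighbor_id, , drop = FALSE])
  set.seed(seed)
  G <- nrow(X)
  i <- sample.int(G, n_null_pairs, replace = TRUE)
  j <- sample.int(G - 1, n_null_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1, j)  # uniform over ordered distinct pairs
  null_r <- numeric(n_null_pairs)
  for (lo in seq(1, n_null_pairs, by = 100000L)) {
    hi <- min(lo + 100000L - 1, n_null_pairs)
    null_r[lo:hi] <- abs(rowSums(Z[i[lo:hi], , drop = FALSE] *
                                   Z[j[lo:hi], , drop = FALSE]))
  }
  p_emp <- vapply(abs(pair_r), function(r)
    (1 + sum(null_r >= r)) / (1 + n_null_pairs), 0)
  m <- nrow(pairs)
  p_bonf <- pmin(1, p_emp * m)
  pairs$r <- pair_r
  pairs$p_empirical <- p_emp
  pairs$p_bonferroni <- p_bonf
  pairs$significant <- p_bonf <= alpha
  pairs
}

#' Restrict neighbour pairs to proximal loci
#'
#' Keeps pairs whose genomic distance is strictly shorter than
#' `max_distance` base pairs.
#'
#' @param pairs Data frame with a `distance` column.
#' @param max_distance Distance bound in bp (default 4000).
#' @return The filtered data frame.
#' @export
proximal_subset <- function(pairs, max_distance = 4000) {
  pairs[!is.na(pairs$distance) & pairs$distance < max_distance, ,
        drop = FALSE]
}
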