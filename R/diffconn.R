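# Cross-network differential connectivity: major connectivity, the
# connectivity ratio between the two age-group networks and the selections
# of the most connected / most differentially connected DEGs.

#' Cross-network connectivity statistics
#'
#' Per gene: the larger of the two connectivities (major connectivity), the
#' major/minor connectivity ratio, and the differential-connectivity score
#' `mean(k_adult, k_elderly) * ratio`. A minor connectivity of exactly zero
#' yields an infinite ratio and is flagged.
#'
#' @param k_adult,k_elderly Named connectivity vectors over the same gene
#'   universe (see [connectivity()]).
#' @param deg Optional logical vector or character vector of gene ids
#'   marking DEGs (union over age groups); filled into `is_deg`.
#' @return Data frame: `gene_id`, `k_adult`, `k_elderly`, `major_k`,
#'   `connectivity_ratio`, `diffconn_score`, `infinite_ratio`, `is_deg`.
#' @export
cross_network_stats <- function(k_adult, k_elderly, deg = NULL) {
  if (!setequal(names(k_adult), names(k_elderly))) {
    d1 <- setdiff(names(k_adult), names(k_elderly))
    d2 <- setdiff(names(k_elderly), names(k_adult))
    stop("gene universes differ between networks: ",
         paste(head(c(d1, d2), 10), collapse = ", "))
  }
  k_elderly <- k_elderly[names(k_adult)]
  major <- pmax(k_adult, k_elderly)
  minor <- pmin(k_adult, k_elderly)
  ratio <- ifelse(minor == 0, Inf, major / minor)
  score <- (k_adult + k_elderly) / 2 * ratio
  is_deg <- if (is.null(deg)) rep(FALSE, length(major))
  else if (is.character(deg)) names(k_adult) %in% deg
  else as.logical(deg)
  data.frame(gene_id = names(k_adult), k_adult = unname(k_adult),
             k_elderly = unname(k_elderly), major_k = unname(major),
             connectivity_ratio = unname(ratio),
             diffconn_score = unname(score),
             infinite_ratio = unname(!is.finite(ratio)),
             is_deg = is_deg, stringsAsFactors = FALSE)
}

select_fraction <- function(records, fraction, order_cols) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  recs <- records[records$is_deg, , drop = FALSE]
  if (nrow(recs) == 0) stop("empty DEG set")
  ord <- do.call(order, order_cols(recs))
  recs$gene_id[ord][seq_len(ceiling(fraction * nrow(recs)))]
}

#' Select the most connected DEGs
#'
#' Ranks DEGs by major connectivity (descending, ties by gene id) and
#' returns the top `ceiling(fraction * n_DEG)`.
#'
#' @param records [cross_network_stats()] data frame with `is_deg` filled.
#' @param fraction Fraction of DEGs to keep (default 0.15).
#' @return Character vector of selected gene ids.
#' @export
select_top_connected <- function(records, fraction = 0.15) {
  select_fraction(records, fraction,
                  function(r) list(-r$major_k, r$gene_id))
}

#' Select the most differentially connected DEGs
#'
#' Ranks DEGs by the differential-connectivity score (the product of the
#' mean connectivity across both networks and the connectivity ratio),
#' descending; genes with an infinite ratio rank above all finite scores,
#' ordered by mean connectivity. Returns the top
#' `ceiling(fraction * n_DEG)`.
#'
#' @param records [cross_network_stats()] data frame with `is_deg` filled.
#' @param fraction Fraction of DEGs to keep (default 0.20).
#' @return Character vector of selected gene ids.
#' @export
select_top_diff_connected <- function(records, fraction = 0.20) {
  select_fraction(records, fraction, function(r) {
    mean_k <- (r$k_adult + r$k_elderly) / 2
    list(-r$infinite_ratio, ifelse(r$infinite_ratio, -mean_k,
                                   -r$diffconn_score), r$gene_id)
  })
}

#' Connectivity contrast between DEGs and non-DEGs
#'
#' Mean and SD of the major connectivity for DEGs and non-DEGs plus a
#' two-sided Wilcoxon rank-sum p-value for the difference.
#'
#' @param records [cross_network_stats()] data frame over all genes.
#' @return List: `deg_mean`, `deg_sd`, `nondeg_mean`, `nondeg_sd`,
#'   `p_value`, `n_deg`, `n_nondeg`.
#' @export
connectivity_by_deg_summary <- function(records) {
  kd <- records$major_k[records$is_deg]
  kn <- records$major_k[!records$is_deg]
  if (length(kd) == 0 || length(kn) == 0) {
    stop("both DEG and non-DEG groups must be non-empty")
  }
  list(deg_mean = mean(kd), deg_sd = sd(kd),
       nondeg_mean = mean(kn), nondeg_sd = sd(kn),
       p_value = wilcox.test(kd, kn, exact = FALSE)$p.value,
       n_deg = length(kd), n_nondeg = length(kn))
}
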