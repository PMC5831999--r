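# Term enrichment with a detected-gene background and the lncRNA-pathway
# median-similarity criterion.

#' Hypergeometric term enrichment
#'
#' For each term, `p = P(X >= overlap)` with
#' `X ~ Hypergeometric(N = |background|, K = |term & background|,
#' n = |query|)`. A record passes the filter when `p < p_cutoff` and the
#' overlap exceeds `min_overlap` genes. No further multiple-testing
#' correction is applied.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param terms Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the detected-gene universe.
#' @param p_cutoff Enrichment p-value cutoff (default 0.05).
#' @param min_overlap Overlap must be strictly greater than this
#'   (default 4).
#' @return Data frame: `term_id`, `term_size`, `overlap`, `p`,
#'   `passes_filter`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(query, terms, background,
                                      p_cutoff = 0.05, min_overlap = 4) {
  background <- unique(background)
  query <- unique(query)
  missing <- setdiff(query, background)
  if (length(missing)) {
    stop("query gene absent from background: ", missing[1])
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(terms), function(tid) {
    term <- intersect(unique(terms[[tid]]), background)
    K <- length(term)
    k <- length(intersect(term, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_size = K, overlap = k, p = p,
               passes_filter = p < p_cutoff && k > min_overlap,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' lncRNA-pathway similarity against the member median
#'
#' Compares the lncRNA's average network similarity to all protein-coding
#' members of a pathway with the median of the members' own average
#' within-pathway similarities. When the lncRNA's average exceeds that
#' median it displays more network similarity to the pathway than half of
#' the pathway's annotated members, and is selected.
#'
#' @param similarity Network similarity matrix (see
#'   [network_similarity()]).
#' @param lnc_id The lncRNA gene id (must not itself be a pathway member).
#' @param members Character vector of pathway member gene ids (>= 2, all in
#'   the network).
#' @return List: `lnc_avg_similarity`, `member_avg_similarities` (named),
#'   `member_median`, `selected`.
#' @export
lncrna_pathway_similarity <- function(similarity, lnc_id, members) {
  if (lnc_id %in% members) {
    stop("lncRNA ", lnc_id, " is itself a pathway member")
  }
  if (length(members) < 2) stop("pathway needs >= 2 members")
  ids <- rownames(similarity)
  missing <- setdiff(c(lnc_id, members), ids)
  if (length(missing)) stop("gene not in the network: ", missing[1])
  lnc_avg <- mean(similarity[lnc_id, members])
  member_avg <- vapply(members, function(m)
    mean(similarity[m, setdiff(members, m)]), 0)
  med <- median(member_avg)
  list(lnc_avg_similarity = lnc_avg, member_avg_similarities = member_avg,
       member_median = med, selected = lnc_avg > med)
}

#' Evaluate the median-similarity criterion over lncRNAs, pathways and
#' networks
#'
#' @param networks Named list `list(adult = , elderly = )` of similarity
#'   matrices or `NetworkResult` objects.
#' @param lnc_ids Character vector of lncRNA gene ids.
#' @param pathways Named list of pathway member vectors (protein-coding
#'   members; lncRNAs are dropped from each pathway before scoring).
#' @param gene_classes Optional named class vector used to restrict pathway
#'   members to protein-coding genes.
#' @return Data frame: `lnc_id`, `pathway_id`, `lnc_avg_adult`,
#'   `lnc_avg_elderly`, `selected_adult`, `selected_elderly`,
#'   `networks_passing`.
#' @export
pathway_similarity_table <- function(networks, lnc_ids, pathways,
                                     gene_classes = NULL) {
  sim <- lapply(networks, function(x)
    if (inherits(x, "NetworkResult")) x$similarity else x)
  stopifnot(all(AGE_GROUPS %in% names(sim)))
  rows <- list()
  for (pid in names(pathways)) {
    members <- pathways[[pid]]
    if (!is.null(gene_classes)) {
      members <- members[gene_classes[members] == "protein_coding"]
    }
    members <- intersect(members, rownames(sim$adult))
    if (length(members) < 2) next
    for (lnc in lnc_ids) {
      if (!(lnc %in% rownames(sim$adult)) || lnc %in% members) next
      ra <- lncrna_pathway_similarity(sim$adult, lnc, members)
      re <- lncrna_pathway_similarity(sim$elderly, lnc, members)
      rows[[length(rows) + 1]] <- data.frame(
        lnc_id = lnc, pathway_id = pid,
        lnc_avg_adult = ra$lnc_avg_similarity,
        lnc_avg_elderly = re$lnc_avg_similarity,
        selected_adult = ra$selected, selected_elderly = re$selected,
        networks_passing = ra$selected + re$selected,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lnc_id = character(0), pathway_id = character(0),
                      lnc_avg_adult = numeric(0),
                      lnc_avg_elderly = numeric(0),
                      selected_adult = logical(0),
                      selected_elderly = logical(0),
                      networks_passing = integer(0)))
  }
  do.call(rbind, rows)
}

#' Inverted expression pattern between age groups
#'
#' TRUE when the fold-changes sit on strictly opposite sides of 1
#' (up-regulated in sepsis in one age group, down-regulated in the other)
#' and the gene is a DEG in at least one group.
#'
#' @param fc_adult,fc_elderly Linear-scale fold-change vectors.
#' @param deg_adult,deg_elderly Logical DEG flags per group.
#' @return Logical vector.
#' @export
inverted_expression_filter <- function(fc_adult, fc_elderly, deg_adult,
                                       deg_elderly) {
  sign_a <- sign(fc_adult - 1)
  sign_e <- sign(fc_elderly - 1)
  (sign_a * sign_e < 0) & (deg_adult | deg_elderly)
}

#' Candidate lncRNA report
#'
#' Assembles the two candidate tables:
#' \itemize{
#'   \item consistent hubs: lncRNAs among the most connected DEGs that pass
#'     the median-similarity criterion in both networks and are DEGs
#'     deregulated in the same direction in both age groups;
#'   \item age-divergent candidates: lncRNAs among the most differentially
#'     connected DEGs that pass the criterion in at least one network and
#'     show the inverted expression pattern.
#' }
#' The two lists are mutually exclusive by construction (same-direction vs
#' inverted fold-change signs).
#'
#' @param records [cross_network_stats()] data frame.
#' @param degs [call_degs()] data frame.
#' @param sim_table [pathway_similarity_table()] data frame.
#' @param top_connected,top_diffconn Gene-id vectors from
#'   [select_top_connected()] / [select_top_diff_connected()].
#' @param gene_classes Named class vector (reported in the `type` column).
#' @return List with data frames `consistent_hubs` and `age_divergent`,
#'   with connectivity, fold-change and p-value columns per age group.
#' @export
candidate_report <- function(records, degs, sim_table, top_connected,
                             top_diffconn, gene_classes = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(degs),
            is.data.frame(sim_table))
  agg <- function(lncs, need_networks) {
    if (nrow(sim_table) == 0) return(character(0))
    ok <- sim_table$networks_passing >= need_networks
    unique(sim_table$lnc_id[ok & sim_table$lnc_id %in% lncs])
  }
  d <- degs[match(records$gene_id, degs$gene_id), , drop = FALSE]
  same_dir <- d$deg_adult & d$deg_elderly &
    sign(d$fc_adult - 1) * sign(d$fc_elderly - 1) > 0
  inverted <- inverted_expression_filter(d$fc_adult, d$fc_elderly,
                                         d$deg_adult, d$deg_elderly)
  build <- function(ids) {
    i <- match(ids, records$gene_id)
    j <- match(ids, degs$gene_id)
    out <- data.frame(
      gene_id = ids,
      k_elderly = records$k_elderly[i], k_adult = records$k_adult[i],
      type = if (is.null(gene_classes)) NA_character_
      else unname(gene_classes[ids]),
      fc_elderly = degs$fc_elderly[j],
      p_elderly = pmax(degs$p_rp_elderly[j], degs$p_sam_elderly[j]),
      fc_adult = degs$fc_adult[j],
      p_adult = pmax(degs$p_rp_adult[j], degs$p_sam_adult[j]),
      stringsAsFactors = FALSE)
    out[order(-pmax(out$k_elderly, out$k_adult), out$gene_id), ,
        drop = FALSE]
  }
  hubs <- intersect(intersect(top_connected, agg(top_connected, 2)),
                    records$gene_id[same_dir])
  divergent <- intersect(intersect(top_diffconn, agg(top_diffconn, 1)),
                         records$gene_id[inverted])
  list(consistent_hubs = build(hubs), age_divergent = build(divergent))
}
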