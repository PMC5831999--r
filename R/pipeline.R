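# End-to-end orchestration: annotate -> filter -> cluster -> deg ->
# networks -> differential connectivity -> pathway -> cis, with every
# intermediate table written to a run directory and a machine-readable
# summary.

#' Pipeline configuration
#'
#' Collects inputs, thresholds and seeds for [run_pipeline()]. All
#' thresholds default to the analysis' reference values but are
#' configurable; every stochastic stage draws from an explicit seed.
#'
#' @param dataset An [expression_dataset()], or a directory readable by
#'   [read_expression_dataset()].
#' @param pathways Named list of gene sets or a GMT path (optional; pathway
#'   stage skipped without it).
#' @param catalog Gene catalog data frame or NULL (cis stage skipped
#'   without it).
#' @param alignments,annotations Probe alignment/annotation tables or file
#'   paths (optional; reannotation stage skipped without them).
#' @param out_dir Run directory for artifacts.
#' @param alpha DEG cutoff for both tests (default 0.01).
#' @param beta Soft-threshold exponent (default 13).
#' @param top_connected_fraction,top_diffconn_fraction Selection fractions
#'   (defaults 0.15 and 0.20).
#' @param cv_fraction Most-variable fraction for clustering (default 0.05).
#' @param min_detected,group_size Detection-filter parameters (5 of 6).
#' @param n_perm_sam,n_perm_rp Permutation budgets (default 399 each; see
#'   [sam_test()] and [rank_product_test()]).
#' @param n_null_pairs Null pairs for the cis stage (default 1e5).
#' @param compute_tom Store TOM matrices (default FALSE; the selection
#'   statistics use adjacency-based connectivity).
#' @param seed Integer master seed.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(dataset, pathways = NULL, catalog = NULL,
                            alignments = NULL, annotations = NULL,
                            out_dir = tempfile("lncnets_run_"),
                            alpha = 0.01, beta = 13,
                            top_connected_fraction = 0.15,
                            top_diffconn_fraction = 0.20,
                            cv_fraction = 0.05, min_detected = 5,
                            group_size = 6, n_perm_sam = 399,
                            n_perm_rp = 399, n_null_pairs = 1e5,
                            compute_tom = FALSE, seed = 1) {
  for (f in c(top_connected_fraction, top_diffconn_fraction, cv_fraction)) {
    if (!is.numeric(f) || f <= 0 || f > 1) {
      stop("fractions must be in (0, 1]")
    }
  }
  stopifnot(alpha > 0, alpha <= 1, beta >= 1, min_detected >= 1,
            length(seed) == 1, is.finite(seed))
  structure(list(dataset = dataset, pathways = pathways, catalog = catalog,
                 alignments = alignments, annotations = annotations,
                 out_dir = out_dir, alpha = alpha, beta = beta,
                 top_connected_fraction = top_connected_fraction,
                 top_diffconn_fraction = top_diffconn_fraction,
                 cv_fraction = cv_fraction, min_detected = min_detected,
                 group_size = group_size, n_perm_sam = n_perm_sam,
                 n_perm_rp = n_perm_rp, n_null_pairs = n_null_pairs,
                 compute_tom = compute_tom, seed = as.integer(seed)),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes reannotation (optional), detection filtering, UPGMA clustering
#' of the most variable lncRNAs, dual-test DEG calling, the two age-group
#' networks, cross-network differential-connectivity selection, pathway
#' enrichment and the lncRNA-pathway similarity criterion, and the
#' cis-neighbour analysis (optional). Every intermediate table is written
#' under `config$out_dir`; re-running the same config reproduces identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result plus `summary` (the
#'   content of `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  say("lncnets ", as.character(utils::packageVersion("lncnets")),
      " pipeline; seed=", config$seed,
      "; alpha=", config$alpha, "; beta=", config$beta)

  annotation <- NULL
  if (!is.null(config$alignments) && !is.null(config$annotations)) {
    annotation <- stage("annotate", {
      al <- config$alignments
      if (is.character(al)) al <- read_probe_alignments(al)
      an <- config$annotations
      if (is.character(an)) an <- read_gene_annotation(an)
      res <- annotate_platform(al, an)
      write_probe_annotation(res, config$out_dir)
      say("annotate: ", res$summary[["approved"]], "/",
          res$summary[["total"]], " probes approved")
      res
    })
  }

  ds <- stage("load", {
    d <- config$dataset
    if (is.character(d)) d <- read_expression_dataset(d)
    stopifnot(inherits(d, "ExpressionDataset"))
    d
  })

  filtered <- stage("filter", {
    f <- detection_filter(ds, config$min_detected, config$group_size)
    write_tsv(f$genes, file.path(config$out_dir, "detected_genes.tsv"))
    say("filter: ", nrow(f$ratios), "/", nrow(ds$ratios),
        " genes detected")
    f
  })

  clust <- stage("cluster", {
    var_lnc <- select_most_variable(filtered, classes = "lncRNA",
                                    fraction = config$cv_fraction)
    if (length(var_lnc) >= 2) {
      cl <- upgma_cluster(filtered, var_lnc)
      writeLines(cl$newick, file.path(config$out_dir,
                                      "lnc_sample_tree.nwk"))
      cut2 <- cut_sample_tree(cl, 2)
      conc <- cluster_concordance(cut2, filtered$samples$status)
      say("cluster: ", length(var_lnc),
          " variable lncRNAs; 2-cut status concordance ",
          sprintf("%.3f", conc))
      list(genes = var_lnc, clustering = cl, concordance = conc)
    } else NULL
  })

  degs <- stage("deg", {
    d <- differential_expression(filtered, alpha = config$alpha,
                                 n_perm_sam = config$n_perm_sam,
                                 n_perm_rp = config$n_perm_rp,
                                 seed = config$seed)
    write_tsv(cbind(filtered$genes["class"], d)[
      , c("gene_id", "class", "fc_adult", "fc_elderly", "p_rp_adult",
          "p_rp_elderly", "p_sam_adult", "p_sam_elderly", "deg_adult",
          "deg_elderly", "deg_any")],
      file.path(config$out_dir, "deg_table.tsv"))
    say("deg: adult=", sum(d$deg_adult), " elderly=", sum(d$deg_elderly),
        " union=", sum(d$deg_any))
    d
  })

  nets <- stage("network", {
    n <- lapply(setNames(AGE_GROUPS, AGE_GROUPS), function(g)
      build_network(filtered, g, beta = config$beta,
                    tom = config$compute_tom))
    for (g in AGE_GROUPS) {
      write_tsv(data.frame(gene_id = names(n[[g]]$connectivity),
                           k = unname(n[[g]]$connectivity)),
                file.path(config$out_dir,
                          sprintf("connectivity_%s.tsv", g)))
    }
    n
  })

  dc <- stage("diffconn", {
    rec <- cross_network_stats(nets$adult$connectivity,
                               nets$elderly$connectivity,
                               deg = degs$gene_id[degs$deg_any])
    top_k <- select_top_connected(rec, config$top_connected_fraction)
    top_dc <- select_top_diff_connected(rec,
                                        config$top_diffconn_fraction)
    summ <- connectivity_by_deg_summary(rec)
    write_tsv(rec, file.path(config$out_dir, "cross_network.tsv"))
    writeLines(top_k, file.path(config$out_dir, "top_connected.txt"))
    writeLines(top_dc, file.path(config$out_dir, "top_diffconn.txt"))
    say("diffconn: DEG mean k=", sprintf("%.1f", summ$deg_mean),
        " non-DEG mean k=", sprintf("%.1f", summ$nondeg_mean),
        " p=", format(summ$p_value, digits = 3))
    list(records = rec, top_connected = top_k, top_diffconn = top_dc,
         summary = summ)
  })

  classes <- setNames(filtered$genes$class, filtered$genes$gene_id)
  path_res <- NULL
  if (!is.null(config$pathways)) {
    path_res <- stage("pathway", {
      pws <- config$pathways
      if (is.character(pws)) pws <- read_gmt(pws)
      bg <- filtered$genes$gene_id
      pws <- lapply(pws, intersect, y = bg)
      enr <- hypergeometric_enrichment(dc$top_connected, pws, bg)
      lncs <- names(classes)[classes %in% c("lncRNA", "pseudogene")]
      lncs <- intersect(lncs, union(dc$top_connected, dc$top_diffconn))
      sim <- pathway_similarity_table(nets, lncs, pws,
                                      gene_classes = classes)
      cand <- candidate_report(dc$records, degs, sim, dc$top_connected,
                               dc$top_diffconn, gene_classes = classes)
      write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
      write_tsv(sim, file.path(config$out_dir, "pathway_similarity.tsv"))
      write_tsv(cand$consistent_hubs,
                file.path(config$out_dir, "candidates_consistent.tsv"))
      write_tsv(cand$age_divergent,
                file.path(config$out_dir, "candidates_divergent.tsv"))
      say("pathway: ", sum(enr$passes_filter), " enriched terms; ",
          nrow(cand$consistent_hubs), " consistent-hub and ",
          nrow(cand$age_divergent), " age-divergent candidate lncRNAs")
      list(enrichment = enr, similarity = sim, candidates = cand)
    })
  }

  cis_res <- NULL
  if (!is.null(config$catalog)) {
    cis_res <- stage("cis", {
      de_lncs <- degs$gene_id[degs$deg_any &
                                classes[degs$gene_id] == "lncRNA"]
      pairs <- nearest_protein_coding(config$catalog,
                                      lnc_ids = de_lncs)
      pairs <- pair_correlation_significance(
        pairs, filtered, n_null_pairs = config$n_null_pairs,
        seed = config$seed + 2, alpha = config$alpha)
      prox <- proximal_subset(pairs)
      write_tsv(pairs, file.path(config$out_dir, "cis_pairs.tsv"))
      say("cis: ", nrow(pairs), " DE lncRNA-neighbour pairs, ",
          sum(pairs$significant), " significant, ",
          nrow(prox), " proximal (<4 kb)")
      list(pairs = pairs, proximal = prox)
    })
  }

  summary <- list(
    n_genes_input = nrow(ds$ratios),
    n_detected = nrow(filtered$ratios),
    detected_by_class = as.list(table(filtered$genes$class)),
    n_variable_lncRNAs = if (is.null(clust)) 0L else length(clust$genes),
    cluster_status_concordance = if (is.null(clust)) NULL
    else clust$concordance,
    n_deg_adult = sum(degs$deg_adult),
    n_deg_elderly = sum(degs$deg_elderly),
    n_deg_union = sum(degs$deg_any),
    deg_mean_major_k = dc$summary$deg_mean,
    deg_sd_major_k = dc$summary$deg_sd,
    nondeg_mean_major_k = dc$summary$nondeg_mean,
    nondeg_sd_major_k = dc$summary$nondeg_sd,
    deg_connectivity_p = dc$summary$p_value,
    n_top_connected = length(dc$top_connected),
    n_top_diffconn = length(dc$top_diffconn),
    candidates_consistent = if (is.null(path_res)) character(0)
    else path_res$candidates$consistent_hubs$gene_id,
    candidates_divergent = if (is.null(path_res)) character(0)
    else path_res$candidates$age_divergent$gene_id,
    n_cis_pairs = if (is.null(cis_res)) 0L else nrow(cis_res$pairs),
    n_cis_significant = if (is.null(cis_res)) 0L
    else sum(cis_res$pairs$significant),
    parameters = config[c("alpha", "beta", "top_connected_fraction",
                          "top_diffconn_fraction", "cv_fraction",
                          "min_detected", "group_size", "n_perm_sam",
                          "n_perm_rp", "n_null_pairs", "seed")])
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(annotation = annotation, dataset = ds,
                 filtered = filtered, clustering = clust, degs = degs,
                 networks = nets, diffconn = dc, pathway = path_res,
                 cis = cis_res, summary = summary))
}

#' Concordance of a 2-cluster cut with a binary label
#'
#' Fraction of samples on the majority diagonal of the cluster x label
#' table, maximised over the two label-to-cluster assignments. 1 means the
#' cut separates the labels perfectly.
#'
#' @param clusters Integer cluster memberships (2 clusters).
#' @param labels Binary sample labels (e.g. sepsis/control).
#' @return Numeric scalar in `[0.5, 1]`.
#' @export
cluster_concordance <- function(clusters, labels) {
  tab <- table(clusters, labels)
  if (any(dim(tab) != c(2, 2))) return(NA_real_)
  max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
}
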