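test_that("hypergeometric enrichment reproduces the exact tail sum", {
  bg <- sprintf("g%02d", 1:10)
  terms <- list(t1 = bg[1:4])
  res <- hypergeometric_enrichment(bg[1:5], terms, bg)
  # N=10, K=4, n=5, overlap depends on construction: term 1:4, query 1:5
  expect_equal(res$overlap, 4)
  res2 <- hypergeometric_enrichment(c(bg[1:3], bg[9:10]), terms, bg)
  expect_equal(res2$overlap, 3)
  expect_equal(res2$p, 11 / 42, tolerance = 1e-12)   # 66/252 by hand
  # zero overlap: P(X >= 0) = 1
  res3 <- hypergeometric_enrichment(bg[9:10], list(t1 = bg[1:4]), bg)
  expect_equal(res3$p, 1)
  # a term of size 4 can never pass the >4 overlap filter
  tiny <- hypergeometric_enrichment(bg[1:4], list(t1 = bg[1:4]), bg)
  expect_lt(tiny$p, 0.01)
  expect_false(tiny$passes_filter)
  expect_error(hypergeometric_enrichment(c(bg[1], "zz"), terms, bg), "zz")
})

test_that("enrichment p decreases monotonically in the overlap", {
  N <- 50; K <- 12; n <- 10
  ps <- vapply(0:10, function(k)
    phyper(k - 1, K, N - K, n, lower.tail = FALSE), 0)
  expect_true(all(diff(ps) < 0))
  # same behaviour through the package entry point
  bg <- sprintf("g%02d", 1:50)
  p_at <- function(k) {
    query <- c(bg[seq_len(k)], bg[13:(13 + (10 - k) - 1)])
    hypergeometric_enrichment(query, list(t = bg[1:12]), bg)$p
  }
  expect_true(p_at(8) < p_at(5))
})

test_that("the median-similarity criterion selects wired lncRNAs", {
  # hand example: lnc averages 0.5 against member averages {0.2, 0.4, 0.6}
  a <- diag(4)
  dimnames(a) <- list(c("L", "m1", "m2", "m3"), c("L", "m1", "m2", "m3"))
  a["L", c("m1", "m2", "m3")] <- a[c("m1", "m2", "m3"), "L"] <- 0.5
  a["m1", "m2"] <- a["m2", "m1"] <- 0.1
  a["m1", "m3"] <- a["m3", "m1"] <- 0.3
  a["m2", "m3"] <- a["m3", "m2"] <- 0.7
  # member averages: m1 = 0.2, m2 = 0.4, m3 = 0.5 -> median 0.4
  r <- lncrna_pathway_similarity(a, "L", c("m1", "m2", "m3"))
  expect_equal(r$lnc_avg_similarity, 0.5)
  expect_equal(r$member_median, 0.4)
  expect_true(r$selected)
  # a fully disconnected lncRNA is never selected over a connected core
  a0 <- a; a0["L", -1] <- a0[-1, "L"] <- 0
  expect_false(lncrna_pathway_similarity(a0, "L",
                                         c("m1", "m2", "m3"))$selected)
  expect_error(lncrna_pathway_similarity(a, "m1", c("m1", "m2")), "member")
  expect_error(lncrna_pathway_similarity(a, "L", "m1"), ">= 2")
})

test_that("inverted-pattern detection needs opposite signs and a DEG call", {
  fc_a <- c(1.86, 0.4, 1.0, 1.5)
  fc_e <- c(0.97, 0.4, 0.8, 0.5)
  deg_a <- c(TRUE, TRUE, TRUE, FALSE)
  deg_e <- c(FALSE, TRUE, TRUE, FALSE)
  inv <- inverted_expression_filter(fc_a, fc_e, deg_a, deg_e)
  expect_equal(inv, c(TRUE, FALSE, FALSE, FALSE))
  # fc exactly 1 has no direction even with DEG support elsewhere
  expect_false(inverted_expression_filter(1.0, 0.5, TRUE, TRUE))
})

test_that("candidate tables split consistent hubs from inverted lncRNAs", {
  gen <- generate_expression_dataset(sepsis_study_config(n_genes = 800,
                                                         seed = 9))
  ds <- detection_filter(gen$dataset)
  d <- differential_expression(ds, seed = 90)
  na <- build_network(ds, "adult", tom = FALSE)
  ne <- build_network(ds, "elderly", tom = FALSE)
  rec <- cross_network_stats(na$connectivity, ne$connectivity,
                             deg = d$gene_id[d$deg_any])
  cls <- setNames(ds$genes$class, ds$genes$gene_id)
  topk <- select_top_connected(rec)
  topd <- select_top_diff_connected(rec)
  sim <- pathway_similarity_table(
    list(adult = na, elderly = ne),
    intersect(c(gen$truth$true_hub_lncRNAs,
                gen$truth$true_diffconnected_lncRNAs),
              ds$genes$gene_id),
    gen$truth$module_pathways, gene_classes = cls)
  cand <- candidate_report(rec, d, sim, topk, topd, gene_classes = cls)
  # the two lists are disjoint by construction
  expect_length(intersect(cand$consistent_hubs$gene_id,
                          cand$age_divergent$gene_id), 0)
  # both-group hubs go to the consistent list only
  expect_true(all(cand$consistent_hubs$gene_id %in%
                    gen$truth$true_hub_lncRNAs))
  expect_false(any(gen$truth$true_hub_lncRNAs %in%
                     cand$age_divergent$gene_id))
  # single-group module lncRNAs with opposite shifts go to the divergent
  # list only
  expect_true(all(cand$age_divergent$gene_id %in%
                    gen$truth$true_diffconnected_lncRNAs))
  expect_gt(nrow(cand$age_divergent), 0)
  # empty upstream selections give empty reports without error
  none <- candidate_report(rec, d, sim, character(0), character(0),
                           gene_classes = cls)
  expect_equal(nrow(none$consistent_hubs), 0)
  expect_equal(nrow(none$age_divergent), 0)
})
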