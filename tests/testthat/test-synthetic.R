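test_that("generation is deterministic under a fixed seed", {
  cfg <- sepsis_study_config(n_genes = 800, seed = 7)
  g1 <- generate_expression_dataset(cfg)
  g2 <- generate_expression_dataset(cfg)
  expect_identical(g1$dataset$ratios, g2$dataset$ratios)
  expect_identical(g1$dataset$flags, g2$dataset$flags)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_expression_dataset(sepsis_study_config(n_genes = 800,
                                                        seed = 8))
  expect_false(identical(g1$dataset$ratios, g3$dataset$ratios))
})

test_that("a shift-free module realizes its target correlation", {
  # 50-gene module, latent_cor 0.9, active in both groups, no planted
  # fold-changes: mean within-module |r| must sit in [0.85, 0.95]
  mean_r <- vapply(1:10, function(s) {
    ids <- sprintf("g%05d", 1:200)
    cfg <- synthetic_config(
      200, modules = list(planted_module(ids[1:50], 0.9,
                                         c("adult", "elderly"))),
      seed = s)
    ds <- generate_expression_dataset(cfg)$dataset
    r <- cor(t(log2(ds$ratios[1:50, 1:12])))
    mean(abs(r[upper.tri(r)]))
  }, 0)
  expect_gt(mean(mean_r), 0.85)
  expect_lt(mean(mean_r), 0.95)
})

test_that("the global null has no planted correlation", {
  mean_r <- vapply(1:5, function(s) {
    ds <- generate_expression_dataset(
      global_null_config(n_genes = 100, seed = s))$dataset
    r <- cor(t(log2(ds$ratios[, 1:12])))
    mean(abs(r[upper.tri(r)]))
  }, 0)
  expect_lt(mean(mean_r), 0.25)
})

test_that("planted fold-changes are recovered in the noise-free limit", {
  ids <- sprintf("g%05d", 1:50)
  cfg <- synthetic_config(
    50, deg_effects = list(deg_effect(ids[1:10], -2, "adult")),
    noise_sd = 1e-4, seed = 1)
  ds <- generate_expression_dataset(cfg)$dataset
  fc <- fold_change(ds, "adult")
  expect_equal(unname(fc[1:10]), rep(0.25, 10), tolerance = 1e-3)
  expect_equal(unname(fc[11:50]), rep(1, 40), tolerance = 1e-3)
  expect_equal(unname(fold_change(ds, "elderly")[1:10]), rep(1, 10),
               tolerance = 1e-3)
})

test_that("invalid configurations are rejected with the offending gene", {
  ids <- sprintf("g%05d", 1:100)
  expect_error(synthetic_config(100, n_per_cell = 1), "n_per_cell")
  expect_error(synthetic_config(100, noise_sd = 0), "noise_sd")
  expect_error(
    synthetic_config(100, deg_effects = list(
      deg_effect(ids[1:5], 2, "adult"),
      deg_effect(ids[4:8], -1, c("adult", "elderly")))),
    "g00004")
  expect_error(
    synthetic_config(100, modules = list(
      planted_module(ids[1:10], 0.9, "adult"),
      planted_module(ids[10:20], 0.9, "elderly"))),
    "g00010")
})

test_that("planted genes are always detected; background follows the rate", {
  ids <- sprintf("g%05d", 1:400)
  cfg <- synthetic_config(
    400, modules = list(planted_module(ids[1:30], 0.9, "adult")),
    deg_effects = list(deg_effect(ids[31:60], 2, "elderly")),
    background_detect_rate = 0.3, seed = 3)
  ds <- generate_expression_dataset(cfg)$dataset
  expect_true(all(ds$flags[1:60, ]))
  frac_full <- mean(apply(ds$flags[61:400, ], 1, all))
  expect_gt(frac_full, 0.15); expect_lt(frac_full, 0.45)
})

test_that("ground truth records every planted structure", {
  cfg <- sepsis_study_config(n_genes = 800, seed = 2)
  tr <- generate_expression_dataset(cfg)$truth
  expect_length(tr$true_hub_lncRNAs, 3)
  expect_length(tr$true_diffconnected_lncRNAs, 3)
  expect_setequal(names(tr$true_module_membership),
                  c("translation", "respiration"))
  # module pathways exclude the lncRNA hubs
  expect_false(any(tr$true_hub_lncRNAs %in%
                     tr$module_pathways$translation))
  # every gene with a planted shift is flagged as a true DEG
  expect_setequal(tr$true_deg_flags$adult,
                  names(which(tr$planted_log2fc$adult != 0)))
})

test_that("the gene catalog honours forced neighbour pairs", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      class = rep(c("protein_coding", "lncRNA"), 30),
                      stringsAsFactors = FALSE)
  pair_up <- data.frame(lnc = c("g002", "g004"), pc = c("g001", "g013"),
                        gap = c(1500, 5000), stringsAsFactors = FALSE)
  cat1 <- generate_gene_catalog(genes, seed = 5, pair_up = pair_up)
  expect_setequal(cat1$gene_id, genes$gene_id)
  near <- nearest_protein_coding(cat1, lnc_ids = c("g002", "g004"))
  expect_equal(near$neighbor_id, c("g001", "g013"))
  expect_equal(near$distance, c(1500, 5000))
  expect_identical(cat1, generate_gene_catalog(genes, seed = 5,
                                               pair_up = pair_up))
})
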