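test_that("fold-changes behave as ratio averages on the log scale", {
  set.seed(4)
  X <- matrix(rnorm(20 * 24), 20, 24)
  X[, 1:6] <- X[, 7:12]      # adult sepsis identical to adult control
  ds <- make_dataset(X)
  expect_equal(unname(fold_change(ds, "adult")), rep(1, 20))
  # swapping arms inverts the fold-change
  swap <- X[, c(7:12, 1:6, 19:24, 13:18)]
  fc1 <- fold_change(make_dataset(X), "elderly")
  fc2 <- fold_change(make_dataset(swap), "elderly")
  expect_equal(unname(fc1), 1 / unname(fc2), tolerance = 1e-12)
})

test_that("SAM p-values equal exhaustive enumeration on a 3v3 toy", {
  set.seed(5)
  G <- 12
  X <- matrix(rnorm(G * 6, sd = 0.4), G, 6)
  X[1, 1:3] <- X[1, 1:3] + 3         # one shifted gene
  ds <- toy_group_dataset(X, n_per_cell = 3)
  res <- sam_test(ds, "adult", n_perm = 30, seed = 1)
  want <- oracle_sam(X, 3, s0 = res$s0[1])
  expect_equal(res$p, want, tolerance = 1e-12)
  expect_true(res$p[1] == min(res$p))
  # each labeling ties its complement at equal |d|: the floor is 2/20
  expect_equal(min(res$p), 2 / choose(6, 3))
})

test_that("SAM handles degenerate genes and guards n_perm", {
  X <- matrix(rnorm(5 * 6), 5, 6)
  X[1, ] <- rep(c(1, 2, 3), 2)       # identical values in both arms
  ds <- toy_group_dataset(X, n_per_cell = 3)
  res <- sam_test(ds, "adult", n_perm = 30)
  expect_equal(res$d[1], 0)
  expect_equal(res$p[1], 1)
  expect_error(sam_test(ds, "adult", n_perm = 5), "n_perm")
})

test_that("rank products match hand enumeration on a 2v2 toy", {
  # 3 genes, 2v2: rank product of gene 1 over the 4 pairings by hand
  X <- rbind(c(5, 6, 1, 2),
             c(1, 2, 5, 6),
             c(3, 3.5, 3.2, 3.1))
  ds <- toy_group_dataset(X, n_per_cell = 2)
  res <- rank_product_test(ds, "adult", n_perm = 10, seed = 1)
  # gene 1 is up in every pairing: diffs largest -> up-rank 1 everywhere
  expect_equal(res$rp_up[1], 1)
  expect_equal(res$rp_down[2], oracle_rp_stat(X, 1:2, 3:4)$down[2])
  want <- oracle_rp_pvalues(X, 2)
  expect_equal(res$p, want, tolerance = 1e-12)
  expect_equal(res$direction[1:2], c("up", "down"))
})

test_that("rank-product p-values are invariant to gene-wise rescaling", {
  set.seed(6)
  X <- matrix(rnorm(15 * 12), 15, 12)
  ds1 <- toy_group_dataset(X, n_per_cell = 6)
  scale_fact <- runif(15, 0.2, 5)
  ds2 <- toy_group_dataset(X + log2(scale_fact), n_per_cell = 6)
  r1 <- rank_product_test(ds1, "adult", n_perm = 50, seed = 3)
  r2 <- rank_product_test(ds2, "adult", n_perm = 50, seed = 3)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$rp_up, r2$rp_up, tolerance = 1e-12)
})

test_that("DEG calls require both tests at the cutoff", {
  mk <- function(p_rp, p_sam) {
    ids <- "g1"
    rp <- list(adult = data.frame(gene_id = ids, p = p_rp[1]),
               elderly = data.frame(gene_id = ids, p = p_rp[2]))
    sam <- list(adult = data.frame(gene_id = ids, p = p_sam[1]),
                elderly = data.frame(gene_id = ids, p = p_sam[2]))
    fc <- list(adult = c(g1 = 2), elderly = c(g1 = 2))
    call_degs(rp, sam, fc)
  }
  expect_false(mk(c(0.005, 1), c(0.02, 1))$deg_adult)   # one test misses
  expect_true(mk(c(0.01, 1), c(0.01, 1))$deg_adult)     # boundary: <=
  expect_false(mk(c(0.01, 1), c(0.01, 1))$deg_elderly)
  bad_rp <- list(adult = data.frame(gene_id = "gX", p = 0.5),
                 elderly = data.frame(gene_id = "g1", p = 0.5))
  sam <- list(adult = data.frame(gene_id = "g1", p = 0.5),
              elderly = data.frame(gene_id = "g1", p = 0.5))
  fc <- list(adult = c(g1 = 2), elderly = c(g1 = 2))
  expect_error(call_degs(bad_rp, sam, fc), "universes")
})

test_that("planted effects are recovered with high sensitivity", {
  gen <- generate_expression_dataset(sepsis_study_config(seed = 6))
  ds <- detection_filter(gen$dataset)
  d <- differential_expression(ds, seed = 60)
  tr_a <- names(which(abs(gen$truth$planted_log2fc$adult) >= 1.5))
  sens <- mean(tr_a %in% d$gene_id[d$deg_adult])
  expect_gt(sens, 0.85)
  fp <- sum(d$deg_adult & !(d$gene_id %in% gen$truth$true_deg_flags$adult))
  expect_lt(fp / sum(!(d$gene_id %in% gen$truth$true_deg_flags$adult)),
            0.05)
})
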