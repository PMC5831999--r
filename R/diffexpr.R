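# Differential expression within one age group: a SAM-style moderated
# t-statistic and a rank-product statistic, both with p-values from the
# orbit of sepsis/control label assignments (enumerated exhaustively when
# the orbit is no larger than n_perm, sampled otherwise).

group_matrix <- function(ds, age_group) {
  stopifnot(age_group %in% AGE_GROUPS)
  sep <- sample_index(ds, age_group, "sepsis")
  ctl <- sample_index(ds, age_group, "control")
  if (length(sep) == 0 || length(ctl) == 0) {
    stop("age group ", age_group, " must contain sepsis and control samples")
  }
  list(X = log2_ratios(ds)[, c(sep, ctl), drop = FALSE],
       n1 = length(sep), n2 = length(ctl))
}

# label assignments: matrix with one row per labeling of which columns are
# "sepsis"; first row is always the observed labeling (1..n1). When the
# orbit is no larger than n_perm all labelings are used (exhaustive, exact
# p = c/B); otherwise n_perm non-observed labelings are drawn without
# replacement from the enumerated orbit (p = (1 + c)/(1 + n_perm), exactly
# uniform under the null), falling back to with-replacement draws when the
# orbit is too large to enumerate.
status_labelings <- function(n1, n2, n_perm, seed) {
  n <- n1 + n2
  total <- choose(n, n1)
  if (total <= 1e5) {
    labs <- t(combn(n, n1))
    obs <- which(apply(labs, 1, function(r) all(r == seq_len(n1))))
    rest <- labs[-obs, , drop = FALSE]
    if (total <= n_perm) {
      return(list(labs = rbind(seq_len(n1), rest), exhaustive = TRUE))
    }
    set.seed(seed)
    pick <- sample(nrow(rest), n_perm)
    list(labs = rbind(seq_len(n1), rest[pick, , drop = FALSE]),
         exhaustive = FALSE)
  } else {
    set.seed(seed)
    labs <- t(replicate(n_perm, sort(sample(n, n1))))
    list(labs = rbind(seq_len(n1), labs), exhaustive = FALSE)
  }
}

#' Average sepsis/control fold-change per gene
#'
#' `fc = 2^(mean log2 ratio in sepsis - mean log2 ratio in control)` over
#' the samples of one age group.
#'
#' @param ds An [expression_dataset()].
#' @param age_group `"adult"` or `"elderly"`.
#' @return Named numeric vector of linear-scale fold-changes.
#' @export
fold_change <- function(ds, age_group) {
  g <- group_matrix(ds, age_group)
  fc <- 2^(rowMeans(g$X[, seq_len(g$n1), drop = FALSE]) -
             rowMeans(g$X[, g$n1 + seq_len(g$n2), drop = FALSE]))
  setNames(fc, ds$genes$gene_id)
}

#' SAM-style permutation test for differential expression
#'
#' Computes, per gene, `d = (mean_sepsis - mean_control) / (s + s0)` on the
#' log2 scale, where `s` is the pooled standard error and the
#' exchangeability constant `s0` is the median of `s` over genes. The
#' two-sided p-value is the fraction of sepsis/control label assignments
#' (within the age group) whose `|d*|` reaches the observed `|d|`; all
#' `choose(n, n_sepsis)` assignments are enumerated when that count is at
#' most `n_perm`, otherwise `n_perm` random assignments are drawn and
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param ds An [expression_dataset()].
#' @param age_group `"adult"` or `"elderly"`.
#' @param n_perm Permutation budget (default 399; >= 10). When the orbit of
#'   distinct assignments is no larger than `n_perm` it is enumerated
#'   exhaustively; for the 6 vs 6 study design the default samples 399 of
#'   the 923 non-observed assignments without replacement, which places the
#'   attainable null rate at the 0.01 cutoff at 0.01 itself (for `n1 = n2`
#'   the orbit pairs each labeling with its complement at equal `|d|`, so
#'   exhaustive two-sided rates fall on a coarser, conservative grid).
#' @param seed Integer seed (used only when sampling).
#' @param s0 Optional fixed exchangeability constant (default: median of
#'   the observed per-gene standard errors).
#' @return Data frame: `gene_id`, `d`, `s`, `s0`, `p`.
#' @export
sam_test <- function(ds, age_group, n_perm = 399, seed = 1, s0 = NULL) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  g <- group_matrix(ds, age_group)
  if (g$n1 < 2 || g$n2 < 2) stop("need >= 2 samples per arm")
  X <- g$X; n1 <- g$n1; n2 <- g$n2; n <- n1 + n2
  lab <- status_labelings(n1, n2, n_perm, seed)
  B <- nrow(lab$labs)
  L <- matrix(0, B, n)
  L[cbind(rep(seq_len(B), n1), as.vector(lab$labs))] <- 1
  S1 <- X %*% t(L)
  tot <- rowSums(X)
  M1 <- S1 / n1
  M2 <- (tot - S1) / n2
  SS <- pmax(rowSums(X^2) - n1 * M1^2 - n2 * M2^2, 0)
  s_all <- sqrt((1 / n1 + 1 / n2) * SS / (n - 2))
  if (is.null(s0)) s0 <- median(s_all[, 1])
  D <- (M1 - M2) / (s_all + s0)
  d_obs <- D[, 1]
  count <- rowSums(abs(D) >= abs(d_obs) - 1e-12)
  data.frame(gene_id = ds$genes$gene_id, d = d_obs, s = s_all[, 1], s0 = s0,
             p = count / B, stringsAsFactors = FALSE)
}

rp_stats <- function(X, sepsis_cols, control_cols) {
  G <- nrow(X)
  si <- rep(sepsis_cols, times = length(control_cols))
  ci <- rep(control_cols, each = length(sepsis_cols))
  D <- X[, si, drop = FALSE] - X[, ci, drop = FALSE]
  R <- apply(D, 2, rank)
  if (!is.matrix(R)) R <- matrix(R, nrow = G)
  list(down = exp(rowMeans(log(R))),
       up = exp(rowMeans(log(G + 1 - R))))
}

#' Rank-product permutation test for differential expression
#'
#' For each of the `n_sepsis x n_control` sample pairings within an age
#' group, genes are ranked by the pairwise log2 ratio (ascending for
#' down-regulation, descending for up-regulation); the rank product is the
#' geometric mean of a gene's ranks over all pairings. The null
#' distribution is generated by re-deriving the rank products under
#' sepsis/control label assignments (the same orbit as [sam_test()], which
#' preserves the dependence between pairings sharing a sample);
#' `p_up`/`p_down` count assignments whose rank product is at most the
#' observed one, and the reported two-sided `p` is
#' `min(1, 2 * min(p_up, p_down))` with the direction recorded.
#'
#' @inheritParams sam_test
#' @param n_perm Permutation budget (default 399, so that with the doubled
#'   two-sided p-value the attainable null rate at the 0.01 cutoff is
#'   exactly 0.01; >= 10).
#' @return Data frame: `gene_id`, `rp_up`, `rp_down`, `p_up`, `p_down`,
#'   `p`, `direction`.
#' @export
rank_product_test <- function(ds, age_group, n_perm = 399, seed = 1) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  g <- group_matrix(ds, age_group)
  if (g$n1 < 2 || g$n2 < 2) stop("need >= 2 samples per arm")
  X <- g$X; n1 <- g$n1; n2 <- g$n2; n <- n1 + n2
  lab <- status_labelings(n1, n2, n_perm, seed)
  B <- nrow(lab$labs)
  obs <- rp_stats(X, seq_len(n1), n1 + seq_len(n2))
  cnt_up <- rep(0L, nrow(X)); cnt_dn <- rep(0L, nrow(X))
  for (b in seq_len(B)) {
    sep <- lab$labs[b, ]
    st <- rp_stats(X, sep, setdiff(seq_len(n), sep))
    cnt_up <- cnt_up + (st$up <= obs$up + 1e-12)
    cnt_dn <- cnt_dn + (st$down <= obs$down + 1e-12)
  }
  p_up <- cnt_up / B
  p_down <- cnt_dn / B
  p <- pmin(1, 2 * pmin(p_up, p_down))
  data.frame(gene_id = ds$genes$gene_id, rp_up = obs$up,
             rp_down = obs$down, p_up = p_up, p_down = p_down, p = p,
             direction = ifelse(p_up <= p_down, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG in an age group when both the rank-product and the
#' SAM-style p-values are at most `alpha` (default 0.01).
#'
#' @param rp Named list `list(adult = , elderly = )` of
#'   [rank_product_test()] results.
#' @param sam Named list of [sam_test()] results.
#' @param fc Named list of [fold_change()] vectors.
#' @param alpha Significance cutoff applied to both tests (default 0.01).
#' @return Data frame (one row per gene): `gene_id`, `fc_adult`,
#'   `fc_elderly`, `p_rp_adult`, `p_rp_elderly`, `p_sam_adult`,
#'   `p_sam_elderly`, `deg_adult`, `deg_elderly`, `deg_any`.
#' @export
call_degs <- function(rp, sam, fc, alpha = 0.01) {
  stopifnot(all(AGE_GROUPS %in% names(rp)), all(AGE_GROUPS %in% names(sam)),
            all(AGE_GROUPS %in% names(fc)))
  ids <- rp$adult$gene_id
  for (x in list(rp$elderly$gene_id, sam$adult$gene_id,
                 sam$elderly$gene_id, names(fc$adult), names(fc$elderly))) {
    if (!identical(as.character(x), as.character(ids))) {
      stop("mismatched gene universes across test results")
    }
  }
  deg_a <- rp$adult$p <= alpha & sam$adult$p <= alpha
  deg_e <- rp$elderly$p <= alpha & sam$elderly$p <= alpha
  data.frame(gene_id = ids,
             fc_adult = unname(fc$adult), fc_elderly = unname(fc$elderly),
             p_rp_adult = rp$adult$p, p_rp_elderly = rp$elderly$p,
             p_sam_adult = sam$adult$p, p_sam_elderly = sam$elderly$p,
             deg_adult = deg_a, deg_elderly = deg_e,
             deg_any = deg_a | deg_e,
             stringsAsFactors = FALSE)
}

#' Run both differential-expression tests for both age groups
#'
#' Convenience wrapper: fold-changes, [sam_test()] and
#' [rank_product_test()] per age group, combined by [call_degs()].
#'
#' @param ds An [expression_dataset()] (normally detection-filtered).
#' @param alpha DEG cutoff applied to both tests (default 0.01).
#' @param n_perm_sam,n_perm_rp Permutation budgets.
#' @param seed Integer seed.
#' @return The [call_degs()] data frame.
#' @export
differential_expression <- function(ds, alpha = 0.01, n_perm_sam = 399,
                                    n_perm_rp = 399, seed = 1) {
  fc <- lapply(setNames(AGE_GROUPS, AGE_GROUPS),
               function(g) fold_change(ds, g))
  sam <- lapply(setNames(AGE_GROUPS, AGE_GROUPS),
                function(g) sam_test(ds, g, n_perm = n_perm_sam,
                                     seed = seed))
  rp <- lapply(setNames(AGE_GROUPS, AGE_GROUPS),
               function(g) rank_product_test(ds, g, n_perm = n_perm_rp,
                                             seed = seed + 1))
  call_degs(rp, sam, fc, alpha)
}
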