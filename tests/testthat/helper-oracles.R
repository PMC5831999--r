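# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. These deliberately re-derive every quantity
# with naive loops, separate from the package's vectorised implementations.

# -- dataset builders --------------------------------------------------------

make_dataset <- function(log2mat, n_per_cell = NULL, flags = NULL,
                         classes = NULL) {
  # columns ordered adult-sepsis, adult-control, elderly-sepsis,
  # elderly-control, n_per_cell each
  S <- ncol(log2mat)
  if (is.null(n_per_cell)) n_per_cell <- S / 4
  stopifnot(S == 4 * n_per_cell)
  ids <- if (is.null(rownames(log2mat)))
    sprintf("g%03d", seq_len(nrow(log2mat))) else rownames(log2mat)
  sample_ids <- paste0(rep(c("sa", "ca", "se", "ce"), each = n_per_cell),
                       seq_len(n_per_cell))
  dimnames(log2mat) <- list(ids, sample_ids)
  samples <- data.frame(
    sample_id = sample_ids,
    age_group = rep(c("adult", "adult", "elderly", "elderly"),
                    each = n_per_cell),
    status = rep(c("sepsis", "control", "sepsis", "control"),
                 each = n_per_cell),
    stringsAsFactors = FALSE)
  if (is.null(flags)) {
    flags <- matrix(TRUE, nrow(log2mat), S, dimnames = dimnames(log2mat))
  }
  if (is.null(classes)) classes <- rep("protein_coding", nrow(log2mat))
  expression_dataset(2^log2mat, flags, samples,
                     data.frame(gene_id = ids, class = classes,
                                stringsAsFactors = FALSE))
}

# toy dataset where only one age group matters: fill the other group with
# the same values so tests can focus on a single group
toy_group_dataset <- function(group_log2, n_per_cell) {
  make_dataset(cbind(group_log2, group_log2), n_per_cell = n_per_cell)
}

# -- SAM oracle --------------------------------------------------------------

oracle_sam <- function(X, n1, s0) {
  # X: genes x (n1 sepsis followed by n2 control); exhaustive label orbit
  n <- ncol(X)
  n2 <- n - n1
  dstat <- function(x, sep) {
    a <- x[sep]; b <- x[-sep]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n - 2))
    (mean(a) - mean(b)) / (s + s0)
  }
  labs <- combn(n, n1)
  vapply(seq_len(nrow(X)), function(g) {
    d_obs <- abs(dstat(X[g, ], seq_len(n1)))
    d_all <- abs(apply(labs, 2, function(sep) dstat(X[g, ], sep)))
    mean(d_all >= d_obs - 1e-12)
  }, 0)
}

# -- rank-product oracle -----------------------------------------------------

oracle_rp_stat <- function(X, sep, ctl) {
  # naive loops over pairings; returns list(up, down) rank products
  G <- nrow(X)
  ranks_dn <- NULL
  for (i in sep) for (j in ctl) {
    d <- X[, i] - X[, j]
    ranks_dn <- cbind(ranks_dn, rank(d))
  }
  list(down = apply(ranks_dn, 1, function(r) exp(mean(log(r)))),
       up = apply(G + 1 - ranks_dn, 1, function(r) exp(mean(log(r)))))
}

oracle_rp_pvalues <- function(X, n1) {
  # exhaustive label orbit; two-sided doubled p as in the package contract
  n <- ncol(X)
  labs <- combn(n, n1)
  obs <- oracle_rp_stat(X, seq_len(n1), n1 + seq_len(n - n1))
  cnt_up <- cnt_dn <- rep(0, nrow(X))
  for (b in seq_len(ncol(labs))) {
    sep <- labs[, b]
    st <- oracle_rp_stat(X, sep, setdiff(seq_len(n), sep))
    cnt_up <- cnt_up + (st$up <= obs$up + 1e-12)
    cnt_dn <- cnt_dn + (st$down <= obs$down + 1e-12)
  }
  B <- ncol(labs)
  pmin(1, 2 * pmin(cnt_up / B, cnt_dn / B))
}

# -- TOM oracle --------------------------------------------------------------

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { w[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  w
}

random_similarity <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# -- probe truth-table builder ----------------------------------------------

# one exon of the requested biotype overlapping [100, 160) on chr1 "+"
truth_table_annotations <- function(classes_present,
                                    strand = "+") {
  rows <- list()
  add <- function(gene_id, biotype, strand, exons, gs, ge) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene_id = gene_id, gene_name = gene_id, source_db = "GENCODE",
      biotype = biotype, chrom = "chr1", strand = strand,
      exon_start = vapply(exons, `[`, 0, 1),
      exon_end = vapply(exons, `[`, 0, 2),
      gene_start = gs, gene_end = ge, stringsAsFactors = FALSE)
  }
  if ("pc" %in% classes_present)
    add("PC", "protein_coding", strand, list(c(100, 200)), 100, 200)
  if ("pg" %in% classes_present)
    add("PG", "unprocessed_pseudogene", strand, list(c(100, 200)), 100, 200)
  if ("lnc" %in% classes_present)
    add("LN", "lincRNA", strand, list(c(100, 200)), 100, 200)
  # a distant unrelated gene so the annotation table is never empty
  add("FAR", "protein_coding", "+", list(c(10000, 10200)), 10000, 10200)
  do.call(rbind, rows)
}

truth_table_probe <- function(mismatches = 0) {
  data.frame(probe_id = "p1", chrom = "chr1", start = 110, end = 170,
             strand = "+", mismatches = mismatches, blocks = "110-170",
             stringsAsFactors = FALSE)
}
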