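# Weighted co-expression network for one age group: soft-thresholded
# adjacency ("network similarity"), connectivity and topological overlap.

check_similarity <- function(a, tol = 1e-9) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > tol) stop("similarity matrix is not symmetric")
  invisible(a)
}

#' Soft-thresholded network similarity
#'
#' `a_ij = |Pearson r(log2 x_i, log2 x_j)|^beta` over the pooled sepsis and
#' control samples of one age group; `a_ii = 1` by convention.
#'
#' @param ds An [expression_dataset()] (detection-filtered).
#' @param age_group `"adult"` or `"elderly"`.
#' @param beta Soft-threshold exponent (default 13).
#' @return Symmetric genes x genes similarity matrix in `[0, 1]`.
#' @export
network_similarity <- function(ds, age_group, beta = 13) {
  stopifnot(beta >= 1)
  idx <- sample_index(ds, age_group)
  if (length(idx) < 3) stop("need >= 3 samples in the age group")
  X <- log2_ratios(ds)[, idx, drop = FALSE]
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene: ", rownames(X)[which(sds == 0)[1]])
  }
  a <- abs(cor(t(X)))^beta
  diag(a) <- 1
  a
}

#' Network connectivity
#'
#' `k_i = sum_{j != i} a_ij`: the row sums of the similarity matrix with the
#' diagonal excluded. High connectivity marks hub genes.
#'
#' @param similarity Symmetric similarity matrix.
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(similarity) {
  check_similarity(similarity)
  rowSums(similarity) - diag(similarity)
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu * a_uj` and `w_ii = 1`. Ranges from 1 (nodes
#' identically connected to all other nodes) to 0 (nodes sharing no
#' connections).
#'
#' @param similarity Symmetric similarity matrix with unit diagonal.
#' @return Symmetric TOM matrix in `[0, 1]`.
#' @export
topological_overlap <- function(similarity) {
  check_similarity(similarity)
  a <- similarity
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  dimnames(w) <- dimnames(similarity)
  w
}

#' Build the full network result for one age group
#'
#' @inheritParams network_similarity
#' @param tom Also compute the topological overlap matrix (default TRUE).
#' @return List of class `NetworkResult`: `similarity`, `connectivity`,
#'   `tom` (NULL when not requested), `age_group`, `beta`.
#' @export
build_network <- function(ds, age_group, beta = 13, tom = TRUE) {
  a <- network_similarity(ds, age_group, beta)
  structure(list(similarity = a, connectivity = connectivity(a),
                 tom = if (tom) topological_overlap(a) else NULL,
                 age_group = age_group, beta = beta),
            class = "NetworkResult")
}
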