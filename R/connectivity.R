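#' Pairwise Pearson correlation matrix of binned counts
#'
#' @param bc A `binned_counts` with at least 3 bins and at least 2 rows of
#'   nonzero variance. Rows with zero variance yield `NA` rows/columns
#'   (they are excluded from adjacency downstream).
#' @return Symmetric correlation matrix with unit diagonal (for valid
#'   rows) and neuron-id dimnames.
#' @export
correlation_matrix <- function(bc) {
  stopifnot(inherits(bc, "binned_counts"))
  if (ncol(bc$counts) < 3) stop("need at least 3 bins")
  B <- ncol(bc$counts)
  rs <- rowSums(bc$counts)
  rvar <- (rowSums(bc$counts^2) - rs^2 / B) / (B - 1)
  valid <- is.finite(rvar) & rvar > 0
  if (sum(valid) < 2) stop("need at least 2 rows with nonzero variance")
  C <- matrix(NA_real_, nrow(bc$counts), nrow(bc$counts),
              dimnames = list(bc$neuron_ids, bc$neuron_ids))
  C[valid, valid] <- stats::cor(t(bc$counts[valid, , drop = FALSE]))
  C
}

#' Permutation P-values for pairwise correlations
#'
#' For each neuron pair the binned count series of both neurons are
#' independently permuted over bins and correlated; repeating this
#' `n_perm` times builds the pair's null distribution of correlations.
#' The reported value is the left-tailed probability of the empirical
#' correlation relative to that null (ties counted as less-or-equal, which
#' is conservative for the negative-correlation criterion). The null is
#' regenerated for every pair, not pooled.
#'
#' @param bc A `binned_counts` (raw or z-scored; Pearson correlation and
#'   its permutation null are invariant to per-row affine scaling).
#' @param n_perm Number of permutations (default 3000).
#' @param seed Optional integer seed for reproducibility.
#' @return Symmetric matrix of left-tailed P-values, `NA` diagonal, `NA`
#'   for pairs involving a zero-variance row.
#' @export
permutation_pvalues <- function(bc, n_perm = 3000, seed = NULL) {
  stopifnot(inherits(bc, "binned_counts"))
  if (ncol(bc$counts) < 3) stop("need at least 3 bins")
  if (n_perm < 200)
    warning("n_perm < 200 gives poor resolution at the 0.005/0.995 thresholds")
  if (!is.null(seed)) set.seed(seed)
  m <- bc$counts * 1.0
  m[!is.finite(m)] <- 0       # invalidated z-scored rows; flagged below
  P <- cpp_perm_pvalues(m, as.integer(n_perm))
  dimnames(P) <- list(bc$neuron_ids, bc$neuron_ids)
  P
}

#' Binary adjacency matrix from permutation P-values
#'
#' An edge joins neurons `i` and `j` when their correlation is highly
#' significant: left-tailed `P <= lo` (significant negative correlation)
#' or `P >= hi` (significant positive correlation), both inclusive.
#' Diagonal entries are 0 (no self-connectivity); pairs with undefined
#' P-values get no edge.
#'
#' @param C Correlation matrix (used for dimension/dimnames checks).
#' @param P Matrix of left-tailed permutation P-values.
#' @param lo,hi Thresholds in (0, 1); defaults 0.005 and 0.995.
#' @return Symmetric 0/1 integer matrix with zero diagonal.
#' @export
adjacency_matrix <- function(C, P, lo = 0.005, hi = 0.995) {
  if (!(lo > 0 && lo < 1 && hi > 0 && hi < 1 && lo < hi))
    stop("thresholds must lie in (0, 1) with lo < hi")
  stopifnot(all(dim(C) == dim(P)))
  A <- (P <= lo | P >= hi) * 1L
  A[is.na(A)] <- 0L
  diag(A) <- 0L
  dimnames(A) <- dimnames(P)
  A
}

#' Identify neurons with no functional connections at any timescale
#'
#' Neurons whose degree is zero in the adjacency matrix of every timescale
#' are eliminated from further analyses; a single edge at a single
#' timescale is enough to be retained.
#'
#' @param adjs List of adjacency matrices (same neurons, one per
#'   timescale).
#' @return List with `retained` (character ids), `removed` (ids),
#'   `n_removed`.
#' @export
prune_never_connected <- function(adjs) {
  stopifnot(length(adjs) >= 1L)
  ids <- rownames(adjs[[1]])
  deg_any <- Reduce(`+`, lapply(adjs, rowSums))
  retained <- ids[deg_any > 0]
  removed <- ids[deg_any == 0]
  list(retained = retained, removed = removed, n_removed = length(removed))
}

#' Graph-theoretic measures of an adjacency matrix
#'
#' * `largest_partition_fraction`: neurons with at least one connection,
#'   divided by the total neuron count of `A`.
#' * `max_degree_normalized`: `max(D)/n` where `D_i` is neuron `i`'s number
#'   of significant connections.
#' * `assortativity`: Pearson correlation of degree between the two
#'   endpoints of every edge, each edge contributing both orientations;
#'   `NA` when undefined (no edges or zero degree variance over edge
#'   endpoints).
#'
#' @param A Binary symmetric adjacency matrix with zero diagonal.
#' @param dt Optional timescale tag carried into the output.
#' @return Data.frame with one row: `dt`, `n`, `largest_partition_fraction`,
#'   `max_degree_normalized`, `assortativity`.
#' @export
graph_metrics <- function(A, dt = NA_real_) {
  n <- nrow(A)
  deg <- rowSums(A)
  lpf <- sum(deg > 0) / n
  mdn <- max(deg) / n
  edges <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  assort <- NA_real_
  if (nrow(edges) > 0) {
    d1 <- c(deg[edges[, 1]], deg[edges[, 2]])
    d2 <- c(deg[edges[, 2]], deg[edges[, 1]])
    if (stats::sd(d1) > 0 && stats::sd(d2) > 0)
      assort <- stats::cor(d1, d2)
  }
  data.frame(dt = dt, n = n, largest_partition_fraction = lpf,
             max_degree_normalized = mdn, assortativity = assort)
}

#' Shuffle control: destroy temporal alignment across neurons
#'
#' Independently permutes each neuron's binned counts over bins. Each
#' row's multiset of values (hence its rate and marginal statistics) is
#' preserved while all cross-neuron temporal structure is destroyed; the
#' two-network correlation structure should vanish on shuffled data.
#'
#' @param bc A `binned_counts`.
#' @param seed Optional integer seed.
#' @return A `binned_counts` with shuffled rows.
#' @export
shuffle_control <- function(bc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- ncol(bc$counts)
  for (i in seq_len(nrow(bc$counts)))
    bc$counts[i, ] <- bc$counts[i, sample.int(nb)]
  bc
}

#' Full connectivity analysis at one timescale
#'
#' Convenience wrapper: correlation matrix, permutation P-values,
#' adjacency and graph metrics for one `binned_counts`.
#'
#' @param bc A `binned_counts`.
#' @param n_perm Permutations per pair.
#' @param lo,hi Significance thresholds on the left-tailed P-value.
#' @param seed Optional integer seed.
#' @return Object of class `connectivity_result`: list with `dt`, `C`,
#'   `P`, `A`, `metrics`, `neuron_ids`.
#' @export
connectivity_analysis <- function(bc, n_perm = 3000, lo = 0.005, hi = 0.995,
                                  seed = NULL) {
  C <- correlation_matrix(bc)
  P <- permutation_pvalues(bc, n_perm = n_perm, seed = seed)
  A <- adjacency_matrix(C, P, lo = lo, hi = hi)
  structure(list(dt = bc$dt, C = C, P = P, A = A,
                 metrics = graph_metrics(A, dt = bc$dt),
                 neuron_ids = bc$neuron_ids),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(
    "connectivity_result: dt = %.4g s, %d neurons, %d edges, partition %.2f\n",
    x$dt, nrow(x$A), sum(x$A) / 2, x$metrics$largest_partition_fraction))
  invisible(x)
}
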