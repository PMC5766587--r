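#' Expanded saddle-point form of the ACA problem
#'
#' The anti-correlated component analysis cost `L = u' C v` over the joint
#' sphere `||u||^2 + ||v||^2 = 1`, `u, v >= 0`, is equivalent to the
#' quadratic form `L = x' Ct x / 2` with `x = [u; v]` and the expanded
#' block matrix `Ct = [[0, C], [C, 0]]` -- a hyperbolic saddle restricted
#' to the non-negative orthant of the unit sphere. The eigenvalues of `Ct`
#' are the eigenvalues of `C` with both signs.
#'
#' @param C Symmetric correlation matrix.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return List with `C_tilde` (2n x 2n) and `n`.
#' @export
build_expanded <- function(C, tol = 1e-8) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > tol)
    stop("C must be symmetric")
  n <- nrow(C)
  Ct <- matrix(0, 2 * n, 2 * n)
  Ct[seq_len(n), n + seq_len(n)] <- C
  Ct[n + seq_len(n), seq_len(n)] <- C
  list(C_tilde = Ct, n = n)
}

# one alternating-minimisation pass from a feasible start; L is
# non-increasing at every half-step because for fixed v the cost is linear
# in u and the exact minimiser over {u >= 0, ||u|| = r} is the scaled
# positive part of -Cv (or a vertex when -Cv <= 0)
.aca_alternate <- function(C, u, v, max_iter = 500, tol = 1e-12) {
  r <- 1 / sqrt(2)
  half_step <- function(w) {
    cvec <- drop(C %*% w)
    if (min(cvec) < 0) {
      s <- pmax(0, -cvec)
      s / sqrt(sum(s^2)) * r
    } else {
      out <- numeric(length(cvec))
      out[which.min(cvec)] <- r
      out
    }
  }
  L <- drop(crossprod(u, C %*% v))
  for (it in seq_len(max_iter)) {
    u <- half_step(v)
    v <- half_step(u)
    Lnew <- drop(crossprod(u, C %*% v))
    if (L - Lnew < tol) { L <- Lnew; break }
    L <- Lnew
  }
  list(u = u, v = v, L = L, iters = it)
}

.aca_starts <- function(C, n_starts) {
  n <- nrow(C)
  r <- 1 / sqrt(2)
  norm_to <- function(x) {
    s <- sqrt(sum(x^2))
    if (s == 0) x else x / s * r
  }
  starts <- list()
  ev <- eigen(C, symmetric = TRUE)
  for (k in c(1L, n)) {               # leading and trailing eigenvectors
    w <- ev$vectors[, k]
    u0 <- norm_to(pmax(0, w)); v0 <- norm_to(pmax(0, -w))
    if (sum(u0) == 0) u0 <- rep(r / sqrt(n), n)
    if (sum(v0) == 0) v0 <- rep(r / sqrt(n), n)
    starts[[length(starts) + 1L]] <- list(u = u0, v = v0)
    starts[[length(starts) + 1L]] <- list(u = v0, v = u0)
  }
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <-
      list(u = norm_to(abs(stats::rnorm(n))), v = norm_to(abs(stats::rnorm(n))))
  }
  starts[seq_len(n_starts)]
}

#' Anti-correlated component analysis
#'
#' Finds two non-negative loading vectors `u`, `v` on the joint unit
#' sphere (`||u||^2 + ||v||^2 = 1`) minimising the bilinear cost
#' `L = u' C v`, the time-averaged product of the two projected z-scores.
#' At a solution the supports of `u` and `v` are (numerically) disjoint,
#' so the non-zero loadings define two mutually exclusive, maximally
#' anti-correlated networks. `L <= 0` always: whenever `C` has a negative
#' entry a disjoint-support feasible point attains `L < 0`, and otherwise
#' the degenerate solution with one empty component attains `L = 0`.
#'
#' The minimiser is a monotone alternating scheme on the non-negative
#' sphere (each half-step solves its constrained subproblem exactly), run
#' from `n_starts` initial points -- half random, half seeded from the
#' sign-split of the extreme eigenvectors of `C` -- and the best local
#' minimum is returned together with the dispersion of `L` across starts
#' as a uniqueness diagnostic.
#'
#' Membership: neuron `i` is `net1` when `u_i > v_i + tol`, `net2` when
#' `v_i > u_i + tol`, otherwise it is assigned to the larger loading
#' (exact ties stay `unassigned`); neurons with both loadings below
#' `tol * max(loading)` are flagged weak. When positions or ids are
#' supplied the labels are canonicalised: `net1` is the component with the
#' smaller mean y-coordinate, or failing that the one containing the
#' lexicographically smallest member id.
#'
#' @param C Symmetric correlation matrix with unit diagonal, `n >= 2`.
#'   Rows/columns with `NA` must be removed by the caller.
#' @param n_starts Number of initialisations (default 16).
#' @param seed Optional integer seed.
#' @param tol Membership tolerance (default 1e-6).
#' @param max_iter Iteration cap per start.
#' @param positions Optional n x 2 matrix of (x, y) positions for label
#'   canonicalisation.
#' @return Object of class `aca_result`: `u`, `v`, `L`, `membership`
#'   (factor levels net1/net2/unassigned), `weak`, `neuron_ids`,
#'   `L_starts`, `dt` (filled by callers).
#' @export
aca_fit <- function(C, n_starts = 16, seed = NULL, tol = 1e-6,
                    max_iter = 500, positions = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot(n >= 2, ncol(C) == n)
  if (anyNA(C)) stop("C contains NA; subset to valid neurons first")
  if (max(abs(C - t(C))) > 1e-8) stop("C must be symmetric")
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(C)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  starts <- .aca_starts(C, n_starts)
  fits <- lapply(starts, function(s)
    .aca_alternate(C, s$u, s$v, max_iter = max_iter))
  Ls <- vapply(fits, `[[`, numeric(1), "L")
  best <- fits[[which.min(Ls)]]
  u <- best$u; v <- best$v; L <- best$L
  if (L >= 0) {
    # no exploitable anti-correlation: canonical L = 0 solution
    u <- c(1, rep(0, n - 1)); v <- rep(0, n)
    ij <- which(C == min(C[upper.tri(C)]), arr.ind = TRUE)[1, ]
    if (C[ij[1], ij[2]] <= 0) {
      u <- rep(0, n); v <- rep(0, n)
      u[ij[1]] <- 1 / sqrt(2); v[ij[2]] <- 1 / sqrt(2)
    }
    L <- drop(crossprod(u, C %*% v))
  }
  # enforce support exclusivity: zero the smaller of any overlapping pair
  ov <- u > tol & v > tol
  if (any(ov)) {
    smaller_u <- ov & (u <= v)
    u[smaller_u] <- 0
    v[ov & !smaller_u] <- 0
    s <- sqrt(sum(u^2) + sum(v^2))
    u <- u / s; v <- v / s
    L <- drop(crossprod(u, C %*% v))
  }
  mtol <- tol * max(c(u, v, .Machine$double.eps))
  membership <- ifelse(u > v, "net1", ifelse(v > u, "net2", "unassigned"))
  weak <- pmax(u, v) < mtol
  res <- structure(list(u = u, v = v, L = L,
                        membership = stats::setNames(membership, ids),
                        weak = stats::setNames(weak, ids),
                        neuron_ids = ids, L_starts = Ls, dt = NA_real_),
                   class = "aca_result")
  .aca_canonicalize(res, positions)
}

# swap symmetry: (u,v) and (v,u) attain the same L; fix the labelling so
# net1 has the smaller mean y (positions) or the lexicographically
# smallest member id
.aca_canonicalize <- function(res, positions = NULL) {
  in1 <- res$membership == "net1"
  in2 <- res$membership == "net2"
  if (!any(in1) || !any(in2)) return(res)
  swap <- FALSE
  if (!is.null(positions)) {
    y1 <- mean(positions[in1, 2]); y2 <- mean(positions[in2, 2])
    if (is.finite(y1) && is.finite(y2) && y1 > y2) swap <- TRUE
  } else {
    if (min(res$neuron_ids[in1]) > min(res$neuron_ids[in2])) swap <- TRUE
  }
  if (swap) {
    tmp <- res$u; res$u <- res$v; res$v <- tmp
    m <- res$membership
    res$membership[m == "net1"] <- "net2"
    res$membership[m == "net2"] <- "net1"
  }
  res
}

#' @export
print.aca_result <- function(x, ...) {
  cat(sprintf(
    "aca_result: L = %.4f; net1 %d, net2 %d, unassigned %d neurons\n",
    x$L, sum(x$membership == "net1"), sum(x$membership == "net2"),
    sum(x$membership == "unassigned")))
  invisible(x)
}

#' Brute-force global oracle for ACA (small n)
#'
#' Independent verification of [aca_fit()]: dense random sampling of the
#' non-negative orthant of the unit sphere in the expanded 2n-dimensional
#' space, followed by a smooth local polish in the squared
#' parameterisation `x_i = y_i^2 / ||y^2||`. Intended for `n <= 6` only.
#'
#' @param C Symmetric correlation matrix, `n <= 6`.
#' @param n_samples Random sphere samples (default 2e5).
#' @param seed Optional integer seed.
#' @return List with `u`, `v`, `L`, `membership`.
#' @export
aca_oracle <- function(C, n_samples = 200000, seed = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n > 6) stop("oracle limited to n <= 6")
  if (!is.null(seed)) set.seed(seed)
  Ct <- build_expanded(C)$C_tilde
  m <- 2L * n
  G <- matrix(abs(stats::rnorm(n_samples * m)), ncol = m)
  G <- G / sqrt(rowSums(G^2))
  Lall <- 0.5 * rowSums((G %*% Ct) * G)
  f <- function(y) {
    x <- y^2
    s <- sqrt(sum(x^2))
    if (s == 0) return(0)
    x <- x / s
    0.5 * drop(crossprod(x, Ct %*% x))
  }
  # polish the best sampled candidates; the landscape has local minima,
  # so a single descent is not enough
  ord <- order(Lall)[seq_len(min(25L, n_samples))]
  best_x <- NULL; L <- Inf
  for (i in ord) {
    opt <- stats::optim(sqrt(G[i, ]), f, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    xi <- opt$par^2
    xi <- xi / sqrt(sum(xi^2))
    Li <- 0.5 * drop(crossprod(xi, Ct %*% xi))
    if (Li < L) { L <- Li; best_x <- xi }
  }
  x <- best_x
  if (L > 0) { x <- c(1, rep(0, m - 1)); L <- 0 }
  u <- x[seq_len(n)]; v <- x[n + seq_len(n)]
  list(u = u, v = v, L = L,
       membership = ifelse(u > v, "net1", ifelse(v > u, "net2", "unassigned")))
}

#' Project binned activity onto the two anti-correlated networks
#'
#' Computes the per-bin projected z-scores `u' z(t)` and `v' z(t)`; when
#' `L < 0` these two population time series are anti-correlated over time.
#'
#' @param result An `aca_result`.
#' @param bc A z-scored `binned_counts` over the same neurons.
#' @return Data.frame with `bin_start_s`, `net1_activity`,
#'   `net2_activity`; attribute `correlation` holds their Pearson
#'   correlation.
#' @export
project_networks <- function(result, bc) {
  stopifnot(inherits(result, "aca_result"), inherits(bc, "binned_counts"))
  if (!bc$zscored) bc <- zscore_counts(bc)
  idx <- match(result$neuron_ids, bc$neuron_ids)
  if (anyNA(idx)) stop("loadings and binned counts cover different neurons")
  Z <- bc$counts[idx, , drop = FALSE]
  if (anyNA(Z)) stop("binned counts contain invalid (constant) rows; ",
                     "exclude them before projecting")
  p1 <- drop(result$u %*% Z)
  p2 <- drop(result$v %*% Z)
  out <- data.frame(bin_start_s = (seq_len(ncol(Z)) - 1) * bc$dt,
                    net1_activity = p1, net2_activity = p2)
  attr(out, "correlation") <- stats::cor(p1, p2)
  out
}
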