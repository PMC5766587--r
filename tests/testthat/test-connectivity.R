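test_that("correlation matrix matches hand-computed Pearson values", {
  bc <- as_bc(rbind(a = c(1, 2, 3), b = c(1, 3, 2), c = c(1, 2, 3),
                    d = c(3, 2, 1)))
  C <- correlation_matrix(bc)
  expect_equal(C["a", "b"], 0.5)        # hand-computed Pearson
  expect_equal(C["a", "c"], 1)
  expect_equal(C["a", "d"], -1)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_error(correlation_matrix(as_bc(rbind(a = c(1, 2), b = c(2, 1)))),
               "3 bins")
  # invalid rows propagate NA but keep others intact
  C2 <- correlation_matrix(as_bc(rbind(a = c(1, 2, 3), b = c(2, 2, 2),
                                       c = c(3, 1, 2))))
  expect_true(all(is.na(C2["b", ])))
  expect_false(anyNA(C2[c("a", "c"), c("a", "c")]))
})

test_that("permutation P-values: identical rows in the far-right tail, seeds reproduce", {
  set.seed(31)
  x <- rpois(1000, 2)
  bc <- as_bc(rbind(a = x, b = x, c = rpois(1000, 2)))
  P <- permutation_pvalues(bc, n_perm = 1000, seed = 7)
  expect_gte(P["a", "b"], 0.995)
  expect_true(is.na(P["a", "a"]))
  expect_equal(P, t(P))
  P2 <- permutation_pvalues(bc, n_perm = 1000, seed = 7)
  expect_identical(P, P2)
  expect_warning(permutation_pvalues(bc, n_perm = 100, seed = 1),
                 "resolution")
})

test_that("the sparse-matching null sampler agrees with brute-force permutation", {
  set.seed(12)
  cases <- list(list(x = rpois(300, 0.5), y = rpois(300, 3)),   # categorical
                list(x = rpois(250, 25), y = rpois(250, 18)),   # value-rich
                list(x = rnorm(200), y = rnorm(200)))           # dense real
  for (cs in cases) {
    set.seed(99)
    ns <- acanet:::cpp_perm_null_sample(cs$x, cs$y, 8000)
    bf <- replicate(8000, cor(sample(cs$x), sample(cs$y)))
    expect_lt(abs(mean(ns) - mean(bf)), 0.01)
    expect_lt(abs(sd(ns) / sd(bf) - 1), 0.05)
    expect_lt(max(abs(quantile(ns, c(0.005, 0.995)) -
                      quantile(bf, c(0.005, 0.995)))), 0.3 * sd(bf))
  }
})

test_that("adjacency applies inclusive thresholds and is hollow-symmetric", {
  C <- diag(3); C[C == 0] <- 0.5
  P <- matrix(0.5, 3, 3); diag(P) <- NA
  expect_equal(sum(adjacency_matrix(C, P)), 0)
  P[1, 2] <- P[2, 1] <- 0.005          # boundary: edge present (inclusive)
  P[1, 3] <- P[3, 1] <- 0.995
  A <- adjacency_matrix(C, P)
  expect_equal(A[1, 2], 1L)
  expect_equal(A[1, 3], 1L)
  expect_equal(A[2, 3], 0L)
  expect_equal(unname(diag(A)), rep(0L, 3))
  expect_equal(A, t(A))
  expect_error(adjacency_matrix(C, P, lo = 0), "thresholds")
})

test_that("never-connected pruning requires zero degree at every timescale", {
  A1 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A2 <- A1
  A2["a", "b"] <- A2["b", "a"] <- 1L    # one edge at one timescale only
  pr <- prune_never_connected(list(A1, A2))
  expect_setequal(pr$retained, c("a", "b"))
  expect_equal(pr$removed, "c")
  # identity when everyone connects somewhere
  A3 <- A2; A3["c", "a"] <- A3["a", "c"] <- 1L
  expect_equal(prune_never_connected(list(A2, A3))$n_removed, 0L)
})

test_that("graph metrics match closed forms and the igraph cross-check", {
  full <- matrix(1L, 5, 5); diag(full) <- 0L
  m <- graph_metrics(full)
  expect_equal(m$largest_partition_fraction, 1)
  expect_equal(m$max_degree_normalized, 0.8)
  expect_true(is.na(m$assortativity))    # zero degree variance

  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1L
  ms <- graph_metrics(star)
  expect_equal(ms$assortativity, -1)     # all edges join degrees (4, 1)

  iso <- matrix(0L, 4, 4)
  iso[1, 2] <- iso[2, 1] <- iso[2, 3] <- iso[3, 2] <- 1L
  expect_equal(graph_metrics(iso)$largest_partition_fraction, 0.75)

  skip_if_not_installed("igraph")
  set.seed(77)
  for (k in 1:5) {
    A <- matrix(0L, 12, 12)
    A[upper.tri(A)] <- rbinom(66, 1, 0.3)
    A <- A + t(A)
    if (sum(A) == 0) next
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ours <- graph_metrics(A)$assortativity
    theirs <- igraph::assortativity_degree(g)
    if (is.finite(theirs) && !is.na(ours))
      expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("row-shuffling preserves per-neuron values and kills cross-correlation", {
  set.seed(3)
  m <- rbind(a = rpois(500, 2), b = rpois(500, 5))
  bc <- as_bc(m)
  sh <- shuffle_control(bc, seed = 5)
  expect_equal(sort(sh$counts["a", ]), sort(m["a", ]))
  expect_equal(sort(sh$counts["b", ]), sort(m["b", ]))
  sh2 <- shuffle_control(bc, seed = 5)
  expect_identical(sh$counts, sh2$counts)
})

test_that("significant-pair rate under independence is near the nominal level", {
  # 28 independent Poisson rows -> 378 pairs at reduced n_perm
  set.seed(55)
  m <- matrix(rpois(28 * 400, 2), nrow = 28)
  P <- permutation_pvalues(as_bc(m), n_perm = 400, seed = 9)
  up <- P[upper.tri(P)]
  frac <- mean(up <= 0.005 | up >= 0.995)
  expect_lt(frac, 0.035)   # 99.9% binomial upper band around 1%
})

test_that("significant correlations on two-ensemble data carry the right signs", {
  cfg <- synth_config(n_neurons = 40, duration = 300, seed = 19)
  sim <- gen_cox_spikes(cfg)
  bc <- bin_spikes(sim$recording, 10)
  C <- correlation_matrix(bc)
  P <- permutation_pvalues(bc, n_perm = 500, seed = 2)
  A <- adjacency_matrix(C, P)
  ens <- sim$truth$ensemble
  same <- outer(ens, ens, function(a, b) a == b & a > 0)
  diff_ <- outer(ens, ens, function(a, b) a != b & a > 0 & b > 0)
  sig <- A == 1 & upper.tri(A)
  expect_gte(mean(C[sig & same] > 0), 0.9)
  expect_gte(mean(C[sig & diff_] < 0), 0.9)
})
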