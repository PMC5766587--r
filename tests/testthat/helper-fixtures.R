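# fixtures are built in code; no data files

# wrap a plain matrix as binned counts (rows = neurons)
as_bc <- function(m, dt = 1) {
  if (is.null(rownames(m))) rownames(m) <- paste0("n", seq_len(nrow(m)))
  structure(list(dt = dt, counts = m, neuron_ids = rownames(m),
                 duration = ncol(m) * dt, zscored = FALSE,
                 valid = rep(TRUE, nrow(m))),
            class = "binned_counts")
}

# small recording of homogeneous Poisson trains
poisson_recording <- function(n_neurons, rate_hz, duration, seed = 1) {
  set.seed(seed)
  trains <- lapply(seq_len(n_neurons), function(i) {
    tt <- sort(runif(rpois(1, rate_hz * duration), 0, duration))
    spike_train(sprintf("p%03d", i), tt[!duplicated(tt)])
  })
  recording(trains, duration = duration)
}

# block correlation matrix: two groups, within-block rw, between rb
block_cor <- function(sizes, rw, rb) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  C <- matrix(rb, n, n)
  for (g in seq_along(sizes)) C[grp == g, grp == g] <- rw
  diag(C) <- 1
  rownames(C) <- colnames(C) <- sprintf("n%02d", seq_len(n))
  C
}

# random valid correlation matrix via random data
random_cor <- function(n, n_obs = 50, seed = 1) {
  set.seed(seed)
  C <- stats::cor(matrix(rnorm(n_obs * n), n_obs, n))
  rownames(C) <- colnames(C) <- sprintf("n%02d", seq_len(n))
  C
}

# accuracy of a membership labelling against ground-truth ensembles,
# maximised over the two possible label alignments
membership_accuracy <- function(membership, truth_ensemble) {
  lab <- membership[truth_ensemble %in% c(1, 2)]
  tru <- ifelse(truth_ensemble[truth_ensemble %in% c(1, 2)] == 1,
                "net1", "net2")
  acc <- mean(lab == tru)
  max(acc, 1 - acc)
}
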