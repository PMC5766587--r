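#' Logarithmic grid of bin widths
#'
#' Builds the grid of timescales used throughout the analysis: `n` bin
#' widths evenly spaced in log10 between `lo` and `hi` seconds, endpoints
#' inclusive. The defaults span five orders of magnitude from 1 ms to
#' 10^1.5 s (= 31.623 s) in 20 steps.
#'
#' @param lo Smallest bin width (s), must be positive.
#' @param hi Largest bin width (s).
#' @param n Number of steps (>= 2).
#' @return An object of class `timescale_grid` with element `dts`.
#' @export
make_timescale_grid <- function(lo = 1e-3, hi = 10^1.5, n = 20) {
  if (lo <= 0) stop("lo must be positive")
  stopifnot(lo < hi, n >= 2)
  dts <- 10^seq(log10(lo), log10(hi), length.out = n)
  structure(list(dts = dts, lo = lo, hi = hi, n = as.integer(n)),
            class = "timescale_grid")
}

#' @export
print.timescale_grid <- function(x, ...) {
  cat(sprintf("timescale_grid: %d log-spaced bin widths, %.4g s to %.4g s\n",
              x$n, x$lo, x$hi))
  invisible(x)
}

#' Bin spike trains into a count process
#'
#' Divides the time axis into consecutive half-open bins `[b*dt, (b+1)*dt)`
#' and counts each neuron's spikes per bin. A trailing partial bin is
#' dropped, so `n_bins = floor(duration/dt)`; spikes falling past the last
#' full bin do not appear in the matrix.
#'
#' @param rec A `spike_recording`.
#' @param dt Bin width in seconds, `0 < dt <= duration`.
#' @return An object of class `binned_counts`: list with `dt`, integer
#'   matrix `counts` (neurons x bins), `neuron_ids`, `duration`, `zscored`
#'   flag and logical `valid` (row has nonzero variance; filled by
#'   [zscore_counts()]).
#' @export
bin_spikes <- function(rec, dt) {
  stopifnot(dt > 0)
  if (dt > rec$duration) stop("dt exceeds recording duration")
  nb <- floor(rec$duration / dt)
  counts <- t(vapply(rec$trains, function(tr) {
    idx <- floor(tr$spike_times / dt) + 1
    tabulate(idx[idx <= nb], nbins = nb)
  }, integer(nb)))
  if (nb == 1L) counts <- matrix(counts, ncol = 1L,
                                 dimnames = list(neuron_ids(rec), NULL))
  rownames(counts) <- neuron_ids(rec)
  structure(list(dt = dt, counts = counts, neuron_ids = neuron_ids(rec),
                 duration = rec$duration, zscored = FALSE,
                 valid = rep(TRUE, nrow(counts))),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts: %d neurons x %d bins, dt = %.4g s%s\n",
              nrow(x$counts), ncol(x$counts), x$dt,
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Z-score binned counts per neuron
#'
#' Each row is mean-subtracted and divided by its (sample) standard
#' deviation. Rows with zero variance cannot be normalised: they are
#' flagged invalid (`valid = FALSE`, values set to `NA`) and reported, not
#' silently dropped; downstream operations exclude them.
#'
#' @param bc A `binned_counts`.
#' @return The z-scored `binned_counts` (idempotent).
#' @export
zscore_counts <- function(bc) {
  stopifnot(inherits(bc, "binned_counts"))
  if (bc$zscored) return(bc)
  m <- bc$counts * 1.0
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad))
    .log("%d zero-variance row(s) flagged invalid at dt = %.4g s: %s",
         sum(bad), bc$dt, paste(bc$neuron_ids[bad], collapse = ", "))
  m <- (m - mu) / sdv
  m[bad, ] <- NA_real_
  bc$counts <- m
  bc$zscored <- TRUE
  bc$valid <- !bad
  bc
}

#' Normalized auto-correlogram of one neuron's binned counts
#'
#' Pearson autocorrelation of the count series at integer lags
#' `0..max_lag` bins; by construction the value at lag 0 is 1.
#'
#' @param bc A `binned_counts` (z-scored or raw; Pearson correlation is
#'   invariant to the affine normalisation).
#' @param neuron Neuron id or row index.
#' @param max_lag Largest lag in bins, `< n_bins`.
#' @return Data.frame with columns `lag_bins`, `lag_s`, `r`.
#' @export
autocorrelogram <- function(bc, neuron, max_lag) {
  i <- if (is.character(neuron)) match(neuron, bc$neuron_ids) else neuron
  if (is.na(i)) stop("unknown neuron: ", neuron)
  x <- as.numeric(bc$counts[i, ])
  nb <- length(x)
  if (max_lag >= nb) stop("max_lag must be smaller than the number of bins")
  r <- vapply(0:max_lag, function(l) {
    if (l == 0) 1 else stats::cor(x[1:(nb - l)], x[(1 + l):nb])
  }, numeric(1))
  data.frame(lag_bins = 0:max_lag, lag_s = (0:max_lag) * bc$dt, r = r)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes DPSS tapers via the eigendecomposition of the symmetric
#' tridiagonal matrix whose eigenvectors are exactly the Slepian
#' sequences. For long series (`N > max_direct`) the tapers are computed
#' at `max_direct` points and spline-interpolated to length `N`, then
#' renormalised to unit energy -- the standard approach for large `N`.
#'
#' @param N Series length in samples.
#' @param W Half-bandwidth in Hz.
#' @param dt Sample interval in seconds.
#' @param K Number of tapers.
#' @param max_direct Largest length solved exactly (default 2048).
#' @return `N x K` matrix of tapers, each with unit energy.
#' @export
dpss_tapers <- function(N, W, dt, K, max_direct = 2048) {
  stopifnot(N >= 2, K >= 1, W > 0, dt > 0)
  w <- W * dt                       # normalized half-bandwidth, cycles/sample
  if (w >= 0.5) stop("W too large: normalized half-bandwidth must be < 0.5")
  n0 <- min(N, max_direct)
  if (K > n0) stop("K exceeds the computable taper count (", n0, ")")
  # scale the normalized bandwidth so that the time-bandwidth product is
  # preserved when solving on the shorter lattice
  w0 <- if (n0 < N) w * N / n0 else w
  if (w0 >= 0.5) w0 <- 0.499
  i <- 0:(n0 - 1)
  diag_v <- ((n0 - 1 - 2 * i) / 2)^2 * cos(2 * pi * w0)
  off_v <- (1:(n0 - 1)) * (n0 - (1:(n0 - 1))) / 2
  Tm <- matrix(0, n0, n0)
  Tm[cbind(i + 1, i + 1)] <- diag_v
  Tm[cbind(1:(n0 - 1), 2:n0)] <- off_v
  Tm[cbind(2:n0, 1:(n0 - 1))] <- off_v
  ev <- eigen(Tm, symmetric = TRUE)
  H <- ev$vectors[, seq_len(K), drop = FALSE]
  # sign convention: symmetric tapers have positive mean, antisymmetric
  # ones a positive initial slope
  for (k in seq_len(K)) {
    s <- sum(H[, k])
    if (abs(s) > 1e-8) { if (s < 0) H[, k] <- -H[, k] }
    else if (H[2, k] - H[1, k] < 0) H[, k] <- -H[, k]
  }
  if (n0 < N) {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = N)
    H <- apply(H, 2L, function(h) stats::spline(x0, h, xout = x1)$y)
  }
  H <- sweep(H, 2L, sqrt(colSums(H^2)), "/")
  H
}

#' Multitaper spectrum of binned spike trains
#'
#' Bins are expected at dt = 1 ms and z-scored. Each neuron's series is
#' multiplied by `K` Slepian tapers; the `K` tapered periodograms are
#' averaged, and the mean and SD of the resulting spectra across neurons
#' are reported. The defaults follow the conventional parameterisation in
#' which the number of tapers obeys `K <= 2TW - 1`; `strict = TRUE`
#' enforces that bound by truncation with a warning, while the default
#' leaves `K` as requested.
#'
#' @param bc A z-scored `binned_counts` (z-scored on the fly otherwise).
#' @param W Half-bandwidth in Hz (default 0.001).
#' @param K Number of Slepian tapers (default 300).
#' @param strict Enforce `K <= max(1, floor(2*T*W - 1))` (default FALSE).
#' @return Object of class `spectrum_result`: list with `freqs` (Hz),
#'   `mean_power`, `sd_power`, `per_neuron` matrix, `n_tapers`, `W`, `T`.
#' @export
multitaper_spectrum <- function(bc, W = 0.001, K = 300, strict = FALSE) {
  if (!bc$zscored) bc <- zscore_counts(bc)
  if (!any(bc$valid)) stop("no rows with nonzero variance")
  Tdur <- ncol(bc$counts) * bc$dt
  kmax <- max(1, floor(2 * Tdur * W - 1))
  if (strict && K > kmax) {
    warning("K = ", K, " exceeds 2TW - 1 = ", kmax, "; truncated")
    K <- kmax
  }
  N <- ncol(bc$counts)
  H <- dpss_tapers(N, W, bc$dt, K)
  nf <- floor(N / 2) + 1
  freqs <- (seq_len(nf) - 1) / (N * bc$dt)
  rows <- which(bc$valid)
  spec <- matrix(NA_real_, length(rows), nf)
  for (r in seq_along(rows)) {
    x <- bc$counts[rows[r], ]
    acc <- numeric(nf)
    for (k in seq_len(K)) {
      X <- stats::fft(x * H[, k])[seq_len(nf)]
      acc <- acc + (Mod(X)^2) * bc$dt
    }
    spec[r, ] <- acc / K
  }
  structure(list(freqs = freqs, mean_power = colMeans(spec),
                 sd_power = apply(spec, 2L, stats::sd),
                 per_neuron = spec, n_tapers = K, W = W, T = Tdur,
                 neuron_ids = bc$neuron_ids[rows]),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("multitaper spectrum: %d neurons, K = %d tapers, W = %g Hz, T = %g s\n",
              nrow(x$per_neuron), x$n_tapers, x$W, x$T))
  invisible(x)
}
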