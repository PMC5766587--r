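test_that("timescale grid is log-even with inclusive endpoints", {
  g <- make_timescale_grid()
  expect_equal(g$n, 20L)
  expect_equal(g$dts[1], 1e-3)
  expect_equal(round(g$dts[20], 3), 31.623)
  # even spacing in log10
  expect_equal(max(abs(diff(diff(log10(g$dts))))), 0, tolerance = 1e-12)
  # n = 2 gives exactly the endpoints
  g2 <- make_timescale_grid(n = 2)
  expect_equal(g2$dts, c(1e-3, 10^1.5))
  expect_error(make_timescale_grid(lo = 0), "positive")
  # round-trip through its parameters
  g3 <- make_timescale_grid(g$lo, g$hi, g$n)
  expect_equal(g3$dts, g$dts)
})

test_that("binning counts spikes in half-open bins and drops the partial tail", {
  rec <- recording(list(spike_train("a", c(0.5, 1.5, 1.6))), duration = 3)
  bc <- bin_spikes(rec, 1)
  expect_equal(as.vector(bc$counts), c(1, 2, 0))

  rec2 <- recording(list(spike_train("a", c(0.5, 1.5)),
                         spike_train("b", numeric(0))), duration = 3)
  expect_equal(as.vector(bin_spikes(rec2, 1)$counts["b", ]), c(0, 0, 0))

  # dt = duration: a single bin holding all spikes
  bc3 <- bin_spikes(rec, 3)
  expect_equal(dim(bc3$counts), c(1L, 1L))
  expect_equal(unname(bc3$counts[1, 1]), 3L)
  expect_error(bin_spikes(rec, 4), "duration")
})

test_that("spike count is conserved across binning plus the dropped tail", {
  rec <- poisson_recording(8, 5, 23.7, seed = 9)
  for (dt in c(0.1, 0.5, 2, 7)) {
    bc <- bin_spikes(rec, dt)
    nb <- ncol(bc$counts)
    tail_spikes <- vapply(rec$trains, function(tr)
      sum(tr$spike_times >= nb * dt), numeric(1))
    expect_equal(unname(rowSums(bc$counts) + tail_spikes),
                 unname(lengths(lapply(rec$trains, `[[`, "spike_times"))))
  }
})

test_that("rebinning pairs of bins equals binning at twice the width", {
  rec <- poisson_recording(5, 10, 40, seed = 4)
  bc1 <- bin_spikes(rec, 0.5)
  bc2 <- bin_spikes(rec, 1.0)
  nb <- ncol(bc2$counts)
  agg <- bc1$counts[, seq(1, 2 * nb, by = 2)] + bc1$counts[, seq(2, 2 * nb, by = 2)]
  expect_equal(agg, bc2$counts, ignore_attr = TRUE)
})

test_that("z-scoring normalises rows, flags constant rows, and is idempotent", {
  bc <- as_bc(rbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_message(z <- zscore_counts(bc), "zero-variance")
  expect_equal(mean(z$counts["a", ]), 0, tolerance = 1e-9)
  expect_equal(sd(z$counts["a", ]), 1, tolerance = 1e-9)
  expect_false(z$valid["b" == z$neuron_ids])
  expect_true(all(is.na(z$counts["b", ])))   # flagged, not dropped
  z2 <- zscore_counts(z)
  expect_equal(z2$counts, z$counts)
})

test_that("autocorrelogram is 1 at lag 0, finds periodicity, and bounds white noise", {
  x <- rep(c(3, 0, 1, 0), 25)
  bc <- zscore_counts(as_bc(rbind(a = x)))
  ac <- autocorrelogram(bc, "a", 8)
  expect_equal(ac$r[1], 1)
  expect_equal(ac$r[ac$lag_bins == 4], 1, tolerance = 1e-9)
  expect_error(autocorrelogram(bc, "a", 100), "max_lag")

  set.seed(8)
  w <- as_bc(rbind(a = rpois(4000, 2)))
  acw <- autocorrelogram(w, "a", 50)$r[-1]
  expect_gte(mean(abs(acw) < 3 / sqrt(4000)), 0.95)
})

test_that("DPSS tapers are orthonormal and concentrated", {
  H <- dpss_tapers(512, W = 0.02, dt = 1, K = 8)
  G <- crossprod(H)
  expect_equal(G, diag(8), tolerance = 1e-6, ignore_attr = TRUE)
  # first taper is bell-shaped and positive
  expect_true(all(H[, 1] > -1e-12))
  expect_gt(H[256, 1], H[10, 1])
  # interpolated long tapers stay orthonormal to looser tolerance
  H2 <- dpss_tapers(5000, W = 0.002, dt = 1, K = 4)
  expect_equal(crossprod(H2), diag(4), tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("multitaper spectrum is flat for Poisson counts and peaks under modulation", {
  # homogeneous Poisson: white spectrum
  rec <- poisson_recording(3, 20, 120, seed = 14)
  bc <- zscore_counts(bin_spikes(rec, 1e-3))
  sp <- multitaper_spectrum(bc, W = 0.1, K = 12)
  lowband <- mean(sp$mean_power[sp$freqs > 0 & sp$freqs <= 10])
  highband <- mean(sp$mean_power[sp$freqs >= 40 & sp$freqs <= 50])
  expect_gt(lowband / highband, 0.8)
  expect_lt(lowband / highband, 1.25)

  # 5 Hz sinusoidal rate modulation: peak at the 5 Hz bin
  tr <- gen_modulated(10, 5, 0.8, 300, seed = 6)
  bcm <- zscore_counts(bin_spikes(recording(list(tr), duration = 300), 1e-3))
  spm <- multitaper_spectrum(bcm, W = 0.05, K = 8)
  inband <- spm$freqs > 0.5 & spm$freqs < 50
  peak <- spm$freqs[inband][which.max(spm$mean_power[inband])]
  expect_equal(peak, 5, tolerance = 0.05)

  # strict mode truncates K with a warning
  expect_warning(multitaper_spectrum(bc, W = 0.01, K = 50, strict = TRUE),
                 "truncated")
  # all-constant input errors
  expect_error(multitaper_spectrum(as_bc(rbind(a = rep(2, 100)))),
               "nonzero variance")
})
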