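test_that("CSV round-trip parses, sorts and deduplicates spike times", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("neuron_id,spike_time_s", "a,0.5", "a,1.5", "b,0.2"), f)
  rec <- read_spikes(f)
  expect_s3_class(rec, "spike_recording")
  expect_equal(n_neurons(rec), 2L)
  expect_equal(lengths(lapply(rec$trains, `[[`, "spike_times")),
               c(a = 2L, b = 1L))

  writeLines(c("neuron_id,spike_time_s", "a,1.5", "a,0.5"), f)
  expect_warning(rec2 <- read_spikes(f), "out of order")
  expect_equal(rec2$trains$a$spike_times, c(0.5, 1.5))

  writeLines(c("neuron_id,spike_time_s", "a,0.5", "a,0.5", "a,1.0"), f)
  expect_warning(rec3 <- read_spikes(f), "duplicate")
  expect_equal(rec3$trains$a$spike_times, c(0.5, 1.0))

  writeLines(c("neuron_id,spike_time_s", "a,-0.5"), f)
  expect_error(read_spikes(f), "negative.*a")
  writeLines("neuron_id,spike_time_s", f)
  expect_error(read_spikes(f), "empty")
})

test_that("JSON round-trip preserves times, duration and metadata", {
  tr <- spike_train("a", c(0.1, 0.7), electrode_id = "e1",
                    position = c(100, 300), waveform_amplitude = 55,
                    waveform_width = 0.4)
  rec <- recording(list(tr, spike_train("b", 0.5)), duration = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_spikes(rec, f, format = "json")
  back <- read_spikes(f)
  expect_equal(back$duration, 2)
  expect_equal(back$trains$a$spike_times, c(0.1, 0.7))
  expect_equal(back$trains$a$position, c(100, 300))
  expect_equal(back$trains$a$waveform_width, 0.4)
})

test_that("cross-electrode duplicates collapse to the largest-amplitude train", {
  tt <- sort(runif(200, 0, 60))
  mk <- function(id, el, amp, shift = 0)
    spike_train(id, tt + shift, electrode_id = el, waveform_amplitude = amp)
  rec <- recording(list(mk("a", "e1", 50), mk("b", "e2", 80)), duration = 61)
  out <- deduplicate_neurons(rec)
  expect_equal(neuron_ids(out), "b")
  expect_equal(attr(out, "removed_ids"), "a")

  # 5 ms offset exceeds the 1 ms window: both retained
  rec2 <- recording(list(mk("a", "e1", 50), mk("b", "e2", 80, shift = 0.005)),
                    duration = 61)
  expect_equal(n_neurons(deduplicate_neurons(rec2)), 2L)

  # missing amplitude on a duplicate pair is an instructive error
  rec3 <- recording(list(spike_train("a", tt, electrode_id = "e1"),
                         mk("b", "e2", 80)), duration = 61)
  expect_error(deduplicate_neurons(rec3), "disable dedup")
})

test_that("duplicate grouping is transitive and keeps one max-amplitude survivor", {
  # a~b and b~c within lag, with jitter so a~c only holds transitively;
  # compare against an exhaustive pairwise union check
  set.seed(42)
  tt <- sort(runif(300, 0, 120))
  mk <- function(id, el, amp, jit)
    spike_train(id, sort(tt + jit), electrode_id = el,
                waveform_amplitude = amp)
  rec <- recording(list(mk("a", "e1", 40, 0),
                        mk("b", "e2", 90, runif(300, 0, 9e-4)),
                        mk("c", "e3", 60, runif(300, 0, 9e-4)),
                        spike_train("d", sort(runif(900, 0, 120)),
                                    electrode_id = "e4",
                                    waveform_amplitude = 10)),
                   duration = 121)
  out <- deduplicate_neurons(rec)
  expect_setequal(neuron_ids(out), c("b", "d"))

  # brute-force oracle: union of pairwise-duplicate components
  pairs <- combn(c("a", "b", "c", "d"), 2)
  adj <- matrix(FALSE, 4, 4, dimnames = list(c("a","b","c","d"),
                                             c("a","b","c","d")))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    fr <- acanet:::.match_fraction(rec$trains[[i]]$spike_times,
                                   rec$trains[[j]]$spike_times, 0.001)
    adj[i, j] <- adj[j, i] <- fr >= 0.9
  }
  expect_true(adj["a", "b"] && adj["b", "c"])
  expect_false(any(adj["d", c("a", "b", "c")]))
  # the a-b-c component must yield exactly one survivor: b (max amplitude)
  expect_false(any(c("a", "c") %in% neuron_ids(out)))

  # idempotence
  again <- deduplicate_neurons(out)
  expect_equal(neuron_ids(again), neuron_ids(out))
})

test_that("low-rate filter removes strictly-below-threshold neurons only", {
  mk <- function(id, n) spike_train(id, seq_len(n) * 60 / (n + 1))
  rec <- recording(list(mk("slow", 5), mk("edge", 10), mk("fast", 40)),
                   duration = 60)
  out <- filter_low_rate(rec, min_rate = 10)
  expect_setequal(neuron_ids(out), c("edge", "fast"))   # 10/min retained
  expect_equal(attr(out, "n_removed"), 1L)
  # idempotent, and identity when nothing is below threshold
  expect_equal(neuron_ids(filter_low_rate(out)), neuron_ids(out))
})

test_that("ISI statistics match direct arithmetic and the telescoping identity", {
  st <- isi_stats(spike_train("a", c(0, 1, 2, 3)), duration = 10)
  expect_equal(st$mean_isi, 1.0)
  expect_equal(st$sd_isi, 0.0)

  st2 <- isi_stats(spike_train("b", c(0, 0.1, 0.3)), duration = 10)
  expect_equal(st2$mean_isi, 0.15)

  # fewer than 2 spikes: ISI undefined, rate still present
  st3 <- isi_stats(spike_train("c", 0.4), duration = 60)
  expect_true(is.na(st3$mean_isi))
  expect_equal(st3$rate, 1)

  # telescoping: mean ISI = (last - first)/(n-1) for arbitrary trains
  set.seed(5)
  for (k in 1:5) {
    tt <- sort(runif(sample(5:50, 1), 0, 100))
    tt <- tt[!duplicated(tt)]
    s <- isi_stats(spike_train("x", tt), duration = 100)
    expect_equal(s$mean_isi, (max(tt) - min(tt)) / (length(tt) - 1))
  }
})

test_that("exponential ISIs have unit coefficient of variation", {
  set.seed(11)
  tt <- cumsum(rexp(1e5, rate = 5))
  st <- isi_stats(spike_train("e", tt), duration = max(tt) + 1)
  expect_equal(st$sd_isi / st$mean_isi, 1, tolerance = 0.02)
})

test_that("Taylor's-law fit recovers closed-form slopes", {
  mk <- function(mu, sdv) data.frame(neuron_id = NA, n_spikes = 100,
                                     rate = 10, mean_isi = mu, sd_isi = sdv)
  # sd = mean exactly: slope 1, R^2 1
  st <- do.call(rbind, lapply(c(0.1, 0.5, 2), function(m) mk(m, m)))
  fit <- fit_taylor_law(st)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # sd = sqrt(mean): slope 0.5
  st2 <- do.call(rbind, lapply(c(0.1, 0.5, 2), function(m) mk(m, sqrt(m))))
  expect_equal(fit_taylor_law(st2)$slope, 0.5, tolerance = 1e-12)
  # sd = c * mean for any c: slope exactly 1 (property)
  st3 <- do.call(rbind, lapply(c(0.05, 0.2, 1, 4), function(m) mk(m, 0.37 * m)))
  expect_equal(fit_taylor_law(st3)$slope, 1, tolerance = 1e-12)
  # zero-sd neurons excluded with a warning; all-zero errors
  st4 <- rbind(st, mk(1, 0))
  expect_warning(f4 <- fit_taylor_law(st4), "sd_isi = 0")
  expect_equal(f4$n_used, 3)
  expect_error(fit_taylor_law(mk(1, 0)), "zero ISI")
})

test_that("gamma-renewal populations with fixed shape give slope ~ 1", {
  rec <- gen_renewal(60, shape = 4, rate_range = c(0.1, 20),
                     duration = 600, seed = 3)
  st <- isi_stats(rec)
  fit <- fit_taylor_law(st)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  # CV = 1/sqrt(k) for neurons with enough ISIs
  many <- st[st$n_spikes >= 500, ]
  cvs <- many$sd_isi / many$mean_isi
  expect_true(all(abs(cvs - 0.5) < 0.05))
})

test_that("spike-width classification separates bimodal widths and degrades safely", {
  set.seed(21)
  n1 <- 40; n2 <- 60
  widths <- c(rnorm(n1, 0.3, 0.04), rnorm(n2, 1.0, 0.1))
  mk <- function(i, w) spike_train(sprintf("n%03d", i), c(i, i + 1) * 0.1,
                                   waveform_width = w)
  rec <- recording(Map(mk, seq_along(widths), widths), duration = 100)
  cls <- classify_spike_widths(rec)
  truth <- rep(c("narrow", "broad"), c(n1, n2))
  expect_gte(mean(cls$labels == truth), 0.95)
  expect_gt(cls$cut, 0.3); expect_lt(cls$cut, 1.0)

  # two widths with a clear gap: cut strictly between
  rec2 <- recording(list(spike_train("a", c(1, 2), waveform_width = 0.3),
                         spike_train("b", c(1, 2), waveform_width = 1.0),
                         spike_train("c", c(1, 2), waveform_width = 0.32),
                         spike_train("d", c(1, 2), waveform_width = 0.98)),
                    duration = 3)
  cls2 <- classify_spike_widths(rec2)
  expect_gt(cls2$cut, 0.32); expect_lt(cls2$cut, 0.98)

  # identical widths: degenerate single class with warning
  rec3 <- recording(lapply(1:6, function(i)
    spike_train(paste0("n", i), c(1, 2), waveform_width = 0.5)), duration = 3)
  expect_warning(cls3 <- classify_spike_widths(rec3), "unimodal")
  expect_true(all(cls3$labels == "broad"))
})
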