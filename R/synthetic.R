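#' Configuration for the two-ensemble Cox-process simulator
#'
#' Defines the study conditions the analysis pipeline assumes: a
#' population of heterogeneously firing neurons recorded for 10 minutes
#' on a 120-electrode, 100-um-pitch array, with two ensembles driven by
#' anti-correlated slow latent processes and placed with opposite depth
#' bias.
#'
#' @param n_neurons Population size (default 150).
#' @param duration Recording length in seconds (default 600).
#' @param ensemble_fractions Fractions of neurons in ensembles 1 and 2
#'   (default `c(0.45, 0.45)`; the remainder is unaffiliated).
#' @param latent_tau Time constant of the Ornstein-Uhlenbeck latent
#'   drives, seconds (default 5).
#' @param latent_rho Instantaneous correlation between the two latents
#'   (default -0.8).
#' @param log_rate_gain Gain `g` coupling the latent into log rate
#'   (default 1).
#' @param base_rates Log-uniform range of baseline rates in Hz (default
#'   `c(0.5, 20)`).
#' @param array Electrode grid: `list(pitch_um, rows, cols)` (default 12
#'   rows x 10 cols at 100 um).
#' @param depth_offset Vertical offset between the two ensembles' centres,
#'   as a fraction of array height (default 0.5).
#' @param depth_spread SD of each ensemble's truncated-Gaussian
#'   y-placement, as a fraction of array height (default 0.25).
#' @param seed Integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 150, duration = 600,
                         ensemble_fractions = c(0.45, 0.45),
                         latent_tau = 5, latent_rho = -0.8,
                         log_rate_gain = 1,
                         base_rates = c(0.5, 20),
                         array = list(pitch_um = 100, rows = 12, cols = 10),
                         depth_offset = 0.5, depth_spread = 0.25,
                         seed = 1L) {
  stopifnot(abs(latent_rho) <= 1, all(base_rates > 0),
            all(ensemble_fractions >= 0), sum(ensemble_fractions) <= 1)
  structure(list(n_neurons = n_neurons, duration = duration,
                 ensemble_fractions = ensemble_fractions,
                 latent_tau = latent_tau, latent_rho = latent_rho,
                 log_rate_gain = log_rate_gain, base_rates = base_rates,
                 array = array, depth_offset = depth_offset,
                 depth_spread = depth_spread, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate the two anti-correlated latent drives
#'
#' Two stationary, unit-variance Ornstein-Uhlenbeck processes with time
#' constant `latent_tau` and instantaneous cross-correlation `latent_rho`,
#' simulated by exact discretisation on a lattice (default 1 ms): the AR(1)
#' update `x[k+1] = a x[k] + sqrt(1 - a^2) e[k]` with `a = exp(-dt/tau)`
#' and bivariate-normal innovations whose correlation equals `latent_rho`
#' (which then also equals the stationary cross-correlation).
#'
#' @param cfg A `synth_config`.
#' @param dt Lattice step in seconds (default 0.001).
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `t` (times), `x` (steps x 2 matrix), `dt`.
#' @export
gen_latents <- function(cfg, dt = 0.001, seed = NULL) {
  if (abs(cfg$latent_rho) > 1) stop("cross-correlation must be in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(cfg$duration / dt)
  a <- exp(-dt / cfg$latent_tau)
  rho <- cfg$latent_rho
  e1 <- stats::rnorm(n); e0 <- stats::rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * e0
  z0 <- stats::rnorm(1); z0b <- stats::rnorm(1)
  init1 <- z0; init2 <- rho * z0 + sqrt(1 - rho^2) * z0b  # stationary init
  b <- sqrt(1 - a^2)
  x1 <- c(init1, as.numeric(stats::filter(b * e1[-1], a, "recursive",
                                          init = init1)))
  x2 <- c(init2, as.numeric(stats::filter(b * e2[-1], a, "recursive",
                                          init = init2)))
  list(t = (seq_len(n) - 1) * dt, x = cbind(x1, x2), dt = dt)
}

#' Simulate a two-ensemble Cox-process recording
#'
#' Each neuron in ensemble `e` fires as an inhomogeneous Poisson process
#' with log-normal rate coupling to its ensemble's latent:
#' `lambda_i(t) = r_i * exp(g * x_e(t) - g^2/2)`. The `-g^2/2` term keeps
#' the mean rate at the baseline `r_i` (the latent has unit variance), and
#' the exponential link makes rate fluctuations scale with the mean,
#' giving the super-Poissonian dispersion seen in cortical firing.
#' Unaffiliated neurons are homogeneous Poisson. Spikes are generated by
#' Bernoulli thinning on the latent lattice, with automatic refinement of
#' the lattice whenever `lambda * dt` approaches 1, and uniform jitter
#' within the lattice step.
#'
#' Positions: x uniform across the array; y drawn from an
#' ensemble-specific truncated Gaussian (ensemble 1 superficial, ensemble
#' 2 deep, centres `depth_offset` of the array height apart, SD
#' `depth_spread` of the height); unaffiliated neurons uniform. Waveform
#' widths are drawn bimodally (narrow ~0.3 ms for 30% of neurons, broad
#' ~0.9 ms) and amplitudes log-normally, so sorting-derived metadata is
#' populated.
#'
#' @param cfg A `synth_config`.
#' @param latents Optional output of [gen_latents()]; generated from
#'   `cfg$seed` otherwise.
#' @return List with `recording` (a `spike_recording`) and `truth`
#'   (data.frame: neuron_id, ensemble, base_rate, x_um, y_um; attribute
#'   `latents`).
#' @export
gen_cox_spikes <- function(cfg, latents = NULL) {
  set.seed(cfg$seed)
  if (is.null(latents)) latents <- gen_latents(cfg, seed = cfg$seed)
  n <- cfg$n_neurons
  n1 <- round(cfg$ensemble_fractions[1] * n)
  n2 <- round(cfg$ensemble_fractions[2] * n)
  ensemble <- c(rep(1L, n1), rep(2L, n2), rep(0L, n - n1 - n2))
  lr <- log(cfg$base_rates)
  rates <- exp(stats::runif(n, lr[1], lr[2]))
  g <- cfg$log_rate_gain
  width_um <- (cfg$array$cols - 1) * cfg$array$pitch_um
  height_um <- (cfg$array$rows - 1) * cfg$array$pitch_um
  centres <- c(0.5 * height_um,                            # unaffiliated
               (0.5 - cfg$depth_offset / 2) * height_um,   # ensemble 1
               (0.5 + cfg$depth_offset / 2) * height_um)   # ensemble 2
  rtruncnorm <- function(mu, sdv, lo, hi) {
    repeat {
      z <- stats::rnorm(1, mu, sdv)
      if (z >= lo && z <= hi) return(z)
    }
  }
  xs <- stats::runif(n, 0, width_um)
  ys <- vapply(ensemble, function(e) {
    if (e == 0L) stats::runif(1, 0, height_um)
    else rtruncnorm(centres[e + 1L], cfg$depth_spread * height_um,
                    0, height_um)
  }, numeric(1))
  narrow <- stats::runif(n) < 0.3
  widths <- ifelse(narrow, stats::rnorm(n, 0.30, 0.05),
                   stats::rnorm(n, 0.90, 0.15))
  widths <- pmax(widths, 0.05)
  amps <- exp(stats::rnorm(n, log(80), 0.4))
  dt0 <- latents$dt
  nlat <- nrow(latents$x)
  trains <- vector("list", n)
  ids <- sprintf("n%03d", seq_len(n))
  for (i in seq_len(n)) {
    lam <- if (ensemble[i] == 0L) rep(rates[i], nlat)
           else rates[i] * exp(g * latents$x[, ensemble[i]] - g^2 / 2)
    # Bernoulli thinning with lattice refinement when lambda*dt approaches 1
    refine <- max(1L, ceiling(max(lam) * dt0 / 0.5))
    dt_s <- dt0 / refine
    p <- rep(lam, each = refine) * dt_s
    hit <- which(stats::runif(length(p)) < p)
    tt <- (hit - 1) * dt_s + stats::runif(length(hit)) * dt_s
    tt <- sort(tt[tt < cfg$duration])
    tt <- tt[!duplicated(tt)]
    row_idx <- floor(ys[i] / cfg$array$pitch_um)
    col_idx <- floor(xs[i] / cfg$array$pitch_um)
    trains[[i]] <- spike_train(ids[i], tt,
                               electrode_id = sprintf("e%02d_%02d", row_idx, col_idx),
                               position = c(xs[i], ys[i]),
                               waveform_amplitude = amps[i],
                               waveform_width = widths[i])
  }
  rec <- recording(trains, duration = cfg$duration,
                   array_geometry = cfg$array)
  truth <- data.frame(neuron_id = ids, ensemble = ensemble,
                      base_rate = rates, x_um = xs, y_um = ys,
                      width_ms = widths, amplitude_uv = amps)
  attr(truth, "latents") <- latents
  list(recording = rec, truth = truth)
}

#' Gamma-renewal spike trains with a common shape parameter
#'
#' Calibration generator for the fluctuation-scaling fit: ISIs are i.i.d.
#' gamma with fixed shape `k` and per-neuron scale chosen so the mean ISI
#' is `1/rate`. The coefficient of variation `1/sqrt(k)` is then identical
#' across neurons, so the log-log regression of ISI SD on ISI mean has
#' slope 1. `k = 1` gives exponential ISIs (a homogeneous Poisson
#' process).
#'
#' @param n_neurons Number of trains.
#' @param shape Gamma shape `k > 0`.
#' @param rate_range Log-uniform range of target rates in Hz.
#' @param duration Recording length (s).
#' @param seed Optional integer seed.
#' @return A `spike_recording`.
#' @export
gen_renewal <- function(n_neurons, shape, rate_range = c(0.1, 20),
                        duration = 600, seed = NULL) {
  stopifnot(shape > 0)
  if (!is.null(seed)) set.seed(seed)
  lr <- log(rate_range)
  rates <- exp(stats::runif(n_neurons, lr[1], lr[2]))
  trains <- lapply(seq_len(n_neurons), function(i) {
    scale <- 1 / (rates[i] * shape)          # mean ISI = 1/rate
    n_draw <- max(20, ceiling(rates[i] * duration * 1.5 + 50))
    tt <- cumsum(stats::rgamma(n_draw, shape = shape, scale = scale))
    while (length(tt) && tt[length(tt)] < duration) {
      tt <- c(tt, tt[length(tt)] +
                cumsum(stats::rgamma(n_draw, shape = shape, scale = scale)))
    }
    tt <- tt[tt < duration]
    tt <- tt[!duplicated(tt)]
    spike_train(sprintf("g%03d", i), tt)
  })
  recording(trains, duration = duration)
}

#' Sinusoidally rate-modulated Poisson spike train
#'
#' Inhomogeneous Poisson process with
#' `lambda(t) = rate * (1 + mod_depth * sin(2 pi f t))`, generated by
#' exact thinning of a homogeneous process at the peak rate. Used to
#' calibrate spectral-peak detection.
#'
#' @param rate_hz Mean rate (Hz).
#' @param mod_freq_hz Modulation frequency (Hz).
#' @param mod_depth Modulation depth in `[0, 1]`.
#' @param duration Length (s).
#' @param seed Optional integer seed.
#' @param neuron_id Id of the returned train.
#' @return A `spike_train`.
#' @export
gen_modulated <- function(rate_hz, mod_freq_hz, mod_depth, duration,
                          seed = NULL, neuron_id = "mod1") {
  stopifnot(mod_depth >= 0, mod_depth <= 1)
  if (!is.null(seed)) set.seed(seed)
  lam_max <- rate_hz * (1 + mod_depth)
  n_cand <- stats::rpois(1, lam_max * duration)
  tt <- sort(stats::runif(n_cand, 0, duration))
  lam <- rate_hz * (1 + mod_depth * sin(2 * pi * mod_freq_hz * tt))
  keep <- stats::runif(n_cand) < lam / lam_max
  tt <- tt[keep]
  tt <- tt[!duplicated(tt)]
  spike_train(neuron_id, tt)
}
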