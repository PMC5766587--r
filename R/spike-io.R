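#' Construct a single-neuron spike train
#'
#' A `spike_train` holds the sorted spike times (seconds from recording
#' start) of one neuron, plus optional metadata carried along from spike
#' sorting: the electrode it was detected on, its position on the array
#' (micrometres), and the amplitude (microvolts) and width (milliseconds)
#' of its mean waveform.
#'
#' @param neuron_id Character scalar, unique within a recording.
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing and non-negative.
#' @param electrode_id Optional character scalar.
#' @param position Optional numeric length-2 vector `c(x_um, y_um)`.
#' @param waveform_amplitude Optional positive scalar (microvolts).
#' @param waveform_width Optional positive scalar (milliseconds).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, spike_times, electrode_id = NULL,
                        position = NULL, waveform_amplitude = NULL,
                        waveform_width = NULL) {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L)
  spike_times <- as.numeric(spike_times)
  if (any(spike_times < 0))
    stop("neuron '", neuron_id, "': negative spike times")
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("neuron '", neuron_id, "': spike times not strictly increasing")
  if (!is.null(position)) {
    position <- as.numeric(position)
    stopifnot(length(position) == 2L)
  }
  if (!is.null(waveform_width) && waveform_width <= 0)
    stop("neuron '", neuron_id, "': waveform width must be positive")
  structure(list(neuron_id = neuron_id, spike_times = spike_times,
                 electrode_id = electrode_id, position = position,
                 waveform_amplitude = waveform_amplitude,
                 waveform_width = waveform_width),
            class = "spike_train")
}

#' Construct a multi-neuron recording
#'
#' @param trains List of [spike_train] objects with unique neuron ids.
#' @param duration Recording duration in seconds; defaults to the latest
#'   spike time across neurons.
#' @param array_geometry Optional list `list(pitch_um=, rows=, cols=)`
#'   describing the electrode grid.
#' @return An object of class `spike_recording`.
#' @export
recording <- function(trains, duration = NULL, array_geometry = NULL) {
  stopifnot(is.list(trains), length(trains) >= 1L)
  ids <- vapply(trains, function(tr) tr$neuron_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate neuron ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tmax <- suppressWarnings(max(vapply(trains, function(tr)
    if (length(tr$spike_times)) max(tr$spike_times) else -Inf, numeric(1))))
  if (is.null(duration)) duration <- max(tmax, 0)
  if (duration < tmax) stop("duration shorter than latest spike time")
  names(trains) <- ids
  structure(list(trains = trains, duration = as.numeric(duration),
                 array_geometry = array_geometry),
            class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  ns <- vapply(x$trains, function(tr) length(tr$spike_times), integer(1))
  cat(sprintf("spike_recording: %d neurons, %.1f s, %d spikes total\n",
              length(x$trains), x$duration, sum(ns)))
  invisible(x)
}

#' Number of neurons in a recording
#' @param rec A `spike_recording`.
#' @return Integer count.
#' @export
n_neurons <- function(rec) length(rec$trains)

#' Neuron ids of a recording
#' @param rec A `spike_recording`.
#' @return Character vector.
#' @export
neuron_ids <- function(rec) names(rec$trains)

#' Read sorted spike trains from disk
#'
#' CSV input is long format with columns `neuron_id` and `spike_time_s`;
#' a JSON sidecar (or `metadata` argument) can supply per-neuron
#' `electrode_id`, `x_um`, `y_um`, `amplitude_uv`, `width_ms`. JSON input
#' is a single object `{duration_s, neurons: {id: {spike_times_s, ...}}}`
#' as written by [write_spikes()].
#'
#' Out-of-order times are sorted with a warning; exact duplicate
#' (neuron, time) pairs are dropped with a warning; negative times are an
#' error naming the offending neuron.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param duration Optional recording duration (s); defaults to the latest
#'   spike time.
#' @param metadata Optional path to a JSON sidecar with per-neuron metadata.
#' @return A `spike_recording`.
#' @export
read_spikes <- function(path, format = c("auto", "csv", "json"),
                        duration = NULL, metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  meta <- NULL
  if (!is.null(metadata)) meta <- jsonlite::read_json(metadata)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty spike file: ", path)
    if (!all(c("neuron_id", "spike_time_s") %in% names(df)))
      stop("CSV must have columns neuron_id, spike_time_s")
    rec <- .rec_from_long(df$neuron_id, df$spike_time_s, meta, duration)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$neurons) || length(obj$neurons) == 0L)
      stop("empty spike file: ", path)
    ids <- rep(names(obj$neurons),
               vapply(obj$neurons, function(x) length(x$spike_times_s), integer(1)))
    tms <- unlist(lapply(obj$neurons, function(x) x$spike_times_s),
                  use.names = FALSE)
    if (is.null(meta)) {
      meta <- lapply(obj$neurons, function(x)
        x[setdiff(names(x), "spike_times_s")])
    }
    if (is.null(duration)) duration <- obj$duration_s
    rec <- .rec_from_long(ids, tms, meta, duration)
  }
  rec
}

.rec_from_long <- function(ids, times, meta, duration) {
  ids <- as.character(ids)
  times <- as.numeric(times)
  neg <- unique(ids[times < 0])
  if (length(neg)) stop("negative spike times for neuron(s): ",
                        paste(neg, collapse = ", "))
  split_times <- split(times, factor(ids, levels = unique(ids)))
  trains <- lapply(names(split_times), function(id) {
    tt <- split_times[[id]]
    if (is.unsorted(tt, strictly = FALSE)) {
      warning("neuron '", id, "': spike times out of order; sorted on load")
      tt <- sort(tt)
    }
    dup <- duplicated(tt)
    if (any(dup)) {
      warning("neuron '", id, "': ", sum(dup),
              " duplicate spike time(s) dropped")
      tt <- tt[!dup]
    }
    m <- meta[[id]]
    spike_train(id, tt,
                electrode_id = .null_or(m$electrode_id),
                position = if (!is.null(m$x_um)) c(m$x_um, m$y_um),
                waveform_amplitude = .null_or(m$amplitude_uv),
                waveform_width = .null_or(m$width_ms))
  })
  recording(trains, duration = duration)
}

.null_or <- function(x) if (is.null(x)) NULL else x

#' Write a recording to disk
#'
#' `format = "csv"` writes the long-format spike table (plus a JSON
#' metadata sidecar at `<path>.neurons.json` when any train carries
#' metadata); `format = "json"` writes a single self-contained file.
#'
#' @param rec A `spike_recording`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- do.call(rbind, lapply(rec$trains, function(tr)
      if (length(tr$spike_times))
        data.frame(neuron_id = tr$neuron_id, spike_time_s = tr$spike_times)))
    utils::write.csv(df, path, row.names = FALSE)
    metas <- .meta_list(rec)
    if (any(vapply(metas, function(m) length(m) > 0L, logical(1))))
      jsonlite::write_json(metas, paste0(path, ".neurons.json"),
                           auto_unbox = TRUE, digits = NA)
  } else {
    neurons <- lapply(rec$trains, function(tr) {
      out <- list(spike_times_s = tr$spike_times)
      c(out, .meta_one(tr))
    })
    jsonlite::write_json(list(duration_s = rec$duration, neurons = neurons),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.meta_one <- function(tr) {
  m <- list()
  if (!is.null(tr$electrode_id)) m$electrode_id <- tr$electrode_id
  if (!is.null(tr$position)) { m$x_um <- tr$position[1]; m$y_um <- tr$position[2] }
  if (!is.null(tr$waveform_amplitude)) m$amplitude_uv <- tr$waveform_amplitude
  if (!is.null(tr$waveform_width)) m$width_ms <- tr$waveform_width
  m
}

.meta_list <- function(rec) lapply(rec$trains, .meta_one)

#' Remove cross-electrode duplicate neurons
#'
#' Spike trains that appear on more than one electrode with sub-millisecond
#' delays are taken to come from a single neuron picked up at several
#' sites. Two trains on different electrodes are considered duplicates when
#' at least `match_frac` of the shorter train's spikes have a one-to-one
#' partner in the other train within `max_lag`. Duplicate groups are formed
#' transitively (union-find) and only the member with the greatest waveform
#' amplitude is kept.
#'
#' @param rec A `spike_recording`.
#' @param max_lag Maximum spike-time delay in seconds (default 1 ms).
#' @param match_frac Minimum matched fraction of the shorter train
#'   (default 0.9).
#' @return A `spike_recording` with duplicates removed; attribute
#'   `removed_ids` lists the eliminated neurons.
#' @export
deduplicate_neurons <- function(rec, max_lag = 0.001, match_frac = 0.9) {
  n <- n_neurons(rec)
  ids <- neuron_ids(rec)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- rec$trains[[i]]; tj <- rec$trains[[j]]
    if (!is.null(ti$electrode_id) && !is.null(tj$electrode_id) &&
        identical(ti$electrode_id, tj$electrode_id)) next
    if (.match_fraction(ti$spike_times, tj$spike_times, max_lag) >= match_frac) {
      if (is.null(ti$waveform_amplitude) || is.null(tj$waveform_amplitude))
        stop("neurons '", ids[i], "' and '", ids[j], "' look like duplicates ",
             "but lack waveform amplitudes; disable dedup or supply amplitudes")
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) == 1L) { keep[members] <- TRUE; next }
    amps <- vapply(rec$trains[members],
                   function(tr) tr$waveform_amplitude, numeric(1))
    keep[members[which.max(amps)]] <- TRUE
  }
  out <- recording(rec$trains[keep], duration = rec$duration,
                   array_geometry = rec$array_geometry)
  attr(out, "removed_ids") <- ids[!keep]
  out
}

# greedy one-to-one matching of the shorter train into the longer,
# both sorted; counts matches within max_lag
.match_fraction <- function(a, b, max_lag) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  if (length(a) == 0L) return(0)
  i <- 1L; j <- 1L; m <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    if (abs(d) <= max_lag) { m <- m + 1L; i <- i + 1L; j <- j + 1L }
    else if (d > 0) j <- j + 1L
    else i <- i + 1L
  }
  m / na
}

#' Remove low-rate neurons
#'
#' Neurons firing at an average rate strictly below `min_rate` over the
#' whole recording are eliminated from all further analyses.
#'
#' @param rec A `spike_recording` with positive duration.
#' @param min_rate Threshold in spikes per minute (default 10).
#' @return A `spike_recording`; attributes `removed_ids` and `n_removed`
#'   report the eliminated neurons.
#' @export
filter_low_rate <- function(rec, min_rate = 10) {
  stopifnot(rec$duration > 0)
  rates <- vapply(rec$trains, function(tr)
    length(tr$spike_times) / rec$duration * 60, numeric(1))
  keep <- rates >= min_rate
  if (!any(keep)) stop("all neurons below ", min_rate, " spikes/min")
  out <- recording(rec$trains[keep], duration = rec$duration,
                   array_geometry = rec$array_geometry)
  attr(out, "removed_ids") <- neuron_ids(rec)[!keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Interspike-interval statistics
#'
#' ISIs are the temporal differences between consecutive spikes of one
#' neuron. The mean and sample (n-1 denominator) standard deviation are
#' reported together with the firing rate in spikes per minute. With fewer
#' than two spikes the ISI fields are `NA` but the rate is still computed.
#'
#' @param x A `spike_train` or `spike_recording`.
#' @param duration Recording duration in seconds (taken from the recording
#'   when `x` is one).
#' @return A data.frame with columns `neuron_id`, `n_spikes`, `rate`
#'   (spikes/min), `mean_isi`, `sd_isi` (seconds).
#' @export
isi_stats <- function(x, duration = NULL) {
  if (inherits(x, "spike_recording")) {
    res <- do.call(rbind, lapply(x$trains, isi_stats, duration = x$duration))
    rownames(res) <- NULL
    return(res)
  }
  stopifnot(inherits(x, "spike_train"))
  if (is.null(duration)) stop("duration required for a bare spike_train")
  ns <- length(x$spike_times)
  isi <- diff(x$spike_times)
  data.frame(neuron_id = x$neuron_id, n_spikes = ns,
             rate = ns / duration * 60,
             mean_isi = if (ns >= 2) mean(isi) else NA_real_,
             sd_isi = if (ns >= 2) stats::sd(isi) else NA_real_)
}

#' Fit the fluctuation-scaling (Taylor's-law) exponent of ISI dispersion
#'
#' Ordinary least squares of log10(SD of ISI) on log10(mean ISI) across
#' neurons. The slope is the power-law exponent: slope 1 means the SD is
#' proportional to the mean (constant coefficient of variation), the
#' signature of super-Poissonian firing.
#'
#' @param stats Data.frame from [isi_stats()] (columns `mean_isi`,
#'   `sd_isi`).
#' @return A list of class `taylor_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_used`.
#' @export
fit_taylor_law <- function(stats) {
  ok <- is.finite(stats$mean_isi) & is.finite(stats$sd_isi) &
    stats$mean_isi > 0
  nz <- ok & stats$sd_isi > 0
  if (!any(nz)) stop("all neurons have zero ISI standard deviation")
  if (sum(ok & !nz) > 0)
    warning(sum(ok & !nz), " neuron(s) with sd_isi = 0 excluded from fit")
  if (sum(nz) < 3) stop("need at least 3 neurons with sd_isi > 0")
  lx <- log10(stats$mean_isi[nz]); ly <- log10(stats$sd_isi[nz])
  fit <- stats::lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_used = sum(nz)),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor's-law fit: slope %.3f, intercept %.3f, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_used))
  invisible(x)
}

#' Classify neurons by spike width
#'
#' Spike-width distributions over a cortical population are typically
#' bimodal: narrow spikes (putative fast-spiking interneurons) versus
#' broad spikes (putative excitatory cells). A two-component Gaussian
#' mixture is fit to the widths; when the components are too close to call
#' (separation below `min_separation` pooled SDs) or the fit fails, the
#' distribution is treated as unimodal and every neuron is labelled
#' `"broad"` with a warning. A histogram-valley fallback is used if the
#' mixture fit errors out.
#'
#' @param rec A `spike_recording` whose trains all carry `waveform_width`.
#' @param min_separation Minimum standardized distance between component
#'   means to accept bimodality (default 2).
#' @return A list of class `spike_width_classes` with `labels` (named
#'   character vector, `"narrow"`/`"broad"`), `cut` (width at the class
#'   boundary, ms; `NA` when unimodal) and `means`.
#' @export
classify_spike_widths <- function(rec, min_separation = 2) {
  widths <- vapply(rec$trains, function(tr) {
    if (is.null(tr$waveform_width))
      stop("neuron '", tr$neuron_id, "' has no waveform width")
    tr$waveform_width
  }, numeric(1))
  ids <- neuron_ids(rec)
  unimodal <- function(msg) {
    warning("spike-width distribution treated as unimodal (", msg,
            "); all neurons labelled 'broad'")
    structure(list(labels = stats::setNames(rep("broad", length(ids)), ids),
                   cut = NA_real_, means = mean(widths)),
              class = "spike_width_classes")
  }
  if (diff(range(widths)) < .Machine$double.eps * 100)
    return(unimodal("all widths identical"))
  if (length(widths) < 10) {
    # too few neurons for a mixture fit: split at the largest gap if it
    # clearly dominates the remaining spacings
    sw <- sort(widths)
    gaps <- diff(sw)
    k <- which.max(gaps)
    if (gaps[k] < 3 * stats::median(gaps[-k]) || length(gaps) < 3)
      return(unimodal("too few neurons, no dominant gap"))
    cutv <- (sw[k] + sw[k + 1]) / 2
    lab <- ifelse(widths <= cutv, "narrow", "broad")
    return(structure(list(labels = stats::setNames(lab, ids), cut = cutv,
                          means = c(narrow = mean(widths[lab == "narrow"]),
                                    broad = mean(widths[lab == "broad"]))),
                     class = "spike_width_classes"))
  }
  fit <- tryCatch(
    mclust::Mclust(widths, G = 2, modelNames = c("V", "E"), verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(fit)) {
    mu <- as.numeric(fit$parameters$mean)
    sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sig) == 1L) sig <- rep(sig, 2)
    sep <- abs(diff(mu)) / sqrt(mean(sig^2))
    if (!is.finite(sep) || sep < min_separation)
      return(unimodal(sprintf("component separation %.2f SD", sep)))
    narrow_comp <- which.min(mu)
    lab <- ifelse(fit$classification == narrow_comp, "narrow", "broad")
  } else {
    # fallback: deepest histogram valley between the two outer modes
    h <- graphics::hist(widths, breaks = "FD", plot = FALSE)
    dens <- h$counts
    valley <- which.min(dens[-c(1, length(dens))]) + 1L
    cutv <- h$mids[valley]
    lab <- ifelse(widths <= cutv, "narrow", "broad")
    if (length(unique(lab)) < 2) return(unimodal("no histogram valley"))
  }
  cutv <- (max(widths[lab == "narrow"]) + min(widths[lab == "broad"])) / 2
  structure(list(labels = stats::setNames(lab, ids), cut = cutv,
                 means = c(narrow = mean(widths[lab == "narrow"]),
                           broad = mean(widths[lab == "broad"]))),
            class = "spike_width_classes")
}
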