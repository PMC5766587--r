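#' Pipeline configuration
#'
#' Collects the analysis defaults: the 20-step logarithmic timescale grid
#' from 1 ms to 31.623 s, the 10 spikes/min low-rate filter, 3000
#' permutations per pair with significance thresholds 0.005/0.995, and the
#' ACA optimiser settings. All parameters are serialised into every output
#' bundle for provenance.
#'
#' Permutation testing is the computational bottleneck at the fastest
#' timescales, so `conn_dts` selects the timescales at which the
#' permutation/adjacency stage runs (default: the five decades
#' 1 ms, 100 ms, 1 s, 10 s and 31.623 s); set `conn_dts = grid$dts` for
#' the full grid. Correlation matrices and ACA run at every grid
#' timescale regardless.
#'
#' @param grid A [make_timescale_grid()] object.
#' @param min_rate Low-rate threshold, spikes/min.
#' @param n_perm Permutations per pair.
#' @param p_lo,p_hi Significance thresholds on the left-tailed P-value.
#' @param aca_n_starts,aca_tol ACA optimiser settings.
#' @param conn_dts Timescales (s) for the permutation/adjacency stage;
#'   `NULL` picks the five-decade subset of the grid.
#' @param dedup Run cross-electrode deduplication first.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = make_timescale_grid(),
                            min_rate = 10, n_perm = 3000,
                            p_lo = 0.005, p_hi = 0.995,
                            aca_n_starts = 16, aca_tol = 1e-6,
                            conn_dts = NULL, dedup = FALSE,
                            seed = 1L, out_dir = NULL) {
  want <- if (is.null(conn_dts)) c(1e-3, 0.1, 1, 10, max(grid$dts))
          else conn_dts
  # snap to the nearest grid timescales
  conn_dts <- unique(vapply(want, function(w)
    grid$dts[which.min(abs(log10(grid$dts) - log10(w)))], numeric(1)))
  structure(list(grid = grid, min_rate = min_rate, n_perm = n_perm,
                 p_lo = p_lo, p_hi = p_hi, aca_n_starts = aca_n_starts,
                 aca_tol = aca_tol, conn_dts = conn_dts, dedup = dedup,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full multiscale analysis pipeline
#'
#' Stages, in order: low-rate filtering (optionally preceded by
#' cross-electrode deduplication); ISI statistics and the Taylor's-law
#' fit; per-timescale binning and correlation matrices over the whole
#' grid; permutation significance, adjacency and pruning of
#' never-connected neurons at the `conn_dts` timescales; graph metrics on
#' the pruned adjacency; ACA at every grid timescale (on the pruned,
#' valid-row correlation matrices); the slowest-timescale reference
#' networks; per-timescale contingency tables with entropy and Cohen's
#' kappa; network projections at the slowest timescale; and spatial
#' (laminar) KS tests when positions are available. All randomness derives
#' from `cfg$seed`.
#'
#' @param rec A `spike_recording`.
#' @param cfg A [pipeline_config()].
#' @return Object of class `acanet_bundle`; see Details. When
#'   `cfg$out_dir` is set, tidy CSV/JSON artifacts are written there.
#' @export
run_pipeline <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "spike_recording"), inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (cfg$dedup) rec <- stage("dedup", deduplicate_neurons(rec))
  rec <- stage("filter_low_rate", filter_low_rate(rec, cfg$min_rate))
  n_low <- attr(rec, "n_removed")
  istats <- stage("isi_stats", isi_stats(rec))
  taylor <- tryCatch(fit_taylor_law(istats), error = function(e) NULL)

  dts <- cfg$grid$dts
  conn_idx <- which(vapply(dts, function(d)
    any(abs(d - cfg$conn_dts) < 1e-12 * d), logical(1)))
  Cs <- vector("list", length(dts)); names(Cs) <- as.character(dts)
  conn <- list()
  bc_slow <- NULL
  for (k in seq_along(dts)) {
    dt <- dts[k]
    bc <- stage("bin", bin_spikes(rec, dt))
    Cs[[k]] <- stage("correlation", correlation_matrix(bc))
    if (k %in% conn_idx) {
      P <- stage("permutation",
                 permutation_pvalues(bc, n_perm = cfg$n_perm,
                                     seed = cfg$seed + 100L + k))
      A <- adjacency_matrix(Cs[[k]], P, lo = cfg$p_lo, hi = cfg$p_hi)
      conn[[as.character(dt)]] <- structure(
        list(dt = dt, C = Cs[[k]], P = P, A = A, metrics = NULL,
             neuron_ids = bc$neuron_ids),
        class = "connectivity_result")
    }
    if (k == length(dts)) bc_slow <- zscore_counts(bc)
    rm(bc)
  }

  pr <- stage("prune", prune_never_connected(lapply(conn, `[[`, "A")))
  keep <- pr$retained
  metrics <- do.call(rbind, lapply(conn, function(cr) {
    graph_metrics(cr$A[keep, keep, drop = FALSE], dt = cr$dt)
  }))
  rownames(metrics) <- NULL

  aca <- list()
  pos_all <- .positions_of(rec)
  for (k in seq_along(dts)) {
    Ck <- Cs[[k]][keep, keep, drop = FALSE]
    ok <- rownames(Ck)[stats::complete.cases(Ck)]
    Ck <- Ck[ok, ok, drop = FALSE]
    if (nrow(Ck) < 2) next
    pos <- if (!is.null(pos_all)) pos_all[ok, , drop = FALSE]
    fit <- stage("aca_fit",
                 aca_fit(Ck, n_starts = cfg$aca_n_starts,
                         seed = cfg$seed + 500L + k, tol = cfg$aca_tol,
                         positions = pos))
    fit$dt <- dts[k]
    aca[[as.character(dts[k])]] <- fit
  }

  reference <- stage("reference_networks", reference_networks(aca))
  cont <- lapply(aca, function(fit)
    contingency(reference, fit, dt = fit$dt))
  cont_df <- do.call(rbind, lapply(cont, function(ct)
    data.frame(dt = ct$dt, n = ct$n, h_bits = ct$entropy,
               kappa = ct$kappa, kappa_p = ct$kappa_p)))
  rownames(cont_df) <- NULL

  proj <- stage("project_networks", {
    ok <- reference$neuron_ids
    bcs <- bc_slow
    idx <- match(ok, bcs$neuron_ids)
    bcs$counts <- bcs$counts[idx, , drop = FALSE]
    bcs$neuron_ids <- ok
    bcs$valid <- bcs$valid[idx]
    project_networks(reference, bcs)
  })

  spatial <- NULL
  if (!is.null(pos_all)) {
    spatial <- tryCatch(spatial_bias_test(reference, pos_all),
                        error = function(e) NULL)
  }

  bundle <- structure(list(
    config = cfg, config_hash = .config_hash(cfg),
    n_neurons = n_neurons(rec), n_low_rate_removed = n_low,
    pruned = pr, isi = istats, taylor = taylor,
    correlations = Cs, connectivity = conn, metrics = metrics,
    aca = aca, reference = reference, contingency = cont,
    contingency_df = cont_df, projections = proj, spatial = spatial,
    positions = pos_all,
    versions = list(acanet = as.character(utils::packageVersion("acanet")),
                    R = R.version.string)),
    class = "acanet_bundle")
  if (!is.null(cfg$out_dir)) .write_bundle(bundle, cfg$out_dir)
  bundle
}

.positions_of <- function(rec) {
  has <- vapply(rec$trains, function(tr) !is.null(tr$position), logical(1))
  if (!all(has)) return(NULL)
  pos <- t(vapply(rec$trains, function(tr) tr$position, numeric(2)))
  colnames(pos) <- c("x", "y")
  rownames(pos) <- neuron_ids(rec)
  pos
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$metrics, file.path(dir, "graph_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$contingency_df, file.path(dir, "contingency.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$isi, file.path(dir, "isi_stats.csv"),
                   row.names = FALSE)
  ref <- bundle$reference
  utils::write.csv(data.frame(neuron_id = ref$neuron_ids, u = ref$u,
                              v = ref$v, network = ref$membership),
                   file.path(dir, "reference_loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$projections, file.path(dir, "projections.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$connectivity)) {
    cr <- bundle$connectivity[[nm]]
    tag <- gsub("[^0-9a-zA-Z.]", "_", nm)
    utils::write.csv(cr$C, file.path(dir, paste0("C_dt", tag, ".csv")))
    utils::write.csv(cr$P, file.path(dir, paste0("P_dt", tag, ".csv")))
    utils::write.csv(cr$A, file.path(dir, paste0("A_dt", tag, ".csv")))
  }
  if (!is.null(bundle$spatial))
    utils::write.csv(bundle$spatial, file.path(dir, "spatial_tests.csv"),
                     row.names = FALSE)
  log <- list(config = bundle$config[setdiff(names(bundle$config), "grid")],
              grid = bundle$config$grid$dts,
              config_hash = bundle$config_hash,
              versions = bundle$versions,
              n_neurons = bundle$n_neurons,
              n_low_rate_removed = bundle$n_low_rate_removed,
              n_pruned = bundle$pruned$n_removed)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.acanet_bundle <- function(x, ...) {
  cat(sprintf(
    "acanet_bundle [%s]: %d neurons (%d low-rate removed, %d never-connected pruned)\n",
    x$config_hash, x$n_neurons, x$n_low_rate_removed, x$pruned$n_removed))
  cat(sprintf("  %d timescales, %d with connectivity; reference L = %.4f\n",
              length(x$aca), length(x$connectivity), x$reference$L))
  invisible(x)
}

#' Summary figures for an analysis bundle
#'
#' Renders the standard panels from a pipeline bundle: the
#' membership-ordered correlation heatmap at the slowest timescale, graph
#' metrics and contingency entropy/kappa versus timescale, the
#' Taylor's-law scatter with its fit, the two network projection traces,
#' and (when positions exist) the spatial distribution of the two
#' networks. Panels whose stage is missing are skipped with a notice.
#' Every figure's caption carries the bundle's config hash.
#'
#' @param bundle An `acanet_bundle`.
#' @param out_dir Optional directory: each figure is also written as PNG.
#' @return Named list of ggplot objects.
#' @export
report <- function(bundle, out_dir = NULL) {
  stopifnot(inherits(bundle, "acanet_bundle"))
  cap <- paste0("config ", bundle$config_hash)
  figs <- list()

  ref <- bundle$reference
  Cslow <- bundle$correlations[[length(bundle$correlations)]]
  ord <- ref$neuron_ids[order(ref$membership, -ref$u + ref$v)]
  ord <- intersect(ord, rownames(Cslow))
  Cm <- Cslow[ord, ord]
  df <- data.frame(i = rep(seq_along(ord), times = length(ord)),
                   j = rep(seq_along(ord), each = length(ord)),
                   r = as.vector(Cm))
  figs$heatmap <- ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = sprintf("Correlation matrix at dt = %.3f s, ordered by network",
                                  max(as.numeric(names(bundle$correlations)))),
                  x = "neuron", y = "neuron", caption = cap)

  if (!is.null(bundle$metrics) && nrow(bundle$metrics)) {
    md <- stats::reshape(bundle$metrics[, c("dt", "largest_partition_fraction",
                                            "max_degree_normalized",
                                            "assortativity")],
                         direction = "long", idvar = "dt",
                         varying = 2:4, v.names = "value",
                         times = c("largest partition", "max degree / n",
                                   "assortativity"), timevar = "metric")
    figs$metrics <- ggplot2::ggplot(md, ggplot2::aes(.data$dt, .data$value)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "bin width (s)", caption = cap)
  } else .log("metrics panel skipped: stage missing")

  if (!is.null(bundle$contingency_df)) {
    figs$entropy <- ggplot2::ggplot(bundle$contingency_df,
                                    ggplot2::aes(.data$dt, .data$h_bits)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "bin width (s)", y = "contingency entropy (bits)",
                    caption = cap)
  }

  if (!is.null(bundle$taylor)) {
    ti <- bundle$isi[is.finite(bundle$isi$mean_isi) & bundle$isi$sd_isi > 0, ]
    figs$taylor <- ggplot2::ggplot(ti, ggplot2::aes(.data$mean_isi,
                                                    .data$sd_isi)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(intercept = bundle$taylor$intercept,
                           slope = bundle$taylor$slope) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "mean ISI (s)", y = "SD of ISI (s)",
                    title = sprintf("Fluctuation scaling: slope %.2f, R^2 %.2f",
                                    bundle$taylor$slope, bundle$taylor$r_squared),
                    caption = cap)
  } else .log("taylor panel skipped: stage missing")

  if (!is.null(bundle$projections)) {
    pr <- bundle$projections
    pd <- data.frame(t = rep(pr$bin_start_s, 2),
                     activity = c(pr$net1_activity, pr$net2_activity),
                     network = rep(c("Network 1", "Network 2"),
                                   each = nrow(pr)))
    figs$projections <- ggplot2::ggplot(pd, ggplot2::aes(.data$t,
                                                         .data$activity,
                                                         colour = .data$network)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "projected z-score",
                    title = sprintf("Network projections (r = %.2f)",
                                    attr(pr, "correlation")),
                    caption = cap)
  }

  if (!is.null(bundle$positions)) {
    lab <- bundle$reference$membership
    common <- intersect(names(lab), rownames(bundle$positions))
    pd <- data.frame(x = bundle$positions[common, 1],
                     y = bundle$positions[common, 2],
                     network = unname(lab[common]))
    figs$positions <- ggplot2::ggplot(pd, ggplot2::aes(.data$x, .data$y,
                                                       colour = .data$network)) +
      ggplot2::geom_point() + ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "x (um)", y = "depth (um)", caption = cap)
  } else .log("positions panel skipped: no positions")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(figs))
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), figs[[nm]],
                      width = 7, height = 5, dpi = 120)
  }
  figs
}
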