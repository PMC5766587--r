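#' Reference networks at the slowest timescale
#'
#' The two anti-correlated networks returned by ACA at the slowest
#' timescale of the grid define Network 1 and Network 2; partitions at all
#' other timescales (Population A / Population B) are compared against
#' this fixed reference.
#'
#' @param aca_results Named list of `aca_result` objects, names = bin
#'   widths in seconds (as produced by [run_pipeline()]).
#' @return The `aca_result` at the largest dt.
#' @export
reference_networks <- function(aca_results) {
  stopifnot(length(aca_results) >= 1L)
  dts <- suppressWarnings(as.numeric(names(aca_results)))
  if (anyNA(dts)) stop("aca_results must be named by bin width (s)")
  ref <- aca_results[[which.max(dts)]]
  if (!inherits(ref, "aca_result"))
    stop("ACA failed at the slowest timescale")
  ref
}

#' 2x2 contingency table of network vs population labels
#'
#' Cross-tabulates each neuron's reference network label (Net 1/Net 2,
#' from the slowest timescale) against its population label (Pop A/Pop B,
#' from ACA at the timescale under study). Only neurons labelled in both
#' partitions are counted (the intersection is used; unassigned neurons
#' are excluded). Population labels are aligned to the reference by
#' maximising the diagonal before Cohen's kappa is computed -- a guard
#' against arbitrary label switching, which entropy is invariant to but
#' kappa is not.
#'
#' @param reference An `aca_result` (or named label vector) giving Net
#'   1/Net 2.
#' @param population An `aca_result` (or named label vector) giving Pop
#'   A/Pop B.
#' @param dt Optional timescale tag.
#' @return Object of class `contingency_result`: `table` (2x2), `entropy`
#'   (bits), `kappa`, `kappa_p`, `n`, `dt`, `aligned` (whether columns
#'   were swapped).
#' @export
contingency <- function(reference, population, dt = NA_real_) {
  ref <- .labels_of(reference)
  pop <- .labels_of(population)
  common <- intersect(names(ref), names(pop))
  ref <- ref[common]; pop <- pop[common]
  keep <- ref %in% c("net1", "net2") & pop %in% c("net1", "net2")
  if (!any(keep)) stop("no neurons labelled in both partitions")
  if (sum(!keep) > 0)
    .log("%d neuron(s) unlabelled in one partition excluded from table",
         sum(!keep))
  ref <- factor(ref[keep], levels = c("net1", "net2"),
                labels = c("Net1", "Net2"))
  pop <- factor(pop[keep], levels = c("net1", "net2"),
                labels = c("PopA", "PopB"))
  tab <- table(ref, pop)
  aligned <- FALSE
  if (sum(diag(tab)) < sum(tab) - sum(diag(tab))) {
    tab <- tab[, 2:1]
    colnames(tab) <- colnames(tab)[2:1]
    aligned <- TRUE
  }
  kp <- cohens_kappa(tab)
  structure(list(table = tab, entropy = shannon_entropy(tab),
                 kappa = kp$kappa, kappa_p = kp$p, n = sum(tab),
                 dt = dt, aligned = aligned),
            class = "contingency_result")
}

.labels_of <- function(x) {
  if (inherits(x, "aca_result")) return(x$membership)
  if (is.null(names(x))) stop("need an aca_result or a named label vector")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("contingency_result: n = %d, H = %.3f bits, kappa = %.3f (P = %.3g)\n",
              x$n, x$entropy, x$kappa, x$kappa_p))
  print(x$table)
  invisible(x)
}

#' Shannon entropy of a contingency table
#'
#' `H = -sum_k p_k log2 p_k` over the cell proportions `p_k = n_k / n`,
#' with `0 log 0 = 0`; measured in bits. For a 2x2 table H ranges from 0
#' (all neurons in one cell) to 2 bits (four equal cells).
#'
#' @param table Matrix or table of non-negative counts.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(table) {
  n <- sum(table)
  stopifnot(n > 0)
  p <- as.numeric(table) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Cohen's kappa for a 2x2 contingency table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between
#' two binary labelings, with observed agreement `p_o` on the diagonal and
#' chance agreement `p_e` from the margins. The P-value is a one-sided
#' large-sample z-test of `kappa > 0` using the standard error of kappa
#' under independence; an optional permutation P-value (random label
#' shuffles) is available for small n.
#'
#' @param table 2x2 table of counts, `n >= 2`.
#' @param n_perm If > 0, also compute a permutation P-value.
#' @param seed Optional seed for the permutation test.
#' @return List with `kappa`, `p`, `se0`, and `p_perm` when requested;
#'   `kappa` is `NA` for degenerate margins (`p_e = 1`).
#' @export
cohens_kappa <- function(table, n_perm = 0, seed = NULL) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == 2L))
  n <- sum(tab)
  stopifnot(n >= 2)
  p <- tab / n
  po <- sum(diag(p))
  rm_ <- rowSums(p); cm_ <- colSums(p)
  pe <- sum(rm_ * cm_)
  if (1 - pe < .Machine$double.eps)
    return(list(kappa = NA_real_, p = NA_real_, se0 = NA_real_))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss' large-sample SE of kappa under the null of independence
  se0 <- sqrt(pe + pe^2 - sum(rm_ * cm_ * (rm_ + cm_))) / ((1 - pe) * sqrt(n))
  pval <- stats::pnorm(kappa / se0, lower.tail = FALSE)
  out <- list(kappa = kappa, p = pval, se0 = se0)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    ref <- rep(c(1, 2), times = rowSums(tab))
    pop <- c(rep(c(1, 2), times = tab[1, ]), rep(c(1, 2), times = tab[2, ]))
    kap_of <- function(a, b) {
      tt <- table(factor(a, 1:2), factor(b, 1:2))
      pp <- tt / n; poo <- sum(diag(pp))
      pee <- sum(rowSums(pp) * colSums(pp))
      (poo - pee) / (1 - pee)
    }
    null <- replicate(n_perm, kap_of(ref, sample(pop)))
    out$p_perm <- (sum(null >= kappa) + 1) / (n_perm + 1)
  }
  out
}

#' Spatial bias of the two networks across the array
#'
#' Two-sample Kolmogorov-Smirnov tests comparing the coordinate
#' distributions of the two networks' neurons, separately for the depth
#' (y) axis and the orthogonal (x) axis. A significant y-axis difference
#' with a non-significant x-axis difference indicates laminar bias.
#'
#' @param membership Named label vector (or `aca_result`) with values
#'   `net1`/`net2`.
#' @param positions Matrix or data.frame with columns `x`, `y` (um),
#'   rownames = neuron ids.
#' @return Data.frame with columns `axis`, `ks_stat`, `p`, `n1`, `n2`.
#' @export
spatial_bias_test <- function(membership, positions) {
  lab <- .labels_of(membership)
  pos <- as.matrix(positions[, 1:2])
  if (is.null(rownames(pos))) stop("positions must have neuron-id rownames")
  common <- intersect(names(lab), rownames(pos))
  lab <- lab[common]; pos <- pos[common, , drop = FALSE]
  i1 <- lab == "net1"; i2 <- lab == "net2"
  if (sum(i1) < 3 || sum(i2) < 3)
    stop("each network needs at least 3 positioned neurons")
  one_axis <- function(col, name) {
    kt <- suppressWarnings(stats::ks.test(pos[i1, col], pos[i2, col]))
    data.frame(axis = name, ks_stat = unname(kt$statistic),
               p = kt$p.value, n1 = sum(i1), n2 = sum(i2))
  }
  rbind(one_axis(2L, "y"), one_axis(1L, "x"))
}
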