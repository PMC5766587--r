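---
title: "Multiscale anti-correlated network analysis of spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale anti-correlated network analysis of spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acanet)
```

## The problem

Spontaneously active cortical populations recorded on planar
multielectrode arrays produce sorted spike trains whose structure spans
five orders of magnitude in time: single neurons burst at a few hertz,
fire tonically, and drift slowly over tens of seconds. Standard
band-pass filtering does not apply to point processes, so `acanet`
analyses the trains as *count processes*: the time axis is divided into
consecutive bins of width $\Delta t$ and spikes are counted per bin.
Sweeping $\Delta t$ over a logarithmic grid (20 steps from $10^{-3}$ s
to $10^{1.5} \approx 31.623$ s by default) exposes how correlation
structure between neurons changes with timescale. The headline
phenomenon the toolchain targets is the emergence, at slow timescales,
of two mutually exclusive neuronal networks whose population activities
are anti-correlated over time.

## Pipeline stages and their parameters

**Preprocessing.** Spike trains that appear on more than one electrode
with sub-millisecond delays are treated as duplicate detections of one
neuron; only the largest-amplitude copy is kept. Duplicate detection
needs an explicit match criterion, which we set to: at least 90% of the
shorter train's spikes one-to-one matched within 1 ms (both
configurable), with transitive (union-find) grouping so that chains of
pairwise duplicates collapse to a single survivor. Neurons with an
average rate below 10 spikes/min over the recording are removed
(strictly below: a neuron at exactly 10 spikes/min stays).

**Firing statistics.** Interspike intervals (ISIs) are consecutive
spike-time differences. The ISI standard deviation uses the sample
($n-1$) denominator — the conventional dispersion estimator; nothing
downstream is sensitive to the choice at the spike counts involved.
The fluctuation-scaling ("Taylor's law") fit regresses
$\log_{10}(\mathrm{SD\ ISI})$ on $\log_{10}(\mathrm{mean\ ISI})$
across neurons by ordinary least squares; a slope of 1 means the SD is
proportional to the mean, i.e. a constant coefficient of variation,
which is the super-Poissonian signature (a Poisson count process would
put the SD proportional to the square root of the mean). Neurons with
zero ISI variance have no defined log-SD and are excluded with a
logged count. Note the fit is defined on ISI statistics: an
exponential-ISI population also sits on slope 1, so the fit
characterises the scaling relation rather than adjudicating between
specific renewal models.

**Binning.** Bins are half-open $[t, t + \Delta t)$, 0-based; a
trailing partial bin is dropped rather than padded, so
$n_\mathrm{bins} = \lfloor T/\Delta t \rfloor$ and spikes past the last
full bin are not counted. Each binned series can be z-scored
(mean-subtracted, divided by its sample SD); rows with zero variance
cannot be normalised and are flagged invalid rather than silently
dropped — downstream stages exclude them and report how many.

**Spectra.** Multitaper spectra of the 1-ms-binned, z-scored trains use
Slepian (DPSS) tapers computed from the tridiagonal eigenproblem; for
series longer than 2048 samples the tapers are solved at 2048 points
and spline-interpolated, the standard large-$N$ approach. The defaults
($W = 1$ mHz, $K = 300$ tapers) are kept configurable because they sit
outside the usual $K \le 2TW - 1$ rule for a 600-s recording; a strict
mode enforces that bound by truncation with a warning. The absolute
normalisation of the reported power is documented (taper energy
normalised, one-sided) but no analysis below depends on it.

**Connectivity.** At each grid timescale the Pearson correlation matrix
$C$ of the binned counts is computed. Significance is assessed per pair
by permutation: both rows are independently permuted over bins and
re-correlated, 3000 times by default, and the left-tailed probability
$P$ of the empirical correlation relative to that pair's own null
sample is recorded. Ties count as "less or equal", which is
conservative for the negative-correlation criterion. Edges join pairs
with $P \le 0.005$ (significant negative) or $P \ge 0.995$ (significant
positive), both inclusive; the adjacency diagonal is zero. No
multiple-testing correction is applied — pairs are tested independently
at deliberately stringent thresholds, and the calibration test below
confirms the realised false-positive rate matches the nominal
$0.005 + (1 - 0.995) = 1\%$. Neurons with no edge at any analysed
timescale are pruned before the graph and ACA stages. Graph measures
follow the elementary definitions: largest-partition fraction (neurons
with degree $> 0$ over total), $\max(D)/n$, and assortativity as the
Pearson correlation of end-point degrees over edges with both
orientations counted (equivalent to the excess-degree version, since
Pearson correlation is shift-invariant).

The permutation stage is exact in distribution but implemented without
materialising permutations of the full bin axis: a random bijection of
bins contributes to the correlation only where both counts are nonzero,
so the null draw reduces to one hypergeometric variate (how many
occupied bins coincide) plus a without-replacement sample of the two
nonzero multisets. When counts take few distinct values — at fast
timescales they are nearly binary — that sample collapses further to a
small random contingency table. This is what makes 3000 permutations
per pair tractable at $\Delta t = 1$ ms, where a naive implementation
would shuffle $6 \times 10^5$ bins per replicate.

## Anti-correlated component analysis

Let $z(t)$ be the vector of z-scored counts in the bin starting at $t$,
so $C = \langle z(t) z^T(t) \rangle$. ACA seeks two non-negative
loading vectors on a joint unit sphere,

$$\min_{u, v} \; L = u^T C v
\quad \text{s.t.} \quad \|u\|^2 + \|v\|^2 = 1, \; u, v \ge 0,$$

i.e. it minimises the time-averaged product of the two projected
population signals $u^T z(t)$ and $v^T z(t)$. Writing $x = [u; v]$ and
$\tilde C = \begin{bmatrix} 0 & C \\ C & 0\end{bmatrix}$ turns the cost
into the quadratic form $\tfrac12 x^T \tilde C x$ — a hyperbolic saddle
whose restriction to the non-negative orthant of the sphere has a
well-defined minimum, unique when the spectrum of $\tilde C$ (the
eigenvalues of $C$ with both signs) is non-degenerate. At a solution
the supports of $u$ and $v$ are numerically disjoint, so the loadings
define two mutually exclusive networks, and $L \le 0$ always: any
negative entry of $C$ is exploitable by a disjoint-support feasible
point, and without negative correlation the degenerate solution with
one empty component attains $L = 0$.

The optimiser is a monotone alternating scheme: for fixed $v$ the cost
is linear in $u$ and its exact minimiser over
$\{u \ge 0,\ \|u\| = 1/\sqrt2\}$ is the scaled positive part of $-Cv$
(a vertex when $-Cv$ has no positive entry), and symmetrically for
$v$; the equal norm split is optimal whenever the cost is negative.
Each half-step solves its subproblem exactly, so $L$ is non-increasing
and converges. Because the feasible set is non-convex the scheme is run
from 16 starts by default — half non-negative random points on the
sphere, half seeded from the sign-split of the extreme eigenvectors of
$C$ (positive part into $u$, negative part into $v$, and the swap),
the natural relaxation of a two-block structure. The best local minimum
is returned, with the dispersion of $L$ across starts kept as a
uniqueness diagnostic rather than assuming the theoretical uniqueness
claim holds for every input. A membership tolerance of
$10^{-6} \times$ the largest loading separates "numerically zero" from
active loadings; neurons below it in both components are assigned to
the larger loading and flagged weak. Since $(u, v)$ and $(v, u)$ give
identical cost, labels are canonicalised: Network 1 is the component
with the smaller mean array depth when positions are available,
otherwise the one containing the lexicographically smallest neuron id.

The test suite verifies the optimiser against an independent
brute-force oracle (dense random sampling of the non-negative sphere in
$2n$ dimensions followed by multi-start Nelder–Mead polish in a squared
parameterisation) on all matrices up to $n = 4$, including the analytic
two-neuron case $C_{12} = -1 \Rightarrow L = -\tfrac12$,
$u = (1/\sqrt2, 0)$, $v = (0, 1/\sqrt2)$.

## Cross-timescale comparison

ACA memberships at the slowest grid timescale (31.623 s) define the
reference Network 1/Network 2; ACA at every other timescale yields
Population A/B. Each timescale's $2 \times 2$ contingency table counts
neurons by (network, population) pairing, over the neurons labelled in
both partitions. Two summaries are reported: the Shannon entropy
$H = -\sum_k p_k \log_2 p_k$ of the four cell proportions (0 bits: all
neurons in one cell; 2 bits: uniform blending; 1 bit: perfect balanced
agreement), and Cohen's unweighted $\kappa$ with a one-sided
large-sample z-test of $\kappa > 0$ using the standard error under
independence — the literature rarely names the test used with
$\kappa$, so the package states its choice and offers a
permutation-based P-value for small populations. Population labels are
aligned to the reference by maximising the table diagonal before
$\kappa$ is computed; entropy is invariant to that alignment, $\kappa$
is not, and an unguarded label switch would flip its sign. Spatial
(laminar) bias is tested by two-sample Kolmogorov–Smirnov comparisons
of the two networks' coordinate distributions, separately for the depth
axis and the orthogonal axis.

## What the synthetic generator emulates

`gen_cox_spikes()` builds the study conditions end to end: 150 neurons
over 600 s (defaults), baseline rates log-uniform in 0.5–20 Hz, two
ensembles of 45% each (the remaining 10% unaffiliated — a realistic
fraction of neurons that belong to neither slow mode), each ensemble
driven by one of two stationary unit-variance Ornstein–Uhlenbeck
latents with time constant 5 s and instantaneous cross-correlation
−0.8, discretised exactly on a 1-ms lattice. Neuron $i$ of ensemble $e$
fires as a Cox (doubly stochastic Poisson) process with
$\lambda_i(t) = r_i \exp(g x_e(t) - g^2/2)$, $g = 1$ by default. The
exponential link keeps rates positive and makes rate fluctuations scale
with the mean — reproducing the constant-CV, super-Poissonian scaling —
while the $-g^2/2$ term keeps the *expected* rate at $r_i$. Note that
preservation is in expectation: over a single 600-s realisation the
time-average of $\exp(g x_e(t))$ fluctuates, so individual empirical
rates wander by $\sim$10–15% around baseline while the population mean
stays within a few percent. Spikes are generated by Bernoulli thinning
on the lattice with automatic refinement when $\lambda \Delta t$
approaches 1, and uniform jitter within the lattice step to avoid
lattice-locking artifacts. Ensemble positions are depth-biased on a
12 × 10, 100-µm-pitch array: truncated-Gaussian y-placement with
centres half the array height apart and SD a quarter of the height
(ensemble 1 superficial), x uniform — so depth shows a bias and the
orthogonal axis does not. Waveform metadata (bimodal widths, log-normal
amplitudes) are attached so the spike-width classifier and
deduplication code paths are exercised on realistic inputs.

Two calibration generators complete the set: gamma-renewal trains with
a common shape $k$ (constant CV $= 1/\sqrt k$, hence Taylor slope 1 —
shape 0.25 gives the strongly super-Poissonian CV of 2) and
sinusoidally rate-modulated Poisson trains for spectral-peak checks.

What the generator does *not* emulate: refractoriness and bursting at
millisecond resolution, non-stationary state switches, more than two
latent modes, electrode-level waveform overlap, and any biophysics.
Passing the end-to-end tests therefore shows the pipeline recovers
planted slow anti-correlated structure of realistic strength — not that
cortical recordings contain such structure, nor that the method is
robust to artefacts the generator omits.

## Numerical choices and degenerate inputs

* Bin-edge handling is half-open with the trailing partial bin dropped;
  a spike exactly at the recording duration is not counted.
* Zero-variance rows are flagged, never silently dropped; correlation
  and P-value entries involving them are `NA` and they receive no
  edges.
* Permutation P-values count ties as less-or-equal; with $n_\mathrm{perm}$
  replicates the attainable P resolution is $1/n_\mathrm{perm}$, and a
  warning is raised below 200 replicates where the 0.005 threshold
  becomes unreachable.
* ACA convergence stops when the cost decreases by less than
  $10^{-12}$ per sweep; support overlaps above tolerance are resolved
  by zeroing the smaller loading and renormalising (rare in practice —
  the fixed point of the alternating map has disjoint supports whenever
  the diagonal dominates locally).
* An edgeless graph yields partition 0, degree 0 and undefined
  (`NA`) assortativity; degenerate $\kappa$ margins yield `NA` with the
  entropy still defined.
* The pipeline derives per-stage seeds from one master seed, so reruns
  are bit-identical.

## Problem sizes in the shipped tests

The packaged test-suite runs the full pipeline at the default study
conditions (150 neurons, 600 s, the 20-point grid) with the
permutation stage at its five-decade timescale subset and 500
replicates per pair — the reduced-replicate mode changes resolution,
not thresholds. Unit and property tests use smaller populations (tens
of neurons, minutes of data) chosen so each statistical assertion
retains comfortable power; oracle comparisons use $n \le 4$ where
exhaustive search is meaningful.

## A minimal run

```{r example, eval = FALSE}
cfg  <- synth_config(seed = 1)
sim  <- gen_cox_spikes(cfg)
pcfg <- pipeline_config(n_perm = 500, seed = 1)
bundle <- run_pipeline(sim$recording, pcfg)
print(bundle)
bundle$contingency_df      # entropy/kappa per timescale
report(bundle)             # standard figure panels
```

## Known limitations

ACA returns exactly two components; populations organised into more
than two slow modes will be folded onto the dominant anti-correlated
pair. The permutation null treats bins as exchangeable, which is
appropriate for testing instantaneous correlation but blind to
autocorrelation-induced inflation of correlation estimates at slow
timescales with few bins (at $\Delta t = 31.623$ s only 18 bins remain
from 600 s, and every quantity computed there is correspondingly
noisy). Assortativity on sparse graphs with near-constant degree is
numerically fragile and reported as `NA` when undefined. The CSV/JSON
readers assume spike times in seconds from recording start.
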