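# acanet

Multiscale analysis of spontaneous multielectrode-array spike
recordings: functional connectivity across logarithmically spaced
timescales, and **anti-correlated component analysis (ACA)** — a
constrained bilinear optimisation that splits a neuronal population
into two mutually exclusive, maximally anti-correlated networks.

The package is for electrophysiologists working downstream of spike
sorting: the input is per-neuron spike times (seconds), optionally with
electrode, position and waveform metadata.

## What it computes

Spike trains are treated as count processes: counts in consecutive bins
of width Δt, swept over 20 log-spaced timescales from 1 ms to
10^1.5 ≈ 31.623 s. Per timescale the pipeline computes

* the Pearson correlation matrix **C** of binned counts, with per-pair
  permutation significance (both rows independently permuted, 3000
  replicates; left-tailed *P* ≤ 0.005 or ≥ 0.995 defines an edge of the
  binary adjacency graph **A**), plus degree, largest-partition and
  assortativity graph measures;
* the ACA decomposition: non-negative loadings *u*, *v* minimising

  L = uᵀ C v  subject to ‖u‖² + ‖v‖² = 1, u, v ≥ 0,

  whose disjoint supports define Network 1 and Network 2, the two most
  anti-correlated sub-populations (the projected population signals
  uᵀz(t) and vᵀz(t) are maximally anti-correlated over time);
* cross-timescale comparison of each partition against the
  slowest-timescale reference: 2 × 2 contingency tables, Shannon
  entropy H = −Σ pₖ log₂ pₖ, Cohen's κ with a one-sided z-test, and
  laminar (depth-axis) Kolmogorov–Smirnov tests.

Neuron-level tools cover ISI statistics, the 10 spikes/min low-rate
filter, cross-electrode duplicate removal, the fluctuation-scaling
(Taylor's-law) fit of log₁₀ ISI SD on log₁₀ ISI mean, spike-width
classification, auto-correlograms and multitaper (Slepian) spectra.
A seed-deterministic Cox-process simulator — two neuron ensembles
driven by anti-correlated Ornstein–Uhlenbeck latents, heterogeneous
log-uniform rates, depth-biased placement on a 120-electrode array —
provides ground truth for end-to-end validation. See the vignette
(`vignettes/anticorrelated-networks.Rmd`) for the model details and
design choices.

## Worked example

```r
library(acanet)

cfg  <- synth_config(n_neurons = 60, duration = 300, seed = 1)
sim  <- gen_cox_spikes(cfg)
pcfg <- pipeline_config(grid = make_timescale_grid(1e-3, 10^1.5, 10),
                        n_perm = 500, seed = 1)
bundle <- run_pipeline(sim$recording, pcfg)
print(bundle)
#> acanet_bundle [000dbc8e]: 60 neurons (0 low-rate removed, 1 never-connected pruned)
#>   10 timescales, 5 with connectivity; reference L = -5.5756

fit_taylor_law(isi_stats(sim$recording))
#> Taylor's-law fit: slope 0.922, intercept 0.209, R^2 0.950 (n = 60)

round(subset(bundle$contingency_df, select = -kappa_p), 3)
#>        dt  n h_bits kappa
#> 1   0.001 58  1.182 0.931
#> ...
#> 10 31.623 58  0.999 1.000

attr(bundle$projections, "correlation")
#> [1] -0.491

bundle$spatial
#>   axis   ks_stat            p n1 n2
#> 1    y 0.6952381 2.169672e-07 28 30
#> 2    x 0.2761905 1.736204e-01 28 30
```

Reading the output: the reference cost L < 0 says the two networks
found at the slowest timescale are genuinely anti-correlated, and their
projected activities have correlation −0.49. The Taylor slope near 1
(SD of ISI proportional to its mean) is the super-Poissonian signature
the Cox generator plants. Contingency entropy falls and κ rises toward
the slowest timescale as the partitions converge on the reference
networks, and the KS tests show the two networks separate along the
depth (y) axis but not the orthogonal (x) axis — the planted laminar
bias. `report(bundle)` renders the corresponding figure panels
(ordered correlation heatmap, metric and entropy curves, Taylor
scatter, projection traces, position maps).

A command-line front end with `simulate`, `analyze`,
`shuffle-control` and `report` subcommands is installed at
`inst/cli/acanet.R`.

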