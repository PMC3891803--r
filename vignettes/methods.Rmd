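---
title: "Fast-scale EEG functional networks: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-scale EEG functional networks: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegnets)
```

## The method

`eegnets` implements a fast-scale functional-network pipeline for
multichannel EEG recorded under two experimental conditions (by default
labelled `BM` and `SM`, for biological vs scrambled point-light motion,
the paradigm whose geometry the built-in simulator emulates):

1. **Preprocessing.** Signals are zero-phase bandpass filtered
   (0.5–50 Hz, 4th-order Butterworth run forward and backward) and
   epoched into 1.3 s trials; trials in which any channel exceeds an
   absolute amplitude threshold (default 100 µV) are rejected. A
   pre-analysis check (`spectrum_compare()`) verifies that the two
   conditions do not differ in power at any frequency bin in 0–50 Hz, so
   that network differences cannot be a trivial consequence of power
   differences.
2. **Sliding-window zero-lag Spearman correlation.** Within each trial a
   333 ms window, advanced in 43.3 ms steps (200 and 26 samples at
   600 Hz), yields a sequence of 20 × 20 rank-correlation matrices — the
   Spearman coefficient is the Pearson correlation of the midrank-
   transformed signals, computed between simultaneous samples only.
   `lag_correlation()` provides the supporting diagnostic: for EEG-like
   signals the rank correlation is maximal at lag zero and decays within
   tens of ms, which justifies the zero-lag restriction.
3. **Fixed-link binarization.** Each correlation matrix is reduced to a
   binary network by keeping exactly the K most correlated electrode
   pairs (`build_fixed_links()`). The alternative fixed-threshold rule
   (`build_threshold()`) is provided for contrast: because overall
   synchronization fluctuates strongly over time, thresholding produces
   networks whose link count varies from window to window, while the
   fixed-K rule removes that source of variability entirely
   (`criterion_stability()`).
4. **Graph measures.** Per node: degree \(k_i\); clustering coefficient
   \(C_i\), the realized fraction of the \(k_i(k_i-1)/2\) possible links
   among the node's neighbors; betweenness \(B_i\), the sum over node
   pairs of the fraction of their geodesics passing through the node
   (unnormalized). Globally: the average shortest path length \(L\) over
   connected pairs, and the means of \(C_i\) and \(B_i\).
   `er_baseline()` gives matched Erdős–Rényi reference distributions and
   the small-world ratio \((C/C_{ER})/(L/L_{ER})\).
5. **Statistics.** For every (electrode, metric, window, K) the
   trial-level values of the two conditions are compared with a
   two-sided Wilcoxon rank-sum test. A difference is reported only if it
   satisfies the dual criterion: `p < 0.05/20` (Bonferroni over the 20
   electrodes) **and** the Bonferroni pass recurs at 3 or more link
   densities of the analysis grid for the same electrode, metric and
   window.

## Numerical and design choices

Several details are deliberate choices where more than one convention is
defensible; they are fixed once and tested:

* **Window and step in samples.** 333 ms and 43.3 ms are converted by
  round-half-up to 200 and 26 samples at 600 Hz; 43.3 ms is not an
  integer number of samples, so the rounding rule is part of the
  contract. A 780-sample trial yields 23 windows starting at 0, 26, …,
  572 samples; windows never extend past the end of the epoch.
* **Degenerate windows.** A channel that is constant within a window has
  no rank variation; its pairs are recorded as missing, excluded from
  link ranking (they can never enter the top K), and the eligible pool
  shrinks accordingly.
* **Tie-breaking.** Ties at the K-th correlation value are broken by
  lexicographic electrode-pair order in montage order, making network
  construction deterministic across platforms. Ranking uses the signed
  correlation (the "most correlated" pairs); ranking by magnitude is
  available behind `absolute = TRUE`.
* **Disconnected pairs.** Sparse 20-node networks (K ≈ 20–30) can be
  disconnected. \(L\) is averaged over connected pairs only and the
  connected-pair fraction is always reported alongside, keeping \(L\)
  finite and interpretable.
* **Conventions for small degrees.** \(C_i = 0\) when \(k_i < 2\) (the
  node stays in the average), and \(B_i = 0\) for degree-1 nodes.
* **Betweenness pair ordering.** Unordered pairs, each counted once. The
  choice is pinned down testably by the conservation law
  \(\sum_i B_i = \sum_{j<k} (d_{jk} - 1)\) over connected pairs (each
  geodesic of length \(d\) has \(d-1\) interior nodes); the ordered-pair
  convention would double every value.
* **Rank test variant.** Trials are the unit of comparison, so the
  two-sample rank-sum (Mann–Whitney) test on trial-level metric values
  is the default; a paired signed-rank mode is available as a
  sensitivity analysis. For combined sample sizes up to 12 the p-value
  is computed by exhaustive enumeration of rank assignments with
  midranks (so two identical samples give exactly p = 1); larger samples
  use the tie-corrected normal approximation with continuity correction.
  The two agree within 0.05 for tie-free inputs at the crossover size.
* **Density grid.** The statistical grid defaults to
  {20, 30, 40, 50, 60, 70, 80}: seven densities spanning the 30/50/70
  operating points used for the global measures. It is configurable, as
  is the robustness count (default 3).
* **No further multiplicity correction.** Beyond the Bonferroni
  threshold and the multi-density rule, no correction is applied across
  windows or densities. This mirrors the published procedure; users
  should treat isolated single-window findings with corresponding
  caution.

## The synthetic generator

No public raw recordings exist for this paradigm, so the package ships a
generator (`generate_trials()`) that stands in for them and gives every
pipeline stage a controlled test surface. It emulates the study design —
20 channels in the 10–20 montage at 600 Hz, 1.3 s trials, 2 blocks × 2
conditions × 25 repetitions with randomized within-block order — and a
statistical structure with the features the pipeline actually consumes:

* **Spatially decaying correlation.** Channels are linear mixtures of
  Gaussian noise with covariance \(\exp(-d/\lambda)\) over scalp
  distance \(d\), plus independent sensor noise, bandpassed to
  0.5–50 Hz. Because the pipeline uses rank correlations, Gaussianity is
  innocuous: only the correlation ordering matters.
* **Long-range synchrony.** A single latent shared by a spatially
  distributed (midline + temporal) electrode set, controlled by
  `hub_strength`. Distance decay alone produces lattice-like networks
  whose path length is too long at low K and too short at high K; real
  EEG combines local (volume-conduction-like) correlation with
  long-range synchrony, and this term supplies the corresponding
  shortcuts.
* **Fluctuating global coupling** (optional): a common signal with
  sinusoidally modulated gain, reproducing the alternation between
  globally synchronized and desynchronized periods that makes
  threshold-mode networks unstable.
* **Condition effects** (optional): in one condition, listed electrodes
  are mixed with a shared latent, `x <- sqrt(1 - s^2) x + s s(t)`,
  raising their mutual zero-lag correlation while preserving variance.
  The default positive control couples F7 with distant electrodes so
  that F7 gains degree in that condition.

The defaults `lambda = 1.0`, `sensor_noise = 0.3`, `hub_strength = 2.6`
were calibrated once, by a coarse grid search on null trials, so that
fixed-link networks operate in the regime reported for task EEG:
time-averaged \(L \approx 2.25\) at K = 30 and \(\approx 1.85\) at
K = 70, with clustering well above and path length near the matched
random graph (small-world ratio ≈ 2.3 at K = 50). The effect-size
default (0.75) was likewise fixed so that the planted electrode is
detected reliably at realistic trial counts. These defaults were frozen
before the validation suite was finalized and are not tuned per run.

What the generator does **not** emulate: evoked (phase-locked)
responses, 1/f spectra and oscillatory peaks, non-stationarity across
trials, ocular/muscle artifacts beyond simple amplitude excursions, and
volume conduction as a physical forward model. Passing tests on
generated data therefore validate the pipeline's *mechanics and
statistical calibration*, not claims about any specific real dataset.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route:

* Graph measures are checked exactly against a matrix-power oracle
  (distances and geodesic counts from powers of the adjacency matrix)
  on **every** graph with up to 6 nodes (33,866 graphs) and on 500
  random 20-node graphs, plus literal DFS path enumeration on a
  subsample; the betweenness conservation law is asserted to 1e-9.
* The rank test is checked against the classical exact distribution on
  tie-free samples and holds its 5% level within a binomial band over
  1000 null replicates.
* The full dual criterion is run on 200 independent null simulations
  (8 trials per condition, 0.45 s epochs, densities {30, 50, 70}) — the
  family-wise robust-pass rate must stay at or below 5% — and on 10
  positive-control simulations (18 trials per condition, 12 windows)
  where the planted electrode must be recovered in more than 80% of
  runs. These sizes are scaled-down but honest versions of the default
  design, chosen to keep the suite fast while leaving the statistical
  conclusions unambiguous.
* The operating-point check (`scripts/acceptance.R`) regenerates 25
  default trials from scratch and recomputes the time-averaged \(L\) at
  30 and 70 links over all 575 windows.

## Known limitations

* The pipeline treats trials as exchangeable units; subject-level
  structure (repeated measures) is only addressed via the optional
  paired mode.
* Zero-lag rank correlation does not remove volume conduction; like any
  sensor-space connectivity measure, between-condition contrasts are
  interpretable, absolute topology less so.
* The fixed-K criterion guarantees equal link counts but not equal
  densities of *true* interactions; comparisons across very different
  overall synchronization levels still warrant care.
* EDF support covers the common uniform-rate EDF layout only.
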