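---
title: "Methods: histone-mark promoter patterns by functional PCA and mixture clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone-mark promoter patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterFPCA)
```

## The model

The package analyzes four histone marks — H3K4me2, H3K4me3, H3K9ac and
H4K20me1, always in this order — around transcription start sites.
Coverage is quantified in consecutive, non-overlapping 100 bp bins; the
100 bins of the 10 kb window centered at each TSS (internally the
1-based inclusive interval `[tss - 4999, tss + 5000]`, i.e. 50 bins
ending at the TSS and 50 following it) are extracted per mark and
concatenated into a 400-bin profile $y(t)$. Minus-strand windows are
reversed so that index 1 is always the most upstream bin; profiles are
therefore orientation-aware even though the underlying coverage is not.

Bins within a mark are spatially correlated, so a profile is treated as
a densely observed realization of a smooth process and decomposed by
the Karhunen–Loève expansion

$$Y(t) = \mu(t) + \sum_{j} C_j\, \psi_j(t),$$

with orthonormal eigenfunctions $\psi_j$ and uncorrelated zero-mean
scores $C_j$. Because the grid is dense and regular, $\mu$ and the
covariance are estimated cross-sectionally and the eigenfunctions come
from a plain eigendecomposition of the $400 \times 400$ sample
covariance — no covariance smoothing, no score shrinkage. Grid spacing
is taken as 1, so inner products are dot products and eigenvectors are
unit-norm.

Retaining the $q$ components that reach a target fraction of variance
explained (FVE), the score vector of each profile follows, under a
Gaussian-after-log assumption and $K$ latent pattern classes, the
mixture density

$$f(\mathbf{C}) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{q} f_j^{(k)}(C_j),$$

a Gaussian mixture with diagonal covariance. The diagonal form mirrors
the decorrelation of the scores and is deliberate; full covariances are
not offered. Each cluster's *characteristic pattern* is the elementwise
mean of its member profiles (reported on both the raw and the
$\log(1+y)$ scale).

Prediction then scans 10 kb windows, stepped one bin at a time, across
the genome: windows overlapping known promoter windows or with maximum
raw count not above the QC cutoff are skipped; the rest are correlated
(Pearson, log scale) with each active characteristic pattern; windows
strictly exceeding a cluster's threshold are merged (same cluster,
overlapping) into significance regions, and transitively overlapping
regions across clusters become putative promoters assigned to the
cluster with the largest correlation.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `bin_size` | 100 bp | resolution of the coverage quantification |
| `flank_bins` | 50 | half-window; 50 + 50 bins = 10 kb promoter window |
| `threshold` | 7 counts | max-intensity QC: training keeps max ≥ 7, the scan tests max > 7 (see below) |
| `fve_threshold` | 0.90 | cumulative FVE deciding $q$; `q_override` available because the right $q$ is data-specific |
| `K` | 4 | number of mixture components; `select_K()` reports BIC + heatmaps but never auto-commits |
| `alpha` | 0.4 | percentile level of within-cluster correlations setting the scan threshold; lower = more sensitive, higher = more confident |
| `n_restarts` | 10 | EM k-means warm starts; best log-likelihood wins |
| `tol`, `max_iter` | 1e-6, 500 | EM convergence (relative log-likelihood change) |
| `var_floor` | 1e-8 | lower bound on component variances, preventing degenerate spikes |
| `min_windows` | 1 (off) | optional "width" filter on regions whose peak rests on one or two windows |
| `shorten` | "none" | halve the first/last contributing window of long calls |

## Numerical and design choices

* **Coordinates.** 1-based inclusive everywhere internally; BED and
  bedGraph I/O converts from 0-based half-open at the boundary.
* **The two max-count rules differ on purpose.** Training drops
  profiles with max *less than* 7 (keeps max = 7); the scan only tests
  windows with max *strictly greater than* 7 (drops max = 7). The two
  rules are implemented exactly as stated even though they disagree at
  the boundary value; `filter_low_signal(mode =)` selects the rule.
* **Log scale.** The transform is $\log(1+y)$ because raw bins contain
  zeros. FPCA is fitted on log profiles, and scan correlations are
  computed on the same log scale the characteristic patterns are
  trained on — Pearson correlation is not invariant under the log map,
  so train and scan scales must agree.
* **Percentile convention.** The threshold is the lower empirical
  percentile (inverse ECDF, `quantile(type = 1)`): the smallest member
  correlation whose empirical CDF reaches $\alpha$. A data-valued
  threshold keeps "exceeds" unambiguous; exceeding is strict (`>`).
* **Determinism.** Eigenfunction signs are fixed (largest-magnitude
  element positive); EM restarts draw sub-seeds from the user seed;
  cluster numbering is canonicalized by descending mean total raw
  signal, so the flattest (inactive-promoter) cluster is always last
  and is excluded from the scan by default. Identical seeds give
  bit-identical models and predictions.
* **Ties and guards.** Equal best correlations in promoter assignment
  break to the lowest cluster index. Shortening that would invert an
  interval (single-window regions) returns the input unchanged with a
  warning. Windows extending past a chromosome end are skipped, not
  padded — padding would bias the max-count filter. A small tolerance
  (1e-9) is applied to the FVE cutoff so spectra landing exactly on the
  threshold are not lost to cumulative-sum rounding. In degenerate
  window coordinates, one worked consequence of the merging arithmetic:
  a chain of 100 bp-stepped 10 kb windows from start 9701 to start
  22301 merges to 9701–32300, and shortening both ends by half a window
  gives 14701–27300.

## The synthetic generator

`make_patterns()` encodes four log-scale mean shapes over the 400-bin
grid: a descending pre-TSS ramp, its post-TSS mirror, a symmetric
unimodal Gaussian peak at the TSS (sd 12 bins), and a flat baseline;
the H4K20me1 segment stays at baseline in all four, reflecting that
this mark does not distinguish the promoter classes. Defaults are
baseline 1.2 and amplitude 2.2 on the log scale, so active profiles
peak near 30 raw counts (well above the QC cutoff of 7) while the flat
cluster straddles the cutoff and exercises the filter.
`simulate_profiles()` adds iid $N(0, \sigma^2)$ noise on the log scale
(default $\sigma = 0.3$, moderate within-cluster variability) and
rounds $e^{x} - 1$ to non-negative integer counts.
`simulate_genome()` lays Poisson(1) background bins over a synthetic
chromosome and embeds full four-mark signatures (default noise
$\sigma = 0.1$, giving site correlations above 0.9 with their
generating pattern) at sites spaced at least 20 kb apart.

What the generator does *not* emulate, and hence what passing tests do
not show about real data:

* Noise is white across bins, whereas real ChIP-seq noise is spatially
  correlated. Consequently FPCA needs many components (about 75–80) to
  reach 90 % FVE on the synthetic profiles, where real promoter data
  concentrate variance in single-digit $q$. All invariants are
  dimension-agnostic, but the synthetic $q$ is not representative.
* Within-cluster variation is a single noise scale. Real promoter
  populations are far more heterogeneous, which widens the training
  correlation distributions that the $\alpha$ thresholds are cut from.
  A related small-sample property is worth knowing: members correlate
  with a pattern they helped average by roughly
  $1 + \sigma^2 / (n_k s^2)$ relative to held-out windows ($n_k$ =
  cluster size, $s^2$ = pattern variance). At realistic cluster sizes
  (hundreds) this bias is negligible; when training on only a handful
  of promoters per cluster the percentile threshold can sit above
  typical held-out correlations and the scan will be conservative.
  Training inputs should therefore be genome-scale promoter sets or
  the profile-matrix route, not toy TSS lists.
* No read-level artifacts (fragment-length smearing, GC bias, input
  controls), no replicate structure, no copy-number variation.

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
scale: 400 training profiles (100 per pattern), a 2 Mb synthetic
chromosome with 20 embedded signatures (19,901 scanned windows), EM
recovery checks at n = 1000, FPCA basis-recovery at n = 500. These
sizes keep each stage within seconds while leaving every estimator in
its intended regime.

## Limitations

* Dense-grid FPCA only; sparse or irregular designs (PACE-style
  conditional scoring) and derivative estimation are out of scope.
* The scan is single-strand: windows are compared in genomic
  orientation only, so a signature matching a pattern's mirror image is
  reported under the mirrored cluster rather than flipped.
* No FDR control or permutation p-values for windows; the percentile
  rule is the only calibration, as designed.
* Venn summaries against annotation sets are descriptive; no enrichment
  statistics versus a genomic background are computed.
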