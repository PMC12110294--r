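---
title: "Multiscale simplicial complex entropy: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale simplicial complex entropy: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msscae)
```

## The entropy

Given a scalar series $x(1), \dots, x(N)$, the package delay-embeds it into
the point cloud $PC_d = \{(x_j, x_{j+1}, \dots, x_{j+d-1})\}$ of
$P = N - d + 1$ consecutive-sample patterns, and builds the Vietoris–Rips
complex at tolerance $\epsilon$: any pair of points at Euclidean distance
$\le \epsilon$ is linked, and a $k$-simplex is a set of $k+1$ points that are
pairwise linked (a $(k{+}1)$-clique of the $\epsilon$-graph). With
$\rho_k$ the number of realized $k$-simplexes and
$\rho_k^m = \binom{P}{k+1}$ the maximum possible, the realized fractions are
$S_k = \rho_k / \rho_k^m$ and the simplicial complex approximate entropy is

$$\mathrm{SCAE}_k = -\log\!\left(\frac{S_{k+1}}{S_k}\right).$$

$\mathrm{SCAE}_0$ measures how unlikely a point is to form an edge with a
neighbor; $\mathrm{SCAE}_1$, how unlikely an edge is to close into a
triangle. Regular, clustered dynamics realize many higher simplexes and get
low entropy; irregular dynamics get high entropy. Unlike sample entropy,
the pattern length is fixed and it is the *simplex dimension* that is
incremented.

```{r fig1}
cen <- census_from_counts(P = 10, rho = c(10, 2))
tidy(cen)
scae(cen, k = 0)
scae(cen, k = 1)
```

**Logarithm base.** The defining formula is conventionally written with a
natural log, but the worked reference example above (10 points, 10 edges,
2 triangles giving $\approx 0.654$ and $\approx 1.123$) is only reproduced
by a base-10 logarithm ($-\ln$ would give 1.504 and 2.590). The package
therefore exposes `log_base` and defaults to 10 so the reference numbers
reproduce. All multiscale *shape* statements — monotone decay, flatness,
crossings, estimability limits — are base-invariant, since two bases differ
by a constant factor.

## The multiscale extension

The composite coarse-graining at scale $\tau$ forms the $\tau$ offset
subseries $y_r^\tau(j) = \frac{1}{\tau}\sum_{l=(j-1)\tau+r}^{j\tau+r-1} x(l)$,
$r = 1..\tau$, and the per-scale entropy is the mean of the per-subseries
values:

$$\langle \mathrm{SCAE}_k(\tau)\rangle =
  -\frac{1}{\tau}\sum_{r=1}^{\tau}
  \log\!\left(\frac{S_{k+1}^{\tau,r}}{S_k^{\tau,r}}\right).$$

Three design points deserve explanation:

* **Subseries length.** The printed window-count formulas one finds for
  composite coarse-graining disagree with each other for non-divisible $N$
  and offsets $r > 1$. We let $j$ run while $j\tau + r - 1 \le N$, i.e.
  subseries $r$ has $\lfloor (N - r + 1)/\tau \rfloor$ points. This uses
  every full window, and coincides with the usual formulas whenever
  $\tau \mid N$.
* **Tolerance is fixed at scale 1.** $\epsilon$ = `eps_factor` × the
  population SD of the *original* series, never recomputed per subseries.
  Coarse-graining averages away the variance of uncorrelated noise, so
  against a fixed yardstick its embedded cloud contracts, edges and
  triangles proliferate, and the entropy falls — which is precisely the
  diagnostic signal. Recomputing $\epsilon$ per scale would cancel the
  contraction and flatten white noise. The same convention is used for the
  SampEn tolerance in the MSE/MMSE baselines.
* **Undefinedness is strict.** If any subseries at a scale has
  $S_{k+1}^{\tau,r} = 0$ (or $S_k^{\tau,r} = 0$), the scale's mean is
  undefined: one $-\log 0$ poisons the composite sum. `strict = FALSE`
  averages over the defined subseries instead, for exploration only.
  `max_estimable_scale()` reports the largest $\tau$ with an unbroken
  defined run from scale 1 — the operational meaning of "the entropy can be
  estimated up to scale $\tau$" for a finite record.

Long records are split into two non-overlapping segments of
`segment_length` (default $10^4$) values when at least twice that long;
per-segment profiles (each with its own scale-1 SD) are pooled. This keeps
the census of a $2\times 10^4$-beat RR record tractable without changing
the entropy scale.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `d` | 2 | embedding dimension; patterns are consecutive pairs |
| `eps_factor` | 0.1 | VR tolerance as a fraction of the scale-1 population SD |
| `k` | 0 (and 1) | simplex dimension of the entropy |
| `log_base` | 10 | see above |
| `tau_max` | 20 | largest coarse-graining scale |
| `segment_length` | 10000 | long-record segmentation threshold/size |
| SampEn `m`, `r_factor` | 2, 0.15 | the de-facto standard of the multiscale-entropy literature |

The population SD (divisor $N$) is used throughout for tolerances; at the
record lengths involved the difference from the sample SD is negligible,
but fixing one convention keeps censuses exactly affine-invariant:
rescaling a series rescales distances and $\epsilon$ together, so the
census is unchanged (a property the test suite asserts).

## Baselines

`mse()` is the classical multiscale sample entropy: non-overlapping window
means (offset $r=1$ only), then SampEn with Chebyshev distance, self-matches
excluded, tolerance fixed from scale 1. `mmse()` replaces the coarse series
with a stride-1 moving average (length $N - \tau + 1$, so it barely shortens
with scale) and takes SampEn templates at lag $\tau$ on the smoothed series;
the lag-$\tau$ convention follows the modified-MSE literature and can be
switched to lag 1 (`template_lag = "one"`). Because the moving average
preserves length, MMSE remains defined at scales where MSE has run out of
data — at the price of strong serial dependence between overlapping
windows, so its large-scale values should be read cautiously.

## Synthetic signals

`gen_white()` draws i.i.d. standard Gaussians. `gen_one_over_f()` uses
frequency-domain synthesis: complex Gaussian coefficients with amplitude
$f^{-\beta/2}$ ($\beta = 1$ by default), zero DC, Hermitian symmetry,
inverse FFT, then standardization to zero mean and unit SD. This emulates
the long-range-correlated, scale-free character of healthy heart-rate
fluctuations; it does *not* emulate nonstationarity, multifractality, or
beat-detection artifacts of real RR records, so passing noise-based tests
shows the machinery distinguishes correlation structure, not that clinical
conclusions transfer. `shuffle_surrogate()` destroys all temporal
correlations while preserving the value multiset exactly, which is the
standard control for "is the multiscale structure due to temporal
ordering?".

Generators are pure functions of their seed and leave the caller's RNG
state untouched.

## Numerical and algorithmic choices

* The census kernel enumerates neighbor pairs through a uniform spatial
  grid of cell size $\epsilon$ (only $3^d$ adjacent cells can contain a
  neighbor) and counts triangles/4-cliques by merging sorted forward
  adjacency lists. Distance tests compare squared distances (no square
  root); ties at exactly $\epsilon$ are included (closed ball). Duplicate
  values — common in RR series — are distinct, always-linked vertices.
* An exhaustive $O(P^3)$ distance-matrix oracle, kept in the test suite,
  pins the kernel on random clouds up to $P = 200$.
* Undefined entropies are values (`NA` + a `defined` flag), not errors, so
  profiles can record "not estimable at this scale" and group comparisons
  can drop them with a count.
* Negative entropies ($S_{k+1} > S_k$, possible in dense complexes) are
  returned as computed, never clipped.
* A constant series has zero SD, so an SD-tied tolerance is undefined:
  single-series calls raise an error, profile code records the scale as
  undefined.

## Problem sizes

The validation experiments run at the sizes the analyses themselves use:
noise-crossing comparisons use 10 realizations of $2\times10^4$ samples
(segmented per the long-record protocol) over scales 1–5, and the
length-dependence studies use 10 realizations of 512–2048 samples over
scales 1–20. On one CPU the full test suite runs in about a minute and the
acceptance script in under half a minute.

## Known limitations

* The maximum estimable scale of a stochastic signal is sensitive to the
  fine structure of the noise generator and to tolerance conventions;
  different 1/f synthesis methods shift it by several scales in either
  direction. Comparisons of estimability limits across implementations
  should fix the generator, not just $\beta$.
* Only unit-lag embeddings are supported, and the entropy is implemented
  for $k \le 2$ (censuses up to 4-cliques); higher dimensions would need a
  general clique counter.
* Mann–Whitney p-values are reported raw per scale, matching the
  convention of plotting them against a single 0.05 line; apply your own
  multiplicity correction if you need family-wise control across scales.
* Artifact and ectopy filtering of real RR records is out of scope: the
  reader expects already-clean interval lists.
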