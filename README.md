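# msscae

Multiscale simplicial complex approximate entropy for one-dimensional time
series, built for heart-rate-variability (RR-interval) analysis but
applicable to any scalar signal.

## The problem and the method

Entropy-based complexity measures ask how unpredictable a physiological
signal is; multiscale versions ask how that unpredictability survives
progressive smoothing, which is what separates the long-range-correlated
fluctuations of a healthy heartbeat from pathologies such as congestive
heart failure or atrial fibrillation. This package quantifies irregularity
topologically. A series *x*(1), …, *x*(N) is delay-embedded into the point
cloud of consecutive *d*-tuples, a Vietoris–Rips complex is built by
linking every pair of points within a tolerance ε (a fixed fraction of the
series' standard deviation), and the simplexes of each dimension *k* are
counted: ρ_k realized out of ρ_k^m = C(P, k+1) possible, giving fractions
S_k = ρ_k / ρ_k^m. The simplicial complex approximate entropy is

    SCAE_k = −log( S_{k+1} / S_k )

— the (log-)improbability that structures of dimension *k* close into
structures of dimension *k*+1. The multiscale profile ⟨SCAE_k(τ)⟩ applies
this to composite coarse-grainings of the series: at scale τ, the τ offset
subseries of τ-sample window means are each embedded and counted (with ε
still tied to the scale-1 SD), and their entropies averaged. Uncorrelated
noise loses variance under coarse-graining, its cloud contracts against the
fixed ε, and its entropy falls steeply; 1/f-correlated signals stay nearly
flat.

The package also provides the classical SampEn-based baselines (MSE with
non-overlapping windows, MMSE with moving averages), seeded generators for
white and 1/f noise, shuffled surrogates, a plain-text RR reader, and
per-scale Mann–Whitney cohort comparisons — everything needed to run the
method's validation experiments end to end.

## Worked example

The reference complex: 10 embedded points, 10 edges, 2 triangles.

```r
library(msscae)
cen <- census_from_counts(P = 10, rho = c(10, 2))
tidy(cen)
#>       k   rho rho_max      S
#> 1     0    10      10 1
#> 2     1    10      45 0.222
#> 3     2     2     120 0.0167
scae(cen, k = 0)
#> <scae_entropy> SCAE_0 = 0.653213 (log base 10)
scae(cen, k = 1)
#> <scae_entropy> SCAE_1 = 1.12494 (log base 10)
```

SCAE_0 = −log10(10/45) ≈ 0.653: the chance that a point forms an edge is
about 10^−0.65 ≈ 22%. SCAE_1 ≈ 1.125: edges close into triangles about
13 times less often than chance edges form.

Multiscale profiles separate correlated from uncorrelated noise:

```r
f <- gen_one_over_f(4096, seed = 11)   # 1/f "pink" noise
w <- gen_white(4096, seed = 11)
pf <- ms_scae(f, k = 0:1, tau_max = 10)
pw <- ms_scae(w, k = 0:1, tau_max = 10)
#    scale `1/f` white        (k = 0 columns)
#        1  2.37  2.60
#        2  2.34  2.31
#        3  2.32  2.13
#        5  2.29  1.90
#       10  2.26  1.60
max_estimable_scale(pf)
#>  0  1
#> 10 10
autoplot(pf)                           # ggplot of the profile
```

White noise starts higher (more irregular) but falls below the 1/f profile
already at scale 2 and keeps dropping; the correlated signal is nearly
flat — its complexity is genuinely multiscale. `mse()` / `mmse()` produce
the SampEn baselines in the same `scale_profile` shape, and
`compare_groups()` turns lists of per-subject profiles into a per-scale
Mann–Whitney U / p table.

A thin command-line front end ships in `inst/cli/msscae`
(subcommands `scae`, `msscae`, `mse`, `mmse`, `simulate`, `surrogate`,
`compare`); every run writes a manifest JSON sufficient to reproduce it.

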