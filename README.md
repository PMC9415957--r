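# ndentropy

Complexity analysis of univariate physiological time series (EEG, heart-rate
variability) from the geometry of their Poincaré plot.

## The problem and the measure

The Poincaré plot of a series *s₁ … s_N* is the scatter of each sample against
its successor. After subtracting the series minimum (so all points lie in the
first quadrant), the plane is divided into *W* equal-width sector rings —
annuli between concentric circles about the origin, the outermost through the
farthest point at distance *L_max*. Counting points per ring gives occupancy
probabilities *p_k = Snum_k / (N − 1)*.

**Distribution entropy (DE)** is the Shannon entropy of that occupancy,

> E_D = −Σ_k p_k log p_k ,

and sees only the histogram: two scatters whose mass sits in rings near the
origin versus far from it can score identically. For signals like EEG, whose
states differ in amplitude more than in waveform, that is a real loss of
discrimination.

**Nonextensive distribution entropy (NDE)** fixes this by giving each ring a
Tsallis nonextensive parameter derived from the reverse-subtracted distance of
its center to the origin,

> q_k = 1 + L_max − (k − 1)·dl − dl/2 ,  dl = L_max / W,

so the innermost ring gets the largest q (smallest weight) and the outermost
the smallest (q_W = 1 + dl/2). The ring contributions are combined in
nonextensive-entropy form,

> S_neq = Σ_k (p_k − p_k^{q_k}) / (q_k − 1) ,

which reduces to Shannon entropy as all q_k → 1 and is sensitive to both the
occupancy histogram and its radial placement, i.e. to signal amplitude.

The package also ships the validation apparatus around the measure: an
exact-covariance fractional Brownian motion (fBm) simulator (circulant
embedding / Davies–Harte), sliding-window analysis with Hurst-index and
ring-count sweeps, and a sleep-EEG pipeline — singular-spectrum detrending,
zero-phase 1–32 Hz band-pass, per-epoch NDE scoring, Jonckheere–Terpstra
ordered-trend testing with Bonferroni-adjusted pairwise comparisons — runnable
end to end on a built-in synthetic stage-labelled EEG generator.

## Worked example

Two ring partitions with the same occupancy set {1/15, 2/15, 1/5, 4/15, 1/3}
over 5 rings with outer radius 10 — once ordered inner → outer, once reversed:

```r
library(ndentropy)

p <- c(1/15, 2/15, 1/5, 4/15, 1/3)
dl <- 10 / 5
pts_fwd <- cbind(rep((1:5 - 0.5) * dl, round(15 * p)), 0)      # mass outward
pts_rev <- cbind(rep((1:5 - 0.5) * dl, round(15 * rev(p))), 0) # mass inward
pts_fwd[15, 1] <- 10; pts_rev[15, 1] <- 10                     # pin L_max

part_fwd <- ring_partition(pts_fwd, 5)
part_rev <- ring_partition(pts_rev, 5)
q <- nonextensive_params(part_fwd)
q
#> [1] 10  8  6  4  2
distribution_entropy(part_fwd); distribution_entropy(part_rev)
#> [1] 1.48975
#> [1] 1.48975
nne(part_fwd$p, q); nne(part_rev$p, q)
#> [1] 0.3758677
#> [1] 0.2216753
```

DE cannot tell the two distributions apart (1.48975 nats for both); NDE gives
the mass-outward arrangement a markedly higher score (0.376 vs 0.222),
because high-amplitude rings carry smaller nonextensive parameters and hence
more weight.

On fractional Brownian motion the mean sliding-window NDE decreases
monotonically with the Hurst index (and so does its replicate spread):

```r
sweep <- hurst_sweep(seq(0.1, 0.9, 0.1), n = 2500, width = 2500,
                     step = 500, rings = 50, replicates = 10, seed = 1)
cor(sweep$H, sweep$mean, method = "spearman")
#> [1] -1
round(range(sweep$mean), 4)
#> [1] 0.0057 0.2257
```

A full synthetic sleep run (30 epochs each of AWAKE, REM, stage 2, 3, 4):

```r
rec <- synth_sleep_record(rep(c(0L, 5L, 2L, 3L, 4L), each = 30), seed = 1)
res <- sleep_analysis(rec, rings = 50)
round(vapply(res$groups, mean, numeric(1)), 4)
#>  AWAKE    REM stage2 stage3 stage4
#> 0.0347 0.0288 0.0168 0.0109 0.0094
res$trend
#> Jonckheere-Terpstra test (normal approximation, tie-corrected)
#> data:  AWAKE, REM, stage2, stage3, stage4
#> JT = 193, mean = 4500, variance = 90750, p-value < 2.2e-16
#> alternative hypothesis: two.sided
```

The per-epoch NDE falls monotonically from wakefulness through deep sleep,
and the ordered-trend test is decisive. `res$pairwise` holds the
Bonferroni-adjusted pairwise comparison table.

A thin command-line wrapper over the same functions is installed as
`exec/pnde`, with subcommands `nde`, `de`, `fbm`, `sweep`, `sleep`,
`selftest`.

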