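---
title: "Poincaré plot nonextensive distribution entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poincaré plot nonextensive distribution entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndentropy)
```

## The measure

Given a univariate series $s_1 \dots s_N$, the analysis proceeds in five
steps, each exposed as its own function:

1. **Positive shift** (`to_positive_series`): $x_i = s_i - \min_j s_j$, so all
   Poincaré points lie in the first quadrant. The subtracted minimum is
   retained; the measure is therefore exactly invariant to adding a constant
   to the input.
2. **Poincaré plot** (`poincare_points`): points $(x_i, x_{i+\tau})$ for
   $i = 1 \dots N - \tau$. The delay $\tau$ defaults to 1, the standard form
   that displays the correlation of adjacent samples.
3. **Sector-ring partition** (`ring_partition`): $W$ concentric circles about
   the origin, the outermost through the farthest point at distance
   $L_{\max}$, cut the quadrant into equal-width annuli of width
   $dl = L_{\max}/W$. Ring occupancy gives probabilities
   $p_k = \mathrm{Snum}_k/(N - \tau)$.
4. **Nonextensive parameter set** (`nonextensive_params`): each ring receives
   $q_k = 1 + L_{\max} - (k-1)\,dl - dl/2$, i.e. one plus the
   reverse-subtracted distance of its center to the origin. Reverse
   subtraction matters because in the nonextensive entropy a *larger* $q$
   means a *smaller* contribution: distal, high-amplitude rings must carry the
   small parameters. All $q_k > 1$ (the minimum is $1 + dl/2$ on the outermost
   ring), and the values are in the input's native amplitude units.
5. **Entropy** (`nne`): $S = \sum_k (p_k - p_k^{q_k})/(q_k - 1)$.

Classical distribution entropy (`distribution_entropy`,
$E_D = -\sum_k p_k \ln p_k$) uses only step 3 and is blind to *which* rings
are occupied; the nonextensive variant weights rings by radial position and
is therefore amplitude-sensitive. The package's tests verify both directions:
DE is exactly scale-invariant while NDE is not, and permuting a non-uniform
occupancy across rings leaves DE unchanged while changing NDE.

### Sign convention

The nonextensive combination is sometimes written with a leading minus as
$-\sum_k (p_k^{q_k} - p_k)/(1 - q_k)$, which is the same expression negated
and is non-positive for $q_k > 1$. We use the positive form above: it is
non-negative, vanishes exactly when one ring holds all mass, and its
$q_k \to 1$ limit is the (positive) Shannon entropy, which is the property
that anchors the whole construction. The limit is taken seriously in code:
any $q_k$ within $10^{-8}$ of 1 is evaluated by $-p_k \ln p_k$ to avoid the
0/0 form, and a dedicated test drives all $q_k = 1 + 10^{-6}$ and checks
agreement with Shannon entropy to $10^{-4}$ relative.

### Numerical conventions

* **Logarithm base**: natural log throughout, so DE and the $q \to 1$ limit
  of the nonextensive form coincide exactly; entropies are in nats.
* **Radial distance**: Euclidean norm of the coordinate pair — concentric
  circles about the origin imply the L2 norm.
* **Ring boundaries**: ring $k$ is the half-open annulus
  $[L_{k-1}, L_k)$ with $L_0 = 0$; the outer ring is closed at $L_{\max}$ so
  the farthest point is always counted. A point at the origin lands in
  ring 1. Binning is `min(floor(d/dl) + 1, W)`, and a brute-force per-point
  linear scan serves as the oracle in the tests.
* **Empty and full rings**: $p_k = 0$ and $p_k = 1$ terms contribute exactly
  0 ($0^q := 0$ for $q > 1$).
* **Degenerate input**: a constant series puts every point at the origin,
  $L_{\max} = 0$; the partition is flagged degenerate and the entropy defined
  as 0 (one ring holds all mass, and that term vanishes in both DE and the
  nonextensive form).
* **Units**: $q_k$ is computed in the input's native amplitude units, with no
  normalization; an optional `rescale` flag in `poincare_nde` divides the
  positive series by its maximum first, but is off by default because the
  amplitude dependence is the point of the measure.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| rings $W$ | 50 | — | On persistent fBm the measure rises with $W$ up to roughly 40 rings and then plateaus; 50 buys stability at modest cost. DE has historically been used with $W = 40$; both are plain arguments. |
| delay $\tau$ | 1 | samples | Standard Poincaré form; exposed for lagged variants. |
| window width | 2500 | samples | For fBm-scale series the windowed mean stabilizes for widths above ~2500; the sweep utilities accept any width. |
| window step | 500 | samples | Overlapping windows; trailing samples that do not fill a window are dropped (partial windows would mix estimators of different variance). |
| epoch window / step | 1000 / 10 | samples | Within 30 s sleep epochs at 100 Hz: 201 windows per epoch, a dense summary of a short segment. |
| replicates | 20 | — | Sweep averaging; replicate $r$ of grid point $i$ uses seed $\texttt{seed} + 1000 i + r$ so runs are exactly reproducible. |

Per-window analysis is fully local: $L_{\max}$, the ring width and the
parameter set are recomputed within each window, never globally, so windows
are comparable across nonstationary records.

## The fractional Brownian motion simulator

The validation experiments need fBm with a prescribed Hurst index $H$: a
centered Gaussian process with covariance
$E[B_t B_s] = \tfrac12 (t^{2H} + s^{2H} - |t-s|^{2H})$. Rather than a
wavelet-synthesis approximation, `generate_fbm` samples the increment process
(fractional Gaussian noise, autocovariance
$\gamma(k) = \tfrac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$) exactly by
circulant embedding (Davies–Harte), falling back to a Cholesky factorization
of the Toeplitz covariance if the embedding eigenvalues ever go negative
(they do not for $H \in (0,1)$ at the sizes used, but the guard is cheap).
Paths start at exactly 0, $\mathrm{Var}(B_t) = t^{2H}$ with $t$ in samples,
and $H = 1$ returns the analytic degenerate path $t \cdot Z$. All downstream
claims are distributional (the trend of NDE against $H$), so path-level
agreement with any particular approximate generator is neither promised nor
needed.

The verification suite checks the increment autocovariance against
$\gamma(k)$ at $H \in \{0.2, 0.5, 0.8\}$ (200 replicates of $n = 4096$) and
the variance-growth exponent $2H$ to $\pm 0.05$. The exponent is estimated by
pooling $(B_{s+t} - B_s)^2$ over all $s$ within each path — legitimate
because fGn is stationary — and regressing $\log \widehat{\mathrm{Var}}(B_t)$
on $\log t$ over $t = 4 \dots 1024$; pooling makes the estimator's spread a
few times smaller than the acceptance band, where single-time-point variance
estimates at 200 replicates would not resolve it.

The Hurst-sweep study runs at a reduced scale chosen to keep the full
verification suite fast while leaving the qualitative contract decisive:
paths of $n = 2500$ (one full-width window each), 10 replicates per Hurst
index over $H = 0.1 \dots 0.9$. At that size the monotone decrease of mean
NDE in $H$ is exact (Spearman $\rho = -1$) and the replicate standard
deviation at $H = 0.9$ is an order of magnitude below that at $H = 0.1$.

## The sleep pipeline

`sleep_analysis` chains four stages:

1. **Detrending** (`svd_detrend`): singular-spectrum analysis with embedding
   window 200 samples (2 s at 100 Hz) and trend rank 1 by default. The Gram
   matrix of the Hankel trajectory matrix is built by a sliding-product
   recursion and eigen-decomposed; the rank-$r$ reconstruction (diagonal
   averaging, computed with FFT convolutions padded to smooth lengths) is
   subtracted. A pure ramp is removed to machine precision with rank 2, and
   on ramp-plus-noise the residual variance matches the noise variance within
   20%. Embedding dimension and rank are unstated in most EEG applications;
   both are arguments.
2. **Band-pass** (`bandpass_1_32`): zero-phase 1–32 Hz. The default is a
   4th-order Butterworth run forward-backward; `method = "fft"` zeroes
   Fourier components outside the band — an ideal band-limiter, which is
   precisely what a harmonic-wavelet (boxcar-in-frequency) filter computes.
   The contract is spectral and tested as such: a 10 Hz tone passes with gain
   within ±5% and zero phase shift; DC, 0.2 Hz drift and 45 Hz are attenuated
   by at least 20 dB.
3. **Epoch scoring** (`score_epochs`): 30 s epochs, each scored by the mean
   NDE of its 201 sliding windows (width 1000, step 10), with $W = 50$ rings.
   The ring count for this stage is genuinely open — the fBm study recommends
   50 while older DE work used 40 — so 50 is the default and the argument is
   exposed.
4. **Trend testing** (`jonckheere_terpstra`, `pairwise_posthoc`): epochs are
   grouped by hypnogram stage. NREM-1 is excluded by default (few epochs in
   typical recordings make its group unstable; `include_n1` re-admits it),
   as are movement (6) and unscored (9) codes. The group order for the
   ordered alternative defaults to AWAKE, REM, stage 2, stage 3, stage 4 —
   decreasing expected complexity — and is configurable. The JT statistic
   sums pairwise Mann–Whitney counts with the half-tie convention;
   significance uses the normal approximation with tie-corrected variance,
   and the pairwise table reports the two-group statistic, its null standard
   error, the standardized statistic, and raw and Bonferroni-adjusted
   significance (adjusted $p = \min(1, p \times \#\text{comparisons})$; 10
   comparisons for 5 groups). A brute-force triple-loop enumeration is the
   oracle in the tests, including tied data.

### What the synthetic generator emulates — and what it does not

`synth_sleep_record` produces per-epoch Gaussian noise with a $1/f^\beta$
spectrum shaped *inside 0.5–35 Hz* and stage-dependent parameters: deeper
NREM stages get a steeper slope and a larger in-band RMS amplitude
(AWAKE $\beta = 0.8$, 10 units; N1 1.2, 15; stage 2 1.6, 25; stage 3 2.0, 45;
stage 4 2.2, 60; REM 1.0, 12). Band-limiting the shaping is deliberate:
scalp-EEG stage amplitudes are conventionally described on the classical
0.5–35 Hz rhythms, and a generator that put the extra deep-sleep power below
1 Hz would see it removed by the very 1–32 Hz filter the pipeline applies,
erasing the amplitude contrast that real slow-wave sleep keeps in band. Since
NDE decreases with in-band amplitude (larger $L_{\max}$ means uniformly
larger $q_k$), the designed NDE ordering is
AWAKE > REM > stage 2 > stage 3 > stage 4.

The generator emulates exactly the two features the measure responds to —
stage-dependent spectral slope and in-band amplitude — and nothing else. It
does **not** emulate sleep spindles, K-complexes, vertex waves, artifacts,
inter-epoch continuity (epochs are independent draws), stage-transition
dynamics, or inter-subject variability. A passing end-to-end test therefore
shows that the pipeline recovers a designed amplitude/slope ordering through
the full preprocessing chain with a decisive trend statistic; it does not
show that the measure separates stages on any particular real recording,
which additionally depends on electrode placement, artifact handling and the
subject.

The end-to-end verification runs 30 epochs per stage (150 epochs, 450,000
samples at 100 Hz), a size at which the whole pipeline completes in seconds
and the designed ordering is recovered with a two-sided trend $p$ far below
the 0.01 requirement.

## Known limitations

* The nonextensive parameters are amplitude-scale-dependent by design, so NDE
  values are comparable only between series in the same units; the `rescale`
  flag trades this sensitivity away when cross-unit comparison is needed.
* A single large-amplitude pulse inflates $L_{\max}$, compresses every other
  point into inner rings and suppresses their contribution; the measure
  inherits this sensitivity to outliers, which is why detrending and
  band-passing precede scoring in the sleep pipeline.
* The JT significance is asymptotic; for very small groups an exact
  permutation approach would be preferable, and is not implemented.
* Multiscale variants and ellipse-based Poincaré descriptors (SD1/SD2, CCM)
  are out of scope.
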