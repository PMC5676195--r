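---
title: "Frequency-domain Granger causality: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain Granger causality: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specgc)
```

## The problem

Multichannel recordings of oscillatory systems — cortical field potentials,
cardiovascular variability series, coupled physiological rhythms — raise the
question of *directed* interaction: how much of what happens in channel 2 at
10 Hz is driven by channel 1? Granger's answer is predictive: channel 1
"causes" channel 2 if the past of channel 1 improves the prediction of
channel 2 beyond what channel 2's own past (and the past of any conditioning
channels) already achieves. For linear vector autoregressive (VAR) processes
this notion has an exact frequency-domain formulation, and this package
implements the three families of measures built on it, together with the
simulation machinery needed to study how reliably they can be estimated.

## Model

All measures start from a stable VAR(p) on $M$ channels,

$$x(t) = \sum_{k=1}^{p} A_k\, x(t-k) + e(t), \qquad e(t) \sim N(0, \Sigma),$$

sampled at $f_s$ Hz. Stability means the companion matrix of
$(A_1, \dots, A_p)$ has spectral radius below 1. In the frequency domain the
model is summarized by the coefficient transform
$\bar A(f) = I - \sum_k A_k e^{-i 2\pi f k / f_s}$, the transfer function
$H(f) = \bar A(f)^{-1}$, and the cross-spectral density
$S(f) = H(f)\, \Sigma\, H(f)^H$ (`var_spectral_matrices()`). Spectra are kept
in per-sample units (no $1/f_s$ factor): every measure in the package is a
scale-invariant ratio, so the convention only affects raw PSD values.

## The three measure families

**Granger–Geweke causality (GGC).** For two channels, the spectral measure
from source $s$ to target $t$ is
$$f_{s \to t}(f) = \ln \frac{S_{tt}(f)}{S_{tt}(f) - \tilde\sigma^2_{ss}\,|\tilde H_{ts}(f)|^2},$$
where $\tilde\sigma^2_{ss} = \Sigma_{ss} - \Sigma_{ts}^2/\Sigma_{tt}$ and
$\tilde H$ absorbs the Cholesky normalization that decorrelates the
innovations (the identity when $\Sigma$ is diagonal, as in all shipped
benchmarks). The conditional version filters the (target, conditioning)
channels of the full model's spectral factor through the inverse transfer of
the *reduced* model fitted without the source, and applies the same ratio to
the filtered factor. Its frequency average equals the time-domain
log-variance-ratio measure $F = \ln(\Sigma^{R}_{tt}/\Sigma_{tt})$ for these
systems; `spectrum_time_average()` verifies this numerically at 2049 grid
points with a trapezoidal rule.

**The reduced-model problem and the state-space solution.** The classical
estimator fits the full and reduced models separately by least squares. But
the subprocess of a VAR obtained by deleting a channel is VARMA, not a
finite-order VAR, so the reduced fit is misspecified at the true order
(bias) and noisy at generous orders (variance). The package's closed-form
route avoids the truncation entirely: the fitted (or true) VAR is put in
innovations state-space form
$s(t+1) = A s(t) + K e(t)$, $x(t) = C s(t) + e(t)$ via the companion
construction (`var_to_ss()`), and the exact innovations representation of
any channel subset is recovered by solving a discrete algebraic Riccati
equation (DARE) for the kept observables (`subprocess_innovations()`). The
conditional spectrum then follows in closed form
(`ss_conditional_spectral_gc()`), with no second model fit.

**Directed coherence and its relatives.** The squared directed coherence
$$|\gamma_{ij}(f)|^2 = \frac{\sigma_j^2 |H_{ij}(f)|^2}{\sum_m \sigma_m^2 |H_{im}(f)|^2}$$
is the fraction of channel $i$'s power at $f$ arriving from channel $j$;
rows sum to one. The partial directed coherence
$|\pi_{ij}(f)|^2 = |\bar A_{ij}(f)|^2 / \sum_m |\bar A_{mj}(f)|^2$ captures
*direct* influence only (columns sum to one). For bivariate diagonal-noise
models the exact identity $f_{1\to 2}(f) = -\ln(1 - |\gamma_{21}(f)|^2)$
ties the two families together, and the package tests it on fuzzed random
stable models. Finally, `spectral_decomposition()` splits the receiver's
PSD as $S_{t|j}(f) = S_{tt}(f)\,|\gamma_{tj}(f)|^2$ — the squared-magnitude
form is the only one for which the parts sum to the total, which is why the
decomposition is defined with it. The decomposition is the interpretive
complement to GGC/DC: those profiles are deliberately invariant to the
receiver's own dynamics, while $S_{t|j}$ re-introduces them to show where
the transmitted power actually lands.

## Benchmark systems

Two simulated systems, with defaults version-pinned in
`inst/extdata/benchmark_defaults.yaml`:

* **Three-node chain** (`make_three_node_benchmark()`): AR(2) oscillators at
  40, 10 and 50 Hz (pole radius 0.9, $f_s = 120$ Hz, unit diagonal
  $\Sigma$), with couplings only along 1 → 2 (lag 2) and 2 → 3 (lag 3),
  coefficient 0.35. The direction 3 → 1 has no direct or indirect path, so
  its true conditional GC is identically zero — the acid test for
  estimators.
* **Two-node transmitter/receiver** (`make_two_node_benchmark()`):
  transmitter at 50 Hz, receiver at 10, 30 or 50 Hz, coupling 1 → 2 at
  lag 1, coefficient 0.35. The coupling and transmitter are identical
  across receiver configurations, making the DC and GGC profiles 1 → 2
  provably invariant while the receiver's PSD and partial spectrum change.

Design choices worth recording:

* **Coupling lags 2 and 3 in the chain.** With AR(2) diagonal blocks, a
  lag-1-only coupling would make the generative order 2; placing the two
  couplings at lags 2 and 3 makes the order genuinely 3, so that "fit at
  the true order p = 3" and order selection by BIC are meaningful. The
  coefficient 0.35 is comfortably inside the stability region (the chain is
  triangular, so the poles are those of the three oscillators regardless of
  coupling strength) and produces GC peaks of order 1–3, clearly visible
  against estimation noise.
* **$f_s = 120$ Hz** accommodates the 50 Hz resonance below Nyquist.
* **500 samples per realization, 100 realizations** (50 in the scaled-down
  test study): 500 samples is a realistic epoch length for stationary
  physiological segments and short enough that the bias/variance contrast
  between estimators is visible; the contrast only grows at smaller n.
* **Pole radius 0.9** gives sharp but not near-singular resonances
  (spectral dynamic range ~10^2–10^3).

## The Monte Carlo study

`run_monte_carlo_study()` simulates realization $i$ with seed
`master_seed + i` (Gaussian innovations through R's default Mersenne
Twister; one `set.seed()` per realization), so the entire study — including
percentile bands — is reproducible from one integer. Per estimator and
direction it reports per-frequency medians with 5th–95th percentile bands,
and `study_metrics()` condenses them into:

* `realization_iae_median` — median over realizations of each single
  realization's integrated absolute error against the truth. This is the
  primary reliability statistic.
* `median_curve_iae` — integrated deviation of the median *curve*. Caveat:
  clamping nonnegative estimates at zero pins the median of a noisy
  near-zero estimator to exactly zero at most frequencies, so this
  statistic can flatter a high-variance estimator on null directions; it is
  reported for completeness and used where bias (not noise) dominates.
* `band_width` — mean 5th–95th percentile width (variability).

Under the defaults, the state-space estimator at the true order dominates
the classical route: narrower bands than var(20) on every direction and an
order-of-magnitude smaller typical error on the uncoupled direction, while
var(3) shows the strong bias on coupled directions that motivates avoiding
separately fitted reduced models.

## Numerical choices

* **DARE solver**: structured doubling iteration (quadratically
  convergent; `I + G H` is provably invertible for the PSD iterates, so no
  fallback path is required), relative increment tolerance $10^{-13}$,
  iteration cap 200, and a verified residual below $10^{-9}$ (in practice
  $\sim 10^{-14}$) — otherwise an error reports the residual norm.
* **Transfer functions** are always obtained by linear solves, never by
  explicit inversion; a singular coefficient transform reports the
  offending frequency.
* **Clamping**: log-ratio arguments below 1 (possible for noisy estimates)
  are clamped to 1, i.e. GC 0; clamp events are counted on the returned
  object and in CLI manifests, and a warning fires when a clamp exceeds
  numerical slack ($10^{-8}$).
* **Correlated innovations** are handled by lower-Cholesky partialization
  with the source block ordered last, which makes the source's causal
  contribution orthogonal to everything retained. With correlated noise
  the measures depend on this ordering (a documented property of the
  Geweke normalization); the shipped benchmarks use diagonal noise, where
  ordering is immaterial. Diagonal-form DC warns when cross-correlations
  exceed 0.01 and offers the Cholesky-orthogonalized variant.
* **Frequency grid**: 513 equally spaced points on $[0, f_s/2]$ by
  default; integral identities use 2049 points with trapezoidal averaging.
* **Residual covariance divisor** $(T - p) - Mp$ (unbiased-flavor), no
  intercept (benchmarks are zero-mean; `demean = TRUE` subtracts column
  means). Order selection minimizes AIC/BIC of the ML residual covariance
  with ties broken toward the smaller order.
* **High-order projection route**: `theoretical_conditional_gc(route =
  "projection")` fits the reduced model at order 128 by Yule–Walker on the
  exact subprocess autocovariances (themselves from a doubling solution of
  the companion Lyapunov equation). It agrees with the closed form to
  $\sim 10^{-13}$ on the benchmarks and exists precisely to cross-validate
  the Riccati route.

## What the generator does and does not emulate

The synthetic processes are exactly the model class the measures are
defined on: linear, stationary, Gaussian, fully observed VAR. Passing tests
therefore demonstrate correctness of the measures and estimators *within
that class*, and the estimator comparison shows the purely statistical
bias/variance behavior uncontaminated by model mismatch. Real recordings
violate the class in known ways — nonlinearity, nonstationarity, unobserved
common drivers, measurement noise, volume conduction — and none of those
failure modes are exercised here; conclusions about estimator rankings
transfer to real data only insofar as a VAR is an adequate local
description.

## Known limitations

* The original coefficient-based PDC implemented here is *not* invariant to
  rescaling an individual channel (only to a common rescaling, and to
  changes of the innovation variances, on which it does not depend at
  all). The variance-weighted generalized PDC, which restores single-channel
  scale invariance, is deliberately out of scope.
* Time-domain and spectral GC estimates are reported without asymptotic
  significance thresholds; the permutation-null test in the suite shows one
  workable resampling approach.
* Only the VAR-fit-then-state-space estimation route is provided; direct
  subspace identification of state-space models from data is out of scope,
  as are regularized fits, missing data, and time-varying models.
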