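# specgc — frequency-domain Granger causality for VAR processes

`specgc` computes directed frequency-domain influence measures for linear
vector autoregressive (VAR) processes, for researchers analyzing oscillatory
multichannel recordings (neural, cardiovascular, or any coupled dynamical
system) and for methodologists studying how reliably those measures can be
estimated.

Three measure families are implemented on a common frequency grid:

* **Granger–Geweke causality (GGC)** — bivariate, conditional, and
  time-domain. For a stable VAR
  `x(t) = Σₖ Aₖ x(t−k) + e(t)`, `e ~ N(0, Σ)`, with transfer function
  `H(f) = (I − Σₖ Aₖ e^{−i2πfk/fs})⁻¹` and spectrum `S(f) = H Σ Hᴴ`, the
  bivariate spectrum from source *s* to target *t* is
  `f_{s→t}(f) = ln [ S_tt(f) / (S_tt(f) − σ̃²_ss |H̃_ts(f)|²) ]`,
  with `σ̃²_ss` the partialized source innovation variance. Two estimators
  are provided for the conditional measure: the classical route (separate
  full and reduced VAR fits) and the **state-space closed form**, which
  derives the reduced model exactly from the fitted full model via a
  discrete algebraic Riccati equation — avoiding the finite-order
  truncation that makes the classical route biased or erratic.
* **Directed coherence (DC) and partial directed coherence (PDC)** —
  `|γ_ij(f)|² = σ_j²|H_ij(f)|² / Σₘ σₘ²|H_im(f)|²` (total influence, rows
  sum to 1) and `|π_ij(f)|² = |Ā_ij(f)|² / Σₘ |Ā_mj(f)|²` (direct
  influence, columns sum to 1).
* **Causal spectral decomposition** — the receiver's PSD split per source,
  `S_t|j(f) = S_tt(f)·|γ_tj(f)|²`, which adds back the receiver dynamics
  that GGC/DC deliberately ignore.

The package also ships the two oscillator benchmark systems (a three-node
chain with one uncoupled direction, and a transmitter/receiver pair with
configurable receiver resonance) and a seeded Monte Carlo study runner that
compares estimator bias and variability against the closed-form truth.

## Worked example

```r
library(specgc)

model <- make_three_node_benchmark()   # chain 1 -> 2 -> 3; 40/10/50 Hz
model
#> VAR(3) model: 3 channels, fs = 120 Hz
#>   companion spectral radius 0.9000 (stable)
#>   channels: ch1, ch2, ch3

grid <- frequency_grid(120)            # 513 points on [0, 60] Hz

# closed-form true conditional GC along the coupled direction 1 -> 2 | 3
truth <- ss_conditional_spectral_gc(var_to_ss(model), 1, 2, 3, grid)
truth
#> GGC spectrum 1 -> 2 | {3} [ss]: 513 frequencies, max 1.709

# estimate the same spectrum from one 500-sample realization
series <- simulate_var(model, 500, seed = 1)
est <- ss_gc_from_data(series, order = 3, source = 1, target = 2,
                       cond = 3, grid = grid)
#> true peak 1.71 at 40.1 Hz | estimated peak 1.68 at 40.0 Hz
```

The true spectrum peaks at the transmitter's 40 Hz resonance — the
causality profile reflects what is *sent*, not the receiver's own 10 Hz
rhythm — and the state-space estimate recovers it from only 500 samples.
On the *uncoupled* direction 3 → 1 the truth is identically zero, and a
50-realization study shows why the estimation route matters:

```r
st <- run_monte_carlo_study(model, c("var(20)", "ss(3)"), 50, 500, grid,
                            master_seed = 1,
                            directions = list(list(source = 3, target = 1,
                                                   cond = 2)))
study_metrics(st)
#>   estimator direction realization_iae_median median_curve_iae band_width
#> 1   var(20)    3->1|2                  1.299            0.068      0.114
#> 2     ss(3)    3->1|2                  0.257            0.204      0.013
```

A single classical var(20) estimate is typically five times farther from
the zero truth (`realization_iae_median`, in GC·Hz over the 0–60 Hz band)
and its 5th–95th percentile band is an order of magnitude wider than the
state-space estimator's at the true order.

A command-line interface wraps the same functions
(`exec/specgc gc|dc|bench|simulate`); every run writes a `manifest.json`
with the config hash, master seed and warning counters, and seeded runs are
byte-identical.

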