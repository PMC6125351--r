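---
title: "Methods: dynamic positive/negative connectivity topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic positive/negative connectivity topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyntopo)
```

## The model and its assumptions

`dyntopo` analyses a node-by-time signal matrix (voxels or regions by
acquisitions at repetition time TR) in four stages.

**1. Sliding-window networks.** An overlapping window of `m` time-points
advancing by `n` points turns the series into
`floor((T - m)/n) + 1` network snapshots; each snapshot is the pairwise
Pearson correlation matrix over the window, Fisher-transformed
(`z = atanh(r)`) for variance stabilization. The default `m = 15`,
`n = 1` corresponds to 45 s windows at TR = 3 s — short enough to see
transient reconfiguration, long enough to estimate a correlation. With
a 120-point run this yields 106 snapshots. Assumption: within one
window the signal is approximately stationary, and Pearson correlation
(which demeans per window) is the right coupling measure.

**2. Stepwise functional connectivity.** Each snapshot is split by
sign. On the positive part `A` (non-negative weights, zero diagonal)
the SFC recursion `A_l = A_{l-1} A` accumulates, for step distances
`l = 2..7`, the weighted count of length-`l` routes between every pair.
Step 1 is excluded: a pair with a direct positive edge cannot
simultaneously be negatively correlated, so the negativity-vs-distance
question only makes sense from step 2. After min-max normalization the
optimal distance `OD(i,j) = argmax_l A_l(i,j)` is a geodesic proxy
through positive connections. The recursion counts *walks*, not simple
paths — revisits are allowed. This is deliberate and kept exactly as
defined; the zero diagonal removes the dominant self-loop
contributions, and the normalization makes the per-step distributions
comparable so the argmax is meaningful.

**3. Topology transitions.** For the positive and the negative network
separately, each node's configuration (its matrix row, the "star
network") is compared between consecutive snapshots by Euclidean
distance, giving a `nodes x (windows - 1)` transition series per sign:
a per-node time course of how strongly that node's connectivity pattern
is reorganizing.

**4. Topological causality.** Per node, a bivariate lag regression asks
whether past positive-transition values improve the prediction of the
negative-transition series beyond its own past (`F_pn`), and vice versa
(`F_np`). The lag order (1–5) is chosen by BIC; nested models are
compared by the F statistic with `(p, n_eff - 2p - 1)` degrees of
freedom. Alpha-level flags (0.05) and Benjamini–Hochberg FDR flags
(q = 0.05, across nodes, per direction) are reported, plus a
display score `F_pn - F_np` after percentile normalization.
Assumptions: linear-Gaussian dynamics of the transition series, and
stationarity over the run. Granger causality here concerns *topology
transition* series, not raw signals.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_m` | 15 | time-points | 45 s at TR = 3 s; correlation estimate vs temporal resolution trade-off |
| `window_n` | 1 | time-points | maximal overlap, smooth state transitions |
| band-pass | off (0.01–0.08 Hz when used) | Hz | synthetic inputs are already band-limited; real BOLD should be filtered |
| `l_max` | 7 | steps | weighted SFC values stabilize by step 7; configurable |
| `max_lag` | 5 | transitions | candidate Granger orders; BIC picks one |
| `alpha`, `fdr_q` | 0.05, 0.05 | — | conventional voxel-wise thresholds |

## What the generators emulate — and what they do not

**`gen_lag_chain`** plants the "negativity from distance plus lag"
mechanism in its purest form: a chain of modules all carrying the same
oscillation (period 30 s by default, inside the resting-state band),
each module delayed by `hop_lag_s` relative to its predecessor. At zero
noise and a sinusoidal base the correlation between modules `d` hops
apart is exactly `cos(2*pi*d*hop/period)` — an analytic oracle. The
default `hop = period/10` makes modules up to two hops apart positively
coupled and modules three or more hops apart negatively coupled, so the
positive graph is a band graph along the chain and the OD–negativity
relation is testable. `nodes_per_module` defaults to 1: at low noise,
extra nodes per module are near-duplicates whose `r = 1` edges saturate
the Fisher transform (clipped at `atanh(1 - 1e-7) ≈ 8.1`) and swamp the
walk counts; multi-node modules are supported and behave well at
realistic noise. A band-limited-noise base mode (0.01–0.08 Hz filtered
white noise, modules delayed by Fourier phase shift) is available for
more realistic spectra, at the cost of the exact oracle.

**`gen_follower`** plants a known causal direction between the two
network types. Time is divided into stationary blocks of exactly one
analysis window (15 points). In block `b`, a random node subset
(persisting with flip probability `reconfig_prob = 0.3` per block)
shares a latent signal — the positive ensemble; all nodes also carry a
second shared latent whose per-node sign mirrors the membership of
block `b - follow_lag_blocks`, creating genuine anti-phase couplings
between the two sign groups. Positive-set changes therefore precede
negative-structure changes by a known number of blocks.

Design notes from prototyping, kept because they shape what the fixture
can show. One window per block matters: with longer blocks, positive
and negative transition series share a deterministic block-boundary
periodicity (a "clock") that the richer positive series measures more
cleanly, biasing the direction test irrespective of the planted lag.
The sign-flip construction also has an unavoidable side channel: the
shared negative latent induces positive couplings *within* each sign
group, so the positive network partially reflects the (lagged) negative
structure. This weakens — but does not destroy — the time-reversed
control, which is why the default fixture is sized at 40 nodes and 80
blocks (1200 time-points): at that size the planted direction is
recovered in essentially all seeds and reverses in the large majority
of time-reversed runs.

Neither generator simulates hemodynamic response functions, scanner
noise spectra, head motion, or spatial autocorrelation. Passing tests
on these fixtures show the *pipeline* recovers planted structure of the
kinds the method assumes; they do not certify behaviour on real BOLD
with its preprocessing artifacts.

## Numerical choices

- **Diagonal convention:** self-correlations are set to zero in every
  matrix; self-loops are meaningless for path counting.
- **Fisher clipping:** `|r| >= 1 - 1e-7` is clipped before `atanh`,
  keeping matrix powers finite when synthetic signals correlate
  perfectly; `|r| > 1` beyond rounding tolerance is an error.
- **Zero-variance windows:** the affected node's row/column is zeroed
  with a warning; degenerate synthetic fixtures must not crash a run.
- **Window indexing:** 0-based, half-open `[start, end)` intervals
  internally and in the API; the count formula is tested property-style.
- **Normalization scope:** min-max per (window, step) over off-diagonal
  entries. The argmax is taken within one window, and the `c^l` scale
  covariance of matrix powers would otherwise let long steps dominate
  or vanish across windows; a pooled-across-windows mode exists behind
  `scope = "pooled"`.
- **OD ties and symmetry:** ties break to the smallest step (the
  conservative geodesic reading). BLAS matrix products are symmetric
  only up to summation order, so near-tie argmaxes are mirrored from
  the upper triangle to keep OD maps exactly symmetric.
- **Curve averaging order:** per-pair time averages first (OD over
  windows where defined, negative values over windows where the pair is
  negative), then binning by rounded average OD; dispersion is across
  pairs within a run. Averaging only over negative windows is the
  default; `include_positive_as_zero = TRUE` switches to the
  zeros-included reading. Values are reported on the `r` scale
  (inverse Fisher) by default.
- **Shared Granger lag:** the per-node lag is selected once on the
  *symmetric* BIC (sum of both directional full-model BICs) and reused
  for both directional tests; this makes the analysis invariant to
  swapping the two inputs (difference scores negate exactly) and avoids
  favouring the direction whose model selected the lag.
- **Percentile display normalization:** absolute `F_pn - F_np`
  differences are clamped at their 98th percentile across nodes and
  rescaled to [-1, 1]; this tames the heavy right tail of F differences
  without changing signs or ordering below the clamp. The 98% clamp is
  an interpretive choice for display; raw differences are always
  reported alongside.
- **Degenerate regressions:** constant or collinear series yield
  `F = 0, p = 1` with a warning (and a per-node `failed` flag in the
  map) rather than aborting a whole run.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with tight oracles: 6–7 node
graphs for brute-force walk enumeration (the enumeration is
exponential), 120-point runs for the structural counts, 1000/500
simulations for type-I/power calibration of the Granger F-test, 50
seeds for direction recovery, and exhaustive Benjamini–Hochberg checks
up to length 12. These sizes are the package's own choices for a fast,
deterministic check suite.

## Known limitations

- The SFC recursion's walk counting means `OD` is a heuristic geodesic
  proxy, not a shortest-path length; on graphs with strong hubs the
  argmax can saturate at `l_max`.
- Granger inference on transition series inherits the usual caveats of
  lag-limited linear causality: contemporaneous coupling is invisible,
  and shared measurement noise between the positive and negative series
  (both derive from the same windows) biases toward symmetric effects.
- The per-run analysis assumes one uninterrupted acquisition;
  concatenating runs without a break indicator would leak lagged terms
  across run boundaries, so runs should be analysed separately.
- FDR is applied across nodes within one run; no group-level
  aggregation is implemented beyond averaging difference maps.
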