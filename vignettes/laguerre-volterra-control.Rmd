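---
title: "Laguerre-Volterra modeling and inverse-model stimulation control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laguerre-Volterra modeling and inverse-model stimulation control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcontrol)
```

# The modeling problem

Evoked field-potential amplitudes in a stimulated neural pathway depend on
the current stimulation intensity *and* on the recent stimulation history:
paired-pulse facilitation and depression modulate responses over tens to
hundreds of milliseconds. `lvcontrol` models this as a single-input,
single-output second-order Volterra system driven by a train of
variable-amplitude impulses, and exploits the structure of that model to
*invert* it — turning a desired response trajectory into the stimulation
amplitudes that reproduce it.

The data unit is an event train: strictly increasing event times $t_i$
(seconds) with input amplitudes $A_i$ and, for estimation, one
contemporaneous output amplitude $y(t_i)$ per event. Amplitudes are used
raw, in their native units (μA for stimulation, mV for evoked responses);
no standardisation is applied by default, since the model is linear in its
parameters and the inverse solve is unit-consistent either way.

## Zero-lag isolation

Because the input amplitude varies from event to event, the terms involving
the *present* impulse are kept separate from the history terms:

$$y(t_i) = c_0 + c_1(0) A_i + c_2(0,0) A_i^2
  + \sum_{l} c_1(l)\, v_l(t_i)
  + \sum_{l_1, l_2} c_2(l_1,l_2)\, v_{l_1}(t_i) v_{l_2}(t_i)
  + 2 A_i \sum_{l} c_2(l)\, v_l(t_i)$$

with $v_l(t_i) = \sum_{t_i - \mu < t_j < t_i} A_j L_l(t_i - t_j)$ the
Laguerre convolutions of past impulses. Two consequences drive the design:

* the first three terms are the static input–output curve, the last three
  the nonlinear dynamics — reconstructed kernels therefore carry separate
  zero-lag entries ($k_1(0)$, $k_2(0,0)$) whose polarity can differ from the
  adjacent history lags;
* with history fixed, $y$ is a *quadratic* in $A_i$, which is what makes the
  per-event analytic inversion possible.

The present impulse is excluded from $v_l$ by construction (the half-open
window $t_i - \mu < t_j < t_i$); its entire effect lives in the isolated
zero-lag terms. An event exactly $\mu$ old is likewise excluded.

## The Laguerre basis

The discrete orthonormal Laguerre functions
$$L_l(m) = \alpha^{(m-l)/2} (1-\alpha)^{1/2} \sum_{k=0}^{l} (-1)^k
  \binom{m}{k} \binom{l}{k} \alpha^{l-k} (1-\alpha)^k$$
compress the kernels: $k_1(m) = \sum_l c_1(l) L_l(m)$ and
$k_2(m_1,m_2) = \sum_{l_1,l_2} c_2(l_1,l_2) L_{l_1}(m_1) L_{l_2}(m_2)$, so a
memory of thousands of lag bins costs only $3 + 2L + L(L+1)/2$ parameters.
Orders are indexed 0-based internally ($l = 0, \dots, L-1$, the $l=0$
function being the pure geometric decay); sums written over $l = 1..L$ in
the model display map onto this range one-for-one.

Two evaluation routes are implemented and cross-checked in the test suite:

* `laguerre_function()` — the closed form above with binomial coefficients
  in log space (`lchoose`), stable to lags of several thousand bins;
* `laguerre_basis()` — the standard two-term recurrence
  $L_l(m) = \sqrt{\alpha} L_l(m-1) + \sqrt{\alpha} L_{l-1}(m) - L_{l-1}(m-1)$,
  used to tabulate the basis on the full lag grid.

Continuous inter-event lags are binned at width `dt` by round-to-nearest.
`dt` defaults to 1 ms — well below the 2 ms minimum inter-impulse interval
of the stimulation protocols, so binning error is bounded by the smoothness
of the basis over one bin.

### Parameter defaults

The basis parameters are not identified by any physical constant; they are
modeling choices, exposed everywhere and searchable via
`lv_cross_validate()`:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.7 | decay; sets the time extent of the basis |
| `n_basis` (L) | 3 | number of functions; 15 parameters total |
| `memory` (μ) | 3 s | history window, events older contribute nothing |
| `dt` | 1 ms | lag-bin width |

A caveat worth knowing: with `dt` = 1 ms, α = 0.7 concentrates the basis in
the first ~30 ms of lag. That is appropriate for very fast dynamics, but the
paired-pulse timescale of hippocampal slice preparations is better matched
by α ≈ 0.99 (basis mass over ~50–500 ms), which is why the synthetic
ground-truth presets use α = 0.99 and why the worked examples fit with it.
Cross-validated VAF is the arbiter in practice: in the README example the
α = 0.7 basis scores a *negative* held-out VAF on α = 0.99 data while the
matched basis scores ~88%.

# Estimation

`lv_design_matrix()` lays out, per event,
$[1, A_i, A_i^2, v_1..v_L, \{v_{l_1} v_{l_2}\}_{l_1 \le l_2}, 2A_i v_1..2A_i v_L]$.
Symmetry of $c_2$ is enforced structurally: the off-diagonal products are
folded into single columns carrying $2 v_{l_1} v_{l_2}$, so each fitted
coefficient is the shared symmetric entry of the double sum and the mapping
back to kernel space is exact. History resets at train boundaries — trains
are collected minutes apart and treated as independent realisations.

`fit_least_squares()` solves the system by SVD, reports the design condition
number, and names the offending columns on rank deficiency; an optional
ridge penalty (intercept excluded) is available for deliberately
over-parameterised fits. With the protocol-sized designs used here
(1200 events × 15 parameters, condition numbers around $10^5$–$10^6$),
noiseless synthetic coefficients are recovered to ~$10^{-12}$ relative,
comfortably inside the $10^{-6}$ the test suite asserts.

Validation uses leave-one-train-out cross-validation: with four trains this
gives four folds, each scored with VAF and NMSE on the held-out train, and
the basis configuration maximising mean held-out VAF wins. Leave-one-out at
the train level (rather than a single split) is a choice; it uses all the
data while still keeping estimation and prediction sets disjoint.

## Metric conventions

* `vaf()` uses the sample ($n-1$) variance; the value is identical under the
  population convention because the factor cancels. Note the formula's
  quirk: a constant offset between prediction and observation has zero
  residual *variance*, so it does not reduce VAF. NMSE does penalise it.
* `nmse()` divides by the uncentered $\sum Y^2$, exactly as defined — a
  zero predictor scores exactly 1, and the metric is invariant to joint
  rescaling of both series.
* `qq_points()` pairs the two series rank-by-rank for distributional
  comparison and reports the maximum deviation from the identity line.

# The inverse plant model

`invert_sequence()` walks the desired trajectory in time order. At each
event the convolutions $v_l$ are built from the amplitudes *solved at
earlier events* — true recursion, never the reference input — so before the
first event the history terms are exactly zero and the first amplitude comes
from the static quadratic alone. Then $aA^2 + bA + c = 0$ is solved with

$$a = c_2(0,0), \quad b = c_1(0) + 2\sum_l c_2(l) v_l, \quad
  c = c_0 + \sum_l c_1(l) v_l + \sum_{l_1,l_2} c_2(l_1,l_2) v_{l_1} v_{l_2} - y.$$

The default branch is $A = (-b + \sqrt{b^2-4ac})/2a$. For a saturating
plant ($a < 0$) operated below the vertex of its static curve this selects
the physically operating root, and composing the forward model with the
inverse is the identity on amplitudes to machine precision (asserted at
$10^{-8}$ relative in the tests). Alternative branches (`"minus"`,
`"nearest"` to the previous amplitude) are exposed as a policy switch.

Degenerate events are flagged rather than fatal — a stimulation device must
emit something:

| condition | action | flag |
|---|---|---|
| $|a| <$ tol | linear solve $-c/b$ | `linear_fallback` |
| $b^2 - 4ac < 0$ (target unreachable) | vertex $-b/2a$ | `no_real_root_vertex` |
| $A < 0$ | clamp to 0 | `clamped_negative` |
| $|a|, |b| <$ tol | error naming the event | — |

The vertex clamp for unreachable targets is a deliberate saturation
semantic: the solver emits the amplitude whose predicted output comes
closest, records the shortfall, and moves on. Causality holds by
construction: the amplitude at event $i$ is invariant to desired outputs at
later events.

# The synthetic-data generator

No recorded slice data ship with the package; every claim the tests make is
made against synthetic data from fully known ground-truth models. The
generator emulates the standard stimulation protocols:

* **Timing** — Poisson trains at mean rate 2 Hz, exponential intervals
  resampled (not clipped, avoiding probability mass at the bounds) into
  [2 ms, 5 s]; 4 trains × 300 pulses = 1200 events by default.
* **FARIT** — fixed intensity, default 200 μA (the fixed level is picked per
  preparation in practice, so it is a parameter).
* **RARIT** — Gaussian amplitudes, mean 150 μA, sd 45 μA (30% CV, a chosen
  spread that keeps essentially all draws positive while exercising the
  plant's dynamic range; the sd is not a protocol constant), truncated
  positive by resampling.
* **Plant** — `make_ground_truth_model()` presets share a positive,
  saturating, monotone static curve over [0, 2·`input_scale`]
  ($c_0 = 0.05$, $c_1(0) = 1.2/s$, $c_2(0,0) = -0.25/s^2$ in mV with
  $s$ = `input_scale`), and differ in history-term sign structure:
  `facilitating`, `depressing`, `mixed` (facilitation at short lags turning
  to depression later). At $A = s$ and a 50 ms gap the history terms
  modulate the response by roughly ±30% — the magnitude of typical
  paired-pulse effects. Output noise is i.i.d. Gaussian per event
  (default sd 0.1 mV, roughly 10% of the evoked-response scale).

`run_endtoend_scenario()` chains the whole protocol: upstream trains with
Gaussian amplitude variability (mean 1 mV, sd 0.25 mV — standing in for
population-spike variability under fixed upstream stimulation) drive a
ground-truth trajectory model (output gain 0.7, which keeps the desired
trajectory inside the plant's reachable range); both models are fitted by
cross-validation; the fitted pair derives stimulation amplitudes; the
ground-truth plant "delivers" them with fresh noise; and the controlled
responses are scored against the reference responses, alongside a
fixed-amplitude benchmark at the same mean intensity. In the noiseless
limit the controlled NMSE is zero to rounding; with noise it degrades
gracefully and stays below the fixed-amplitude benchmark in ~50 of 50
seeded replicates (the acceptance suite requires ≥ 45).

**What this does and does not show.** The generator reproduces protocol
statistics, second-order dynamics, and per-event Gaussian observation
noise. It does not emulate slow nonstationarity (electrode drift, synaptic
run-down over a session), non-Gaussian or state-dependent noise,
higher-than-second-order dynamics, or upstream feature-extraction error.
Passing tests therefore demonstrate correctness of the estimator and the
inversion under the model's own assumptions — not robustness of the
paradigm to a real preparation's violations of them.

# Numerical choices and degenerate inputs

* Singularity threshold: singular values below
  $\max(n,p)\,\varepsilon\, d_1$ trigger a rank-deficiency error (OLS) with
  the dependent columns named via pivoted QR.
* Inverse-solver tolerance for $|a| \approx 0$ is $10^{-12}$ absolute —
  coefficients of $A^2$ in native units are $O(10^{-5})$, so only an exactly
  (or structurally) zero quadratic term takes the linear branch.
* Lag-bin index is clipped to the grid, so an event just inside the memory
  window cannot index past the last tabulated lag.
* Empty histories, zero-amplitude events, and constant desired trajectories
  are all well-defined (the latter at baseline yields all-zero stimulation).
* Problem sizes: unit tests run on 2 s / 200-bin bases and 10–300-event
  trains; the end-to-end material uses the full 4 × 300-event protocol at
  the default 3 s / 3000-bin grid, and replicated studies use 50 replicates.

# Limitations

* The series is truncated at second order throughout; systems with strong
  third-order interactions will fold them into biased second-order terms.
* Control is open-loop: no error feedback corrects the delivered response.
  The `flags` diagnostics make infeasible events visible, but nothing is
  re-planned.
* The quadratic inverse presumes the fitted $c_2(0,0) \ne 0$ regime was
  explored by the estimation data; extrapolating the inverse far beyond the
  fitted amplitude range inherits all the usual risks of polynomial
  extrapolation.
* Basis parameters are chosen by grid search, not optimised continuously.
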