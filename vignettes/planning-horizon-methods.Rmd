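---
title: "Models and methods: planning horizons in sequence production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: planning horizons in sequence production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planhorizon)
```

## The scientific problem

In a viewing-window discrete sequence production (DSP) task, participants
produce a fixed sequence of 14 keypresses (digits 1–5, one per finger) as
fast and accurately as possible, while only the next `w` digits are visible;
the rest are masked and revealed press by press. The window size `w` spans
1–8 and 14, randomised within blocks. Because `w` controls exactly how much
advance information is available, the MT-versus-`w` curve measures how many
future movements the motor system can usefully plan — the *planning
horizon* — and how that capacity splits into preplanning (before the first
press) and online planning (during execution).

This package implements the complete analysis chain for such experiments
together with a generative simulator of them, so that every stage can be
verified end to end against known ground truth.

## The horizon model

Mean MT per window size is modelled as

$$\mathrm{MT}(w) = a\,e^{-b(w-1)} + c,$$

with span $a$ (ms), decay rate $b$ (1/window-item) and asymptote $c$ (ms);
at $w = 1$ the curve equals $a + c$. The *effective planning horizon* is
defined by the window size at which the predicted MT has dropped 99% of the
gap to the asymptote:

$$w^\* = \frac{-\log(0.01)}{b} + 1.$$

The 1% criterion is a convention: changing it rescales $w^\* - 1$ by a log
ratio and never reorders participants, so all comparative conclusions are
criterion-free. `horizon_fit()` estimates $(a, b, c)$ by
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nls.lm`, the
standard algorithm for this model class).

Numerical choices:

* **Positivity of `b`.** The optimiser works on $\log b$, since a negative
  decay rate has no interpretation here and would leave $w^\*$ undefined.
* **Initialisation and multi-start.** $a_0 = \mathrm{MT}(w_{\min}) -
  \mathrm{MT}(w_{\max})$, $c_0 = \mathrm{MT}(w_{\max})$, and $b_0 \in
  \{0.5, 0.2, 1, 2\}$; the lowest-SSE converged solution is kept. On
  noiseless curves this recovers generating parameters to $10^{-6}$ or
  better; against a profile-`b` grid search with exact linear $(a, c)$
  solves, the fitted SSE is never worse (this is asserted in the test
  suite).
* **Degenerate data.** Constant MT curves leave `b` unidentifiable; the fit
  is flagged invalid (`valid = FALSE`) and excluded downstream rather than
  reported. Fits are applied to participant-level *mean* MT per `w`
  (9 points in the canonical design), not to trial-level data, which keeps
  the noise model simple; replicated `w` values are averaged first.
* **Convergence tolerances** are set tight (`ftol = ptol = 1e-14`, 500
  iterations) because the curves have only 9 points and the cost of extra
  iterations is negligible.

Per-day fits pool all non-error trials of the day before averaging per `w`.
The split-half analysis (`split_half_horizon_mt()`) estimates the horizon
from odd-numbered blocks and the large-window MT (`w > 5`) from
even-numbered blocks, removing the spurious correlation that shared
measurement noise would otherwise induce.

## Trial processing conventions

* A press is the first force sample at/above 1 N after the key was below;
  the release is the first sample back below. IPIs are intervals between
  consecutive *press* threshold crossings (consistent with the RT
  definition, which also uses the press crossing); MT is first press onset
  to last release.
* **Debounce:** a key must stay below threshold for at least 20 ms before a
  new press on the same key is registered, guarding against transducer
  noise double-counts. A trace ending mid-press yields a missing release.
* A trial is an error if any produced digit differs from its target or the
  press count differs from 14; presses beyond the 14th are ignored for
  timing. Error trials are excluded from every RT/MT/IPI aggregate.
* The adaptive reward threshold drops by 5% after a block only if the block
  median MT beats the best median so far (strictly) and the block error
  rate is at most 15%; "5% or more faster" for the 3-point reward is
  implemented inclusively (`mt <= 0.95 * threshold`). Block medians exclude
  error trials by default (`include_errors` flag available, since either
  reading of the procedure is defensible).

## IPI planning categories

Transition $i$ (1–13) of a trial with window `w` is labelled `SR` when
`w = 1` (pure serial cycling — improvements there reflect single-response
processes, not sequence planning), `preplanned` when
$i \le \min(w - 1, 3)$, and `online` otherwise. The boundary is fixed by
design, not estimated. The final transition is executed atypically fast;
it stays in the `online` category by default, with
`exclude_last_transition = TRUE` in `ipi_table()` as a robustness check.
Aggregation is always participant-then-group so that each participant
contributes equally regardless of trial counts. Normalised practice
improvement between two days is
$(m_{d_1} - m_{d_5}) / \mathrm{mean}(m_{d_1}, m_{d_5}) \times 100$,
computed within each cell; it is invariant to rescaling a participant's
durations.

## Eye analysis

Gaze is mapped to digit units as $D_t = 1 + (x_t - x_0)/p_x$, with $x_t$
the median horizontal gaze in a 25 ms window centred on the press (the
window is symmetric by choice; only "around the keypress" is prescribed by
the paradigm), $x_0$ the first-digit position at trial start and $p_x$ the
tracker-units-per-digit constant of the block. Blink samples are dropped
before the median; an empty window yields a missing value rather than an
interpolation. Relative eye position subtracts the press position, so 0
means fixating the pressed digit. Profiles use presses 3–10 by default (the
mid-sequence presses most sensitive to fixation strategy) and group windows
as 1, 2, 3, 4+.

## Within-subject statistics

`rm_anova()` performs the classical balanced within-subject decomposition
(each effect tested against its subject-by-effect interaction), computed
via `stats::aov` with an `Error(subject/...)` stratum. For two-level
factors, $F = t^2$ of the paired test to machine precision. No sphericity
correction is applied by default, matching common reporting practice for
this paradigm; `gg = TRUE` applies a Greenhouse–Geisser adjustment whose
epsilon is computed from orthonormal contrasts of the subject-level cell
covariance. Participants missing any cell are dropped listwise with a
warning. **No multiple-testing correction is applied anywhere** — the
t-test batteries mirror the single-comparison reporting style of the field
and should be read accordingly. Degenerate inputs are handled explicitly:
a zero effect sum of squares reports $F = 0, p = 1$ (the error term is then
also zero, so the ratio would otherwise be numerical noise), and
zero-variance t tests/correlations return `NA` with a warning. Error bars
for condition means use within-subject SEMs: each participant's mean across
conditions is removed (grand mean added back) before computing the SEM, so
they visualise the repeated-measures error term.

## The generative simulator

No raw data are distributed with studies of this paradigm, so the simulator
is a first-class module: it defines the conditions under which the pipeline
is validated. It emulates the canonical design — 14 participants × 5 days ×
8 blocks × 27 trials, `w ∈ {1..8, 14}` randomised within block, sequences
built from concatenated random shuffles of 1–5.

The timing model is a *soft horizon* scheme built from the same exponential
law the analysis fits, which makes parameter recovery well-posed and
interpretable:

* Transition $i$ sees $k_i = \min(w - 1, 14 - i)$ upcoming items and gets a
  raw duration $c_\mathrm{ipi} + a_\mathrm{ipi} e^{-b k_i}$; the preplanned
  prefix ($i \le \min(w-1,3)$) and, for $w > 1$, the final transition are
  discounted by `first_last_discount` (80 ms), reproducing the fast
  first/last intervals seen empirically (the final-interval speed-up is an
  end-of-sequence effect reported only for `w > 1`, so `w = 1` profiles
  stay flat).
* The 13 raw IPIs of each trial are then rescaled by a common factor so the
  scheduled MT equals $a e^{-b(w-1)} + c$ *exactly*. Without this step the
  end-of-sequence truncation and the discounts would bend the noiseless MT
  curve slightly away from the exponential; rescaling preserves the IPI
  profile shape while making noiseless parameter recovery exact — the
  property the recovery suite leans on.
* RT is `rt_base + rt_per_item * min(w, preplan_cap)` (550 + 70·min(w, 3)
  ms), yielding ~760 ms initiation for large windows with a plateau beyond
  three items.
* Noise is multiplicative lognormal with unit mean (CV 0.12 by default):
  strictly positive, right-skewed latencies whose expected MT equals the
  schedule.
* Each press is wrong independently with probability 0.0095, chosen so the
  trial-level error rate $1 - (1-p)^{14} \approx 12.4\%$ sits inside the
  10–15% band typical of the task.

Calibration targets were fixed up front from the group values this
paradigm reports: $a = 2800$, $c = 3200$ ms (so MT(1) = 6000 ms and the
`w = 1` interpress time is ≈ 460 ms); day-1 decay rate `b` equivalent to a
horizon of 3.20 items, with `1/b` growing 0.0369 per day so the day-5
horizon is 3.88. Practice additionally shrinks MT(1) by a per-day factor
(`day_gain_w1`, 586 ms over five days) and the asymptote by a stronger one
(`day_gain_c`, 1110 ms at `w = 14`). Two factors are needed: a single
uniform gain would make *relative* improvements equal across `w` (and the
horizon expansion alone would even depress them at `w = 2–3`), whereas the
observed pattern is gains growing with window size up to the `w ≈ 4`
plateau — which the asymmetric parameterisation produces naturally.
Between-participant heterogeneity draws a lognormal skill factor (CV 0.10)
on $a, c$ and a horizon (SD 1.0 item, truncated at 1.3), negatively coupled
(ρ = 0.6) so slower participants have shorter horizons; this generates the
negative split-half horizon–MT correlation in the direction reported
empirically. The coupling magnitude is a package choice — the paradigm's
literature reports only the direction and a correlation bound, not a
generative effect size.

Force traces render each press as a half-cosine pulse at 200 samples/s that
crosses 1 N exactly at the scheduled press time and falls below it at the
release; the shape is cosmetic, only the crossing times carry information.
Scripted gaze is a saccade-and-fixate step function leading press $i$ by
$\min(w-1, 3) \times 0.4$ digits plus Gaussian noise (SD 0.3 digits), with
saccades placed halfway between presses so the 25 ms analysis window sees a
stable fixation.

Seeding uses one master seed with per-participant child streams, so adding
participants never changes earlier participants' data and identical
parameters yield bit-identical tables.

### What the simulator does *not* emulate

Passing tests demonstrate that the pipeline is internally correct under the
generative model, not that the model is reality. In particular there is no
visual acuity/crowding limit, no sequence-specific learning or chunking, no
biomechanical coupling between fingers (IPI noise is independent across
transitions), no RT-MT trade-off, and gaze dynamics are step functions
rather than saccade kinematics with measurement drift. Conclusions about
real data should rest on the estimators' contracts (definitions, exclusion
rules, invariances), which the tests verify directly, not on resemblance of
simulated numbers to published group values.

## Problem sizes and runtime

The test suite validates small cohorts (2–8 participants, 1–2 days) for the
unit and property checks, and the full 14 × 5 × 8 × 27 design for parameter
recovery at true horizons of 2.5, 3.5 and 4.5 items, where the group-mean
recovered horizon lands within a few hundredths of an item of the realized
truth. These sizes were chosen to keep the default check fast while still
exercising the full design where the claim depends on it.

## Interface notes

The package's surface is its functions, this vignette and
`run_pipeline()`, which executes the whole chain and writes tidy CSVs plus
an exclusion log; `write_experiment()`/`read_experiment()` define the
plain-text interchange format (per-press CSV plus a JSON parameter/truth
sidecar). A `--strict` style behaviour is available via
`run_pipeline(strict = TRUE)`, which fails instead of warning when any
horizon fit is invalid.
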