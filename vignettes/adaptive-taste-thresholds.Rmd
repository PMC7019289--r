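---
title: "Adaptive yes-no taste threshold estimation: models, procedures, and repeatability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive yes-no taste threshold estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptaste)
```

## The measurement problem

A taste recognition threshold is the concentration of a tastant (citric
acid, sodium chloride, quinine hydrochloride, sucrose) at which a person
reliably recognizes the taste. Measuring it with a yes/no task is fast and
natural for participants, but yes/no responses confound *sensitivity* with
*response criterion*: a liberal responder says "yes" to blanks, a
conservative one withholds "yes" near threshold. `adaptaste` implements two
Bayesian adaptive procedures that address this differently, plus the
statistical machinery to compare their test-retest repeatability.

## The two psychometric models

**QUEST family.** The probability of a "yes" at log10 concentration $c$ is a
Weibull-type function

$$\Psi_{yes}(c) = \delta\gamma + (1-\delta)\left[1 - (1-\gamma)
  e^{-10^{\beta (c - \tau + \epsilon)}}\right],$$

with slope $\beta = 3.5$, false-alarm/guess rate $\gamma = 0.01$, lapse rate
$\delta = 0.01$ (all fixed a priori), and threshold $\tau$ the single free
parameter. The lateral shift $\epsilon$ is solved numerically
(`solve_epsilon()`) so that $\Psi_{yes}(\tau) = 0.80$: "threshold" is by
definition the concentration yielding 80% "yes" responses. The false-alarm
rate is *assumed*, not estimated.

**quick Yes-No (qYN) family.** Sensitivity follows a saturating d′ function
of linear concentration,

$$d'(c) = \frac{\beta\,(c/\tau)^{\gamma}}{\sqrt{(\beta^2-1) +
  (c/\tau)^{2\gamma}}}, \qquad
\Psi_{yes}(c) = \epsilon + (1-\epsilon)\left[1 - \Phi(\lambda - d'(c))\right],$$

with upper asymptote $\beta = 5$ (fixed), lapse $\epsilon = 0$ (fixed),
slope $\gamma$, decision criterion $\lambda$ (z-units; the false-alarm rate
is $1-\Phi(\lambda)$), and threshold $\tau$ defined by $d'(\tau) = 1$. Here
criterion and slope are *estimated* alongside the threshold, so a liberal
responder does not masquerade as a sensitive one.

The two threshold definitions are genuinely different (80% yes vs d′ = 1),
so systematic offsets between the procedures' estimates are expected and are
not a bug; the simulator deliberately allows measuring an observer of one
family with the procedure of the other to study exactly this.

## Concentration ladders

Stimuli live on decadic log-spaced ladders (`build_log_grid()`); the four
packaged presets span 0.015–46.8 mM (citric acid, 14 levels, step 0.269),
0.342–342 mM (NaCl, 12 levels, 0.273), 7.7×10⁻⁵–3.13 mM (quinine-HCl, 21
levels, 0.230), and 0.073–584 mM (sucrose, 14 levels, 0.300). "14 steps" is
read as 14 *levels* (13 intervals): only that reading reproduces the printed
step widths. Estimation uses a finer virtual grid with midpoints inserted
between physical levels (`insert_midpoints()`, 2n−1 values); proposals are
snapped back to physical levels at presentation (`snap_to_physical()`, ties
toward the lower, less intense concentration — the conservative choice where
no convention is stated).

Two numerical notes on the presets. The nominal quinine start concentration
(0.077 mM) is exactly 3 log10 units above the ladder minimum, which is not an
integer number of 0.2305-wide steps; since the first stimulus must be
physically available, the preset snaps it to the nearest level (0.0763 mM).
And the qYN threshold grid for quinine uses the full-range midpoint grid (41
values) by default: a truncated range is supported via `tau_range_override`
in `qyn_init()`, but no particular truncation is assumed.

## The QUEST engine

The posterior over $\tau$ lives on a dense candidate grid (granularity 0.01
log10 units, extended one physical step past the stimulus range so the
posterior is not artificially cut off; final estimates are clamped to the
stimulus range regardless). The prior is normal, centered on the start
concentration, with SD 20 log10 units — read in log10 units (the plausible
alternative, grid units of 0.01, gives SD 0.2 and a sharply informative
prior that contradicts its description); at SD 20 the prior is flat over any
tastant range to within 2%, which the tests verify.

Each trial multiplies the posterior by $\Psi$ (yes) or $1-\Psi$ (no) and
renormalizes. Stimulus placement is at the posterior-mean threshold snapped
to the physical ladder — consistent with the posterior-mean estimator, which
is the unbiased choice in this family — with an anti-repeat rule: if the
snapped proposal would repeat the previous level, it moves one step up after
a "no" and one step down after a "yes". Termination: after more than 10
trials, stop once the central 90% credible interval is narrower than half a
physical step; hard cap at 20 trials. Credible-interval quantiles
interpolate the discrete CDF linearly over its mass-carrying (strictly
increasing) points — interpolating across zero-posterior runs would drag the
outer quantiles toward the grid edges.

A property worth knowing: with the slope fixed at 3.5, the per-trial Fisher
information about $\tau$ peaks around 40 (nat units, at the 80% placement
point), so an interior threshold needs ≈25–30 on-threshold trials before the
credible interval reaches half a step. Within the 20-trial cap, early
termination therefore occurs mainly for observers at or beyond the ends of
the stimulus range, where the clamped posterior concentrates quickly.
Simulated interior-threshold sessions usually run the full 20 trials; this
is a property of the procedure's parameterization, not of the
implementation.

## The qYN engine

The posterior lives on the 3-D lattice $\tau \times \gamma \times \lambda$:
virtual-grid threshold candidates, 10 slope values log10-equispaced over
[0.5, 3.0], 8 criterion values linearly equispaced over [0.75, 2.50]
(false-alarm rates ≈22.7% down to <1%). The prior is uniform over all
combinations. Likelihoods are floored at $10^{-12}$ per cell: with
$\epsilon = 0$ the model assigns probability ~0 to a "no" at extreme
suprathreshold concentrations, and one contrary lapse would otherwise zero
out entire posterior slices.

Stimulus selection maximizes expected information gain, realized — as is
standard in this procedure family — as one-step-ahead minimization of the
expected Shannon entropy of the full 3-D posterior,
$p_{yes} H(\text{post}\mid yes) + (1-p_{yes}) H(\text{post}\mid no)$,
searched over the physical levels only (the program can only present
physical concentrations), with ties broken toward the lower concentration.
This criterion reproduces the procedure's signature behavior: placements
slightly above and below threshold to pin down the slope, interleaved with
very low concentrations that probe the false-alarm rate. No anti-repeat rule
is added; the entropy criterion provides the variability itself. Sessions
run exactly 20 trials — no dynamic stopping, so the three parameters always
receive enough data.

Estimates are marginal-posterior-weighted means; the threshold (in log10
space) is clamped to the stimulus range. The false-alarm rate is reported by
default as $1-\Phi(\hat\lambda)$ — the transform of the averaged criterion,
matching the analysis pipeline's transformation order — with the
average-of-transforms alternative available via `far_method =
"mean_transform"`.

## The simulated-observer world

`sim_observer()` wraps a true parameter set of either family; `respond()`
draws one Bernoulli response per stimulus. `run_test_retest()` samples a
cohort: true thresholds normal in log10 mM (defaults can be set per tastant
from published human summaries, though no test depends on those values),
slopes log-uniform over [0.5, 3.0], criteria uniform over [0.75, 2.50].
Between sessions, thresholds and criteria can drift — zero-mean jitter
(`retest_jitter_*`) and/or a systematic criterion shift
(`retest_shift_lambda`). For the drift-recovery check we use a pure shift of
0.5 z-units (two criterion-grid steps — a clearly interpretable "participant
became more liberal/conservative" change) with no additional jitter, since
random criterion jitter only attenuates the signal whose *sign* is being
tested; for the FAR-slope coupling check we use jitter of 0.4 z-units and no
shift. The generator emulates stationary, independent Bernoulli responding;
it does not model adaptation, fatigue, inter-stimulus timing, or
taste-quality confusion, so a green recovery test establishes correctness of
the inference machinery, not robustness to those human factors.

## Repeatability statistics

Given paired test/retest measurements (pairs with a missing member are
excluded up front), the package reports Spearman's rank correlation and the
difference-based Bland-Altman summary: mean difference $\bar d$ (test −
retest), sample SD of differences (n−1 denominator — the standard
Bland-Altman practice; no convention is stated in the source material),
coefficient of repeatability $CR = 1.96\,sd$, limits of agreement
$\bar d \pm CR$, the 95% CI of the mean difference
$\bar d \pm 1.96\,sd/\sqrt{n}$ (the SE is $sd/\sqrt{n}$, following the
cited standard method), and 95% CIs of the LoAs by the exact-paired
(noncentral-t) construction, with a labeled normal approximation
($LoA \pm 1.96\,sd\sqrt{3/n}$) as a fallback. The constant 1.96 is used as
the conventional z-score literal so that $CR = 1.96\,sd$ holds to machine
precision. The within-participant-SD pathway is reported alongside:
$s_w = \sqrt{\overline{d^2/2}}$ and $CR' = 1.96\sqrt{2}\,s_w$.

False-alarm rates have multiplicative session noise (differences grow with
the mean), so their analysis runs on log10-transformed data
(`log_agreement()`); results map back to the original scale with
$y_{back} = 2M(10^{y_{log}}-1)/(10^{y_{log}}+1)$, a line through the origin
in the session mean $M$ — the back-transformed LoAs fan out with the mean
rather than being horizontal.

Dividing a threshold CR in log10 mM by the ladder's step width
(`cr_in_steps()`) expresses expected between-session differences in
concentration steps, comparable across tastants.

## Numerical choices and degenerate inputs

* The Weibull exponent argument is clipped at ±700 before exponentiation;
  unreachable on any packaged ladder, it only guards user-supplied extremes.
* `solve_epsilon()` brackets adaptively and solves to 1e−10; targets outside
  the attainable (γ, upper asymptote) band are rejected at model
  construction.
* Exact midpoint snapping ties resolve to the lower concentration via a
  1e−12 comparison tolerance (floating-point midpoints are not exactly
  equidistant).
* Zero total likelihood in either engine raises a degenerate-posterior error
  rather than silently renormalizing.
* Constant input to `spearman_rho()` and single pairs to `agreement()` are
  errors, not NaNs.
* Artifact CSVs serialize doubles with 17 significant digits so that
  re-reading a written paired table reproduces its agreement report
  bit-identically.

## Known limitations

* No n-AFC (forced-choice) QUEST variant, no lapse-rate estimation, no
  non-normal priors.
* qYN does not estimate the d′ asymptote β or the lapse ε, and has no
  dynamic stopping.
* The repeatability module deliberately omits rmANOVA machinery and ICCs;
  it covers the difference-based (Bland-Altman) pathway only.
* Human-subject summary values (mean thresholds, human CRs, human trial
  counts) are properties of participants, not of this software, and are not
  asserted anywhere; simulation tests check signs, recovery error bounds,
  and internal consistency instead.
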