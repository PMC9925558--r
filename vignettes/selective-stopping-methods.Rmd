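---
title: "Methods: simulating and analysing response-selective stopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing response-selective stopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(selstop)
```

## The task and what the package computes

In the multicomponent stop-signal task, two thirds of trials are *go*
trials: an imperative signal (IS) calls for a synchronous bimanual button
press (presses less than 50 ms apart). On the remaining third, one side's
go stimulus turns into a stop signal after a staircased stop-signal delay
(SSD), and only that hand must be cancelled while the other continues. A
warning signal (WS) before the IS either carries no information (*reactive*
condition, fixation cross) or announces which hand might have to stop
(*proactive* condition, "Maybe Stop Left/Right" cues). Dual-coil TMS over
both primary motor cortices probes corticospinal excitability (CSE) and
short/long-interval interhemispheric inhibition (SIHI, LIHI) at four
timepoints (WS, IS, IS+150 ms, stop-signal+150 ms).

The package provides, as separately testable modules: the deterministic
trial schedule with pseudorandomised TMS allocation (`build_schedule()`,
`assign_tms()`); a generative model of task behaviour and MEP amplitudes
(`simulate_cohort()`); the behavioural processing rules and SSRT estimation
(`filter_correct_rt()`, `summarize_sst()`, `estimate_ssrt()`); MEP/EMG
processing (`extract_mep()`, `apply_emg_exclusion()`,
`label_hand_status()`); and Bayesian mixed-model contrasts summarised with
the probability of direction, 89% highest-density intervals and an
HDI+ROPE decision rule (`fit_model()`, `contrast()`,
`summarize_contrast()`). `run_pipeline()` chains all stages behind a
manifest.

## The generative behavioural model

Behaviour follows an independent race. On every trial a *bimanual
finishing time* is drawn from a shifted lognormal,

$$T = \delta + \exp(Z), \qquad Z \sim \mathcal{N}(\mu, \sigma^2),$$

with each hand's press equal to $T$ plus independent Gaussian synchrony
jitter. On stop trials a stop process of fixed subject-level latency
(SSRT) races the cued hand: the hand is cancelled iff its finishing time
exceeds SSD + SSRT. The SSD staircases 1-up/1-down in 50 ms steps from
200 ms with a 50 ms floor, independently per hand and condition, which
drives the probability of responding on stop trials to ~0.5.

Key defaults (all settable via `cohort_config()`):

* **Go finishing times**: shift $\delta$ = 150 ms; reactive mean 430 ms.
  The marginal SD of 89 ms is split into 84 ms within-subject and 30 ms
  between-subject spread ($\sqrt{84^2 + 30^2} \approx 89$). The generator
  uses the same distributional family as the RT analysis model, so
  parameter recovery is well-posed by construction.
* **Proactive slowing**: +17 ms on go finishing times under informative
  cues (the strategic cost of holding back the cued hand).
* **Stop latency**: 268 ms (reactive) and 278 ms (proactive), between-
  subject SD 15 ms, deterministic within subject by default
  (`ssrt_trial_sd` adds optional trial-level variability). A deterministic
  stop process gives the integration-method estimator a clean recovery
  target.
* **Synchrony jitter**: SD 18 ms per hand. Press asynchrony then has SD
  $18\sqrt{2} \approx 25$ ms, so about 5% of go trials cross the 50 ms
  asynchrony threshold; together with a 2% incomplete-press rate this
  reproduces the ~7% go error rate typical of the task. Omissions occur at
  0.3%.
* **Stopping interference**: on successful stops the continuing hand's
  response is *re-initiated* — a fresh finishing-time draw — multiplied by
  `interference_mult` (defaults 1.22 reactive, 1.16 proactive, i.e. about
  one fifth less interference under proactive cues and ~19% elongation
  overall).

The re-initiation choice deserves its own paragraph. Had we multiplied the
*same* coupled finishing time that lost the race, conditioning on a
successful stop (the stopping hand being slow) would select slow bimanual
draws, inflating the observed elongation to roughly twice the planted
multiplier, and the continuing response measured from the stop signal
could never be faster than a go response. Empirically the opposite holds:
continuing-hand responses are faster relative to the stop signal than go
responses are relative to the IS, which is naturally produced when the
stop signal acts as a fresh imperative for a re-planned unimanual
response. The multiplicative delay then expresses the cost of uncoupling
the bimanual program.

Edge rules: responses completed before the stop signal appears are
premature responses (counted as responses by the staircase); "stopped
wrong hand" lapses count as responses (configurable); stop trials with no
response at all leave the staircase unchanged (neither success nor failure
is evidenced). Staircases start at the first stop trial of a condition, so
practice blocks warm them toward equilibrium before the main blocks. The
"Respond quicker" feedback threshold is the go-only-block mean RT +
250 ms; such trials remain correct go trials, the flag lives in the
feedback label.

## The generative MEP model

Each TMS trial yields Gamma-distributed MEP amplitudes with shape 4 (CV
0.5) and a mean determined by the trial's *hand status* — the level the
neurophysiological models use as their HAND factor: `WS_baseline`,
`IS_unknown` (reactive), `IS_maybe_stopping` / `IS_definitely_going`
(proactive, cued vs uncued hand), `IS150`, and `SS150_continuing` /
`SS150_stopping`. Unconditioned (CSE) means default to 2.15 mV at WS,
with preparatory suppression at IS (1.63–1.86 mV) and facilitation after
the stop signal (2.13 / 2.01 mV). Conditioned (SIHI/LIHI) trials multiply
the cell mean by a planted conditioned/unconditioned ratio (< 1 inhibitory):
SIHI ~0.69–0.74 throughout; LIHI 0.73 at baseline, partially released
during preparation (0.87–0.92), and released past unity in the continuing
hand after the stop signal (1.12 vs 0.87 at IS — a 29% release, the
package's planted cancellation effect). Subjects scale all MEP means by a
lognormal factor (SD 0.35) and their IHI ratios by a pathway-level
lognormal factor (SD 0.05). The 50 ms pre-pulse window exceeds the 0.025 mV
RMS exclusion threshold on 2.2% of records.

The generator does *not* emulate physiologically detailed EMG waveforms
(`synth_emg_trace()` builds schematic traces solely to exercise the
peak-to-peak and RMS operators), resting-motor-threshold hunting, or any
CSE-behaviour coupling (stopping success is independent of amplitude, the
null the logistic analysis should recover). Passing recovery tests
therefore show the *pipeline* is unbiased under its own assumptions — not
that real data satisfy them.

## Behavioural processing rules

`filter_correct_rt()` keeps correct go trials and successful stops with
RT > 200 ms (fast-guess filter) and derives the stop-signal-relative RT
`rt - ssd` on stop rows. `summarize_sst()` reports the standard
per-condition task summary (omission and error percentages, go RT,
p(respond|stop), SSD, signal-respond RT, continuing-hand RT) over the main
blocks.

`estimate_ssrt()` implements the integration method with replacement of go
omissions: with $p$ the probability of responding on the hand's stop
trials (failed, premature and wrong-hand stops over all stop trials), the
estimate is the $\lceil p N \rceil$-th smallest go RT minus the mean SSD.
The go pool is hand-specific (that hand's press on synchronous go trials);
omissions enter as copies of the slowest observed go RT; asynchronous and
incomplete trials stay out of the pool (a press occurred, so nothing is
replaced). The ceiling quantile convention is the common integration-method
choice; interpolation variants shift estimates by well under the staircase
step. Estimates are refused — never silently fabricated — when $p$ leaves
`[0.25, 0.75]` or the mean signal-respond RT exceeds the mean go RT
(race-model violation); every subject × condition × hand cell yields
exactly one row with a validity flag.

## Neurophysiological processing rules

`extract_mep()` takes the max-minus-min of the trace in the (10, 100] ms
window after the test pulse and the RMS over the [-50, 0) ms window before
it, sample-aligned at 2,000 Hz (window endpoints are half-open so a sample
exactly at the pulse or at +10 ms is excluded; a record with RMS exactly
0.025 mV is retained — the exclusion is strict). The pathway-to-hand
mapping is fixed: left-to-right pathways condition the left hand's test
response, right-to-left the right hand's; dual-coil CSE trials yield two
records sharing a trial id. Stop-trial CSE records at IS/IS150 exist for
the stopping-success logistic model only and never enter the Gamma IHI
models.

## Bayesian models and posterior indices

Four families cover the analyses: shifted-lognormal (trial-level RTs),
Gaussian (averaged SSRT), Gamma with log link (MEP amplitudes), Bernoulli
with logit link (stopping success). Fixed effects use cell-means coding —
one population-level mean per factor-level combination — so every reported
effect is an explicit contrast between named cells, and for log-link
models `exp` of a contrast is a ratio of means (for LIHI, a ratio of
conditioned/unconditioned ratios; no per-subject aggregation is ever
needed).

Sampling is delegated to JAGS (one seeded chain per requested chain;
reproducible for fixed data, seed and JAGS version). Population-level
priors are effectively flat (normal, precision $10^{-6}$); precisions get
vague conjugate Gamma(10^-3^, 10^-3^) priors, which JAGS updates by exact
Gibbs steps. Random effects are by-participant intercepts under a hard
sum-to-zero constraint: with flat cell-mean priors an unconstrained
intercept set leaves a common location ridge that chains wander along
(split Rhat in the thousands in our profiling), while the constrained
parameterisation is fully likelihood-identified and mixes in seconds. We
deliberately stop the random-effects ladder there: by-participant slopes
with correlations are not supportable by the reduced cohorts the package
targets, and every fit reports split-chain Rhat with a structured warning
at the conventional 1.1 threshold. The default layout is 8 chains × 1500
warmup + 1500 kept draws (12,000 post-warmup draws); the smoke profile
uses 2 chains × 600.

For the shifted-lognormal family the shift is a fixed, known constant
(default 150 ms, matching the generator) and the model is Gaussian in
$\log(\mathrm{RT} - \delta)$; contrasts are formed on implied
response-scale cell means $\delta + \exp(\mu_k + \sigma^2/2)$ so percent
changes refer to mean RTs including the shift. Fitting a lognormal to the
re-initiated stop-hand RTs is formally misspecified (a shifted-lognormal
times a constant is not shifted-lognormal), but the moment-matching error
is below 0.1 percentage points at the planted effect size.

`summarize_contrast()` computes, from raw draws: the median; the 89% HDI
as the exhaustively shortest contiguous window of the sorted draws
containing $\lceil 0.89 n \rceil$ of them (ties resolved to the lowest
window; at least 100 draws are required); the probability of direction
(percentage of draws on the median's side of the scale's null — 0 for
differences, 1 for ratios); the percentage of HDI draws inside the region
of practical equivalence (draw-based, not interval-length-based — the two
differ for skewed posteriors); and the three-way decision — accept the
null if the HDI lies inside the ROPE, reject if disjoint from it,
undecided otherwise. Default ROPEs: ±5 percentage points on percent-change
scales (ratio 0.95–1.05), ±0.05 log-odds for the logistic model, and for
identity-link (ms) contrasts ±5% of the reference-condition posterior
median response (the reference being the contrast's baseline side),
overridable via `rope =`.

## Problem sizes and runtime choices

The package's test and default profiles are sized so the whole pipeline
runs in minutes on one core: the smoke pipeline uses 4 subjects and 2
chains; the interference-recovery study 6–8 subjects; the LIHI-recovery
study 12 subjects (the posterior SD of the ratio-of-ratios contrast is
~8 percentage points at that size, comfortably inside the planted effect's
uncertainty band); staircase and SSRT calibration use the full 27-subject
design. All seeds fan out deterministically from one master seed (derived
sub-seeds stay within R's 32-bit integer range), and `run_pipeline()`
records config, seeds, timings, convergence flags and file digests in
`manifest.json`.

## Known limitations

* The generator shares its distributional families with the analysis
  models; real data bring trigger failures, RT drift, within-subject SSRT
  variability and EMG artifacts that are out of scope here.
* SSRT estimation is nonparametric only; parametric (e.g. ex-Gaussian
  race) estimators are not provided.
* Random slopes and their correlations are not sampled (see above); with
  large cohorts and informative priors a fuller structure would be
  preferable.
* Condition order is a flag, not a counterbalancing scheme; cohort-level
  counterbalancing is the caller's responsibility.
* The stopping-success analysis assumes amplitude-independent success in
  the generator; planted couplings can be studied by regenerating MEPs
  with a custom dependence, but no built-in hook is provided.
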