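---
title: "Methods: the racestop simulation and estimation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the racestop simulation and estimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racestop)
```

## The task and the model

The package implements the full methods pipeline of a picture-word
interference stop-signal experiment. On every trial a target picture is
named aloud while a written distractor word — semantically related or
unrelated to the picture — must be ignored; on a quarter of trials a visual
stop-signal follows picture onset after a fixed stop-signal delay (SSD) of
250 or 325 ms and the naming response must be withheld. The response window
is 1250 ms: a go process finishing later produces no observable response.

Stopping behaviour is modelled by the independent horse-race model. A go
process with finishing time $T_{go}$ races a stop process with finishing
time $T_{stop}$ started at the SSD $d$; the response is emitted iff
$T_{go} < d + T_{stop}$. Two assumptions are hard-wired and not exposed as
parameters: *context independence* (the go finishing-time distribution is
unaffected by stop-signal presentation) and *stochastic independence* of
the two finishing times. Both latencies are ex-Gaussian
($\mathcal{N}(\mu,\sigma) + \mathrm{Exp}(\tau)$), the standard positively
skewed shape for response times; setting $\sigma=\tau=0$ gives the
constant-latency mode used by the analytic tests, where
$P(\text{respond}\mid d) = F_{go}(d + s)$ exactly for constant stop
latency $s$.

Omissions, wrong picture names and disfluencies are applied *after* the
race as independent Bernoulli contamination, because the analysis treats
them purely as exclusion categories. One modelling choice deserves note:
omission is a property of the go process, so it applies on stop trials
too — an omitted go response cannot escape inhibition — which deflates
$p(\text{respond}\mid\text{signal})$ by the omission rate (~0.6%),
negligibly. A go finish that beats the stop process but exceeds the
response window is unobservable and therefore scored as a successful stop.

## Estimating the stop-signal RT

With fixed delays the SSRT is estimated by the **integration method**. Per
participant, SSD and distractor condition: the correct go-trial RTs of the
*matching condition* are rank ordered; with $N$ go RTs and response
probability $p$ in the stop-trial cell, the stop process's finishing time
is read off as the $n$th go RT and

$$\mathrm{SSRT} = \text{$n$th go RT} - \mathrm{SSD}, \qquad
  n = \mathrm{round}(N\,p)\ \text{(half up, clamped to } [1, N]).$$

The non-integer rank case is undefined in classic descriptions; round half
up with clamping is this package's declared convention, tested by
enumeration. $p = 0$ leaves the stop finishing time unidentified; such
cells propagate as flagged missing estimates and are excluded listwise
from group summaries. Whether published applications used trimmed go RTs
or imputed missed responses at the window maximum is typically unstated;
the default here is untrimmed and unimputed, with both alternatives
exposed as flags (`trim`, `impute_misses`) on `estimate_table()`.

The **mean method**, $\overline{\text{go RT}} - \overline{\mathrm{SSD}}$,
is provided for one-up/one-down tracking data (`simulate_tracking()`, 50 ms
steps, floored at 0). It deserves a warning that the package's own tests
document: the staircase converges where $P(T_{go} < d + s) = 1/2$, so the
mean SSD tracks $\mathrm{median}(T_{go}) - s$ and the estimate overshoots
a constant stop latency $s$ by $\mathrm{mean} - \mathrm{median}$ of the go
distribution — about 22 ms for the calibrated skewed defaults, zero only
for symmetric go distributions. This bias is the standard argument for the
integration method with fixed delays.

## The constrained design

The schedule builder reproduces the published structure exactly: 4 blocks
of 80 trials; each block contains all 40 pictures once per distractor
condition, with 60 go and 20 stop trials (10 per condition, 10 per SSD);
across blocks every picture-by-condition cell is a stop trial exactly
once, at the SSD fixed by a counterbalance assignment that splits the
pictures 20/20 between the delays (two complementary assignments alternate
across participants). Within a delay group the 20 pictures are split into
four random subgroups of five; subgroup $i$ supplies block $i$'s related
stop trials and block $i{+}1$'s unrelated stop trials, which satisfies all
marginal counts and never makes a picture a stop trial twice in a block.

Within-block order obeys three adjacency rules: no more than four
consecutive trials of the same distractor condition (interpreted as the
related/unrelated factor, not go/stop — the source describes it in the
distractor context), no consecutive target pictures from the same semantic
category, and no consecutive picture names sharing the onset phoneme.
Whether the run-length cap also applied to trial type or SSD is unstated;
only the distractor reading is implemented.

The original pseudorandomization used the external Mix program, whose
algorithm is unpublished. Plain rejection sampling (reshuffle until valid)
reproduces the constraint set but its measured acceptance rate on the
packaged 40-item set is about 1 in 2000 shuffles, so a 10,000-attempt
budget fails for roughly 1 block in 120 — routine at cohort scale. The
implementation therefore draws orders by *constrained sequential
sampling*: positions are filled left to right, choosing uniformly among
the not-yet-placed trials that do not violate a constraint against the
previous trial, restarting from scratch on a dead end (each restart counts
against `max_attempts`, and exhausting the budget is an explicit error,
never a silent relaxation). Every returned order is re-verified against
the full constraint set, and `validate_design()` serves as the independent
oracle in the tests. The sampled distribution over valid orders is not
exactly uniform — irrelevant here, since order never enters the analyses.

## The synthetic cohort and its calibration

`generate_cohort()` is a stated world, not a fitting device. Its defaults
were fixed once, by solving for the ex-Gaussian locations that make the
*observable* summaries match published group anchors, and have not been
revisited since:

- go process: $\sigma = 55$, $\tau = 95$ ms; $\mu = 615$ (unrelated) and
  $630$ ms (related, the injected +15 ms semantic interference shift).
  These values make the post-classification, post-2.5 SD-trim mean naming
  latencies land at ~700/715 ms (trimming a skewed distribution lowers the
  raw mean of 710/725 by ~10 ms, which the calibration accounts for).
- stop process: $\sigma = 20$, $\tau = 30$ ms; $\mu = 335$ (unrelated) and
  $355$ ms (related, the injected +20 ms stop shift), i.e. mean stop
  latencies of 365/385 ms. These put the overall failed-inhibition rate at
  ~34% across the two delays, between the published per-delay rates.
- contamination: 0.6% omissions, 2% wrong names, 0.8% disfluencies
  (errors = wrong names or disfluencies, jointly ~2.8%).
- between-participant variability: normal offsets on the go and stop
  $\mu$ (SD 40 and 25 ms), applied equally to both conditions so the
  injected within-subject shifts are preserved. The magnitudes are package
  choices sized to make permutation inference meaningful at $n = 36$ and
  to reproduce published between-participant SDs (~110 ms for go RT).

Ground truth for every recovery test is the injected parameter set,
written to a `ground_truth.json` sidecar — never the published empirical
cells, whose raw data are not available. A green recovery test therefore
establishes that the pipeline recovers known parameters from data the
model itself generated: it validates the estimator and the code path, not
the empirical adequacy of the ex-Gaussian race for human speakers, and it
cannot detect violations real data might show (context dependence,
strategic slowing, trigger failures, RT drifts over blocks).

## Inference

Published analyses of this design use mixed-effects models; this package
deliberately substitutes repository-native inference. `paired_permutation()`
tests a mean within-participant difference by random sign flips of the
differences with add-one smoothing, $p = (\#\{|T^*| \ge |T|\} + 1)/(B+1)$;
an exhaustive mode enumerates all $2^n$ sign patterns, where the identity
pattern makes $p = \#/2^n$ exact without smoothing. Ties are compared with
a relative tolerance of $10^{-12}$ so sign-symmetric statistics count as
hits. `factorial_permutation()` handles the 2 (SSD) x 2 (condition) table:
main effects as marginal paired contrasts, the interaction as the
per-participant double difference, each tested by sign flip. Type-I
calibration at the nominal 5% level is part of the test suite.

## Numerical conventions and degenerate inputs

- SD trimming uses the sample SD ($n-1$), bounds computed once from the
  full input per participant and condition, collapsed over blocks
  (single pass, non-iterative); values exactly on a bound are retained;
  fewer than two values pass through with a warning flag; $k = \infty$
  is the identity.
- RTs are recorded to 0.1 ms; CSV logs are byte-identical for equal seeds.
- Empty estimate cells and $p = 0$ cells are flagged (`flag = TRUE`) and
  excluded listwise from group aggregation, never imputed as zero.
- All randomness flows through explicit integer seeds; cohort generation
  derives per-participant design and simulation seeds from the master
  seed, all below $2^{31}$.

## Known limitations

No trigger-failure or parametric (ex-Gaussian deconvolution) SSRT
estimators; no dependence parameter between the racers; disfluency
detection on real recordings (manual/acoustic coding) is out of scope —
trial logs must carry explicit boolean columns. The mean-method skew bias
described above is inherent to that estimator, not corrected for.
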