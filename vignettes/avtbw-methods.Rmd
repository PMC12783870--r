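---
title: "Models and methods behind avtbw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind avtbw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avtbw)
library(dplyr)
```

This vignette documents the models the package fits, the synthetic
observer it simulates, and the numerical and design choices made where
more than one defensible option existed.

## The simultaneity-judgement task and its data

An observer watches paired audio-visual streams whose onsets are offset
by a stimulus onset asynchrony (SOA), negative when the auditory stream
leads (AL) and positive when the visual stream leads (VL), and rates each
trial on a 5-point scale: 1 = certainly synchronous, 2 = probably
synchronous, 3 = not sure, 4 = probably asynchronous, 5 = certainly
asynchronous. Ratings 1–2 are coded synchronous, 4–5 asynchronous, and 3
is removed: it expresses uncertainty, not a judgement, so it contributes
neither to the numerator nor the denominator of the per-SOA proportion of
synchronous responses. (Whether "not sure" trials should instead stay in
the denominator is a genuine fork; removing them is the reading most
consistent with treating the option as uninformative, and it is what
`sj_proportions()` implements. Cells in which every trial was "not sure"
become missing points, which the fitters simply skip — they are never
imputed.)

## The two psychometric models

**Gaussian simultaneity curve.** Per subject and condition the per-SOA
proportions are fitted by

$$y = a\,e^{-\left((x-b)/c\right)^2},$$

with $a \in [0.01, 1]$, $b$ free, $c \ge 1$ ms. The upper bound on $a$
exists because $y$ is a proportion; the small lower bounds on $a$ and $c$
only exclude degenerate spikes and flat lines. $b$ is the point of
subjective simultaneity (PSS) and $c$ is reported as the temporal binding
window (TBW). Two caveats are worth stating plainly. First, the exponent
carries no factor of 2, so $c$ is **not** a standard deviation in the
conventional Gaussian parameterization; it is the offset at which the
curve falls to $a/e$. The package implements and reports this form
verbatim, because the TBW it estimates is defined by it. Second, a TBW is
only interpretable when the fit is adequate, which is what the exclusion
rule below enforces.

**Side-split logistic.** The same proportions, restricted to one side of
the axis (SOA 0 belongs to both sides), are fitted by

$$y = \frac{1}{1 + e^{b(t-x)}},$$

with the slope bounded to $[0, 1]$ on the AL side and $[-1, 0]$ on the VL
side, and $t$ unconstrained. At $x = t$ the model value is exactly 0.5
for any slope, so $t$ is the inflection point of the curve — despite the
"75% threshold" label this parameter sometimes carries in the SJ
literature, no 75% criterion enters the formula, and the package
documents $t$ as the inflection parameter. Because VL slopes and AL
inflections are negative by construction, reported `b_slope` and
`t_threshold` are absolute values; the raw signed estimates are kept
alongside.

**Goodness of fit and exclusion.** Fit quality is the Wherry adjusted
R²,

$$\bar R^2 = 1 - (1 - R^2)\,\frac{n-1}{n-p-1},$$

with $n$ the number of defined SOA points and $p = 3$ (Gaussian) or 2
(logistic). A subject × condition row is excluded from Gaussian-derived
analyses when the Gaussian fit failed to converge or $\bar R^2 < .5$, and
from logistic-derived analyses when either side fails its fit or falls
below $\bar R^2 = .3$. The inequalities are strict: a fit at exactly the
threshold is kept. Curves with zero variance have undefined R²; the
resulting `NaN` is treated as "not kept". Convergence failures are
recorded and routed into exclusion rather than raised, so a cohort run
never aborts on one pathological subject.

## Numerical strategy for the bounded fits

Both models are fitted by bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) with multiple starts. The deterministic starts use
the data: $a_0$ = maximum proportion (clipped strictly inside the box,
because a start pinned on a bound stays there), $b_0$ = SOA at the
maximum, $c_0 \in \{150, 300, 450\}$ ms; logistic slope magnitudes
$\{0.01, 0.05\}$ with the side's sign and $t_0$ at the half-maximum SOA.
These alone are not enough: on noisy 11-point curves the residual surface
is genuinely multimodal, and a local optimizer launched into one basin
can converge cleanly to a minimum a few percent worse than the global
one. The fitters therefore also scan a coarse parameter grid spanning the
whole bounded box, greedily select the best few grid points that lie in
*distinct* regions of the box, and launch the optimizer from each. The
lowest objective wins, with ties broken by start order; a run with a
clean convergence code is preferred only when its objective is
essentially tied with the best. The test suite verifies, on seeded
simulated subjects, that the resulting objectives match an independent
dense grid search over the same box to better than $10^{-6}$ relative.

## The synthetic observer

The generator exists so that every stage downstream of data collection is
testable against known ground truth. An observer is four numbers plus a
nuisance parameter: peak synchrony probability `a_peak`, PSS `b_pss`
(ms), width `c_tbw` (ms), lapse rate `unsure_rate`, and
`confident_split`. A trial at SOA $x$ becomes rating 3 with probability
`unsure_rate`; otherwise a Bernoulli draw with probability
$a\,e^{-((x-b)/c)^2}$ decides synchronous vs asynchronous, and
`confident_split` (default 0.75) decides whether the extreme (1/5) or
moderate (2/4) rating is reported. The split is deliberately
inconsequential: ratings 1/2 and 4/5 collapse on recoding, so no analysis
depends on it. This is the *minimal* mechanism whose coded output has
exactly the Gaussian structure the fits assume — the point of the
generator is a clean closed loop, not realism. What it does **not**
emulate: sequential dependencies and adaptation across trials, reaction
times, asymmetric lapse behaviour, drifting attention, or any
rating-scale use strategy beyond the single split. Passing recovery tests
therefore demonstrates that the estimation chain is correct and well
calibrated *under the model's own assumptions*; it does not certify
performance on human data, whose deviations from those assumptions are
exactly what the adjusted-R² gate is meant to catch.

Cohort priors default to `a ~ U(0.85, 1)`, `b ~ N(50, 40)` ms (a mild
visual-leading bias, consistent with simultaneity peaking slightly on the
visual-leading side), `c ~ U(200, 500)` ms (spanning typical group-mean
TBWs for pulsed audio-visual streams), `unsure ~ U(0, 0.15)`. Per-subject
random streams are derived from the master seed so any subset of a cohort
reproduces identically. Ground truth is always returned and serialized
next to the simulated responses.

## Stimuli

**Rhythmic envelopes** are raised cosines, $e(t) = (1 - \cos 2\pi f
t)/2$, chosen so the stream starts and ends at zero amplitude and
contains exactly $f \cdot d$ pulses — which makes pulse-count arithmetic
(3/6/9 pulses in 3 s at 1/2/3 Hz; 3/1.5/1 s for 3 pulses) exact and
testable by counting local maxima. The phase convention matters only for
that exactness; nothing downstream depends on it.

**Quasi-rhythmic (speech-like) envelopes** emulate the syllabic contour
of natural speech: pulse times with Gamma-distributed inter-pulse
intervals at a stated coefficient of variation (default 0.2), pulse
amplitudes likewise varied (CV 0.3), smoothed by a raised-cosine kernel
of width $1/(2f)$ and normalized to peak 1. Two implementation choices
deserve note. Intervals are Gamma rather than truncated-normal so they
are positive by construction with the CV exact. And the drawn intervals
are renormalized so that the pulses span the token's duration: a raw
cumulative sum of jittered intervals drifts like a random walk, audibly
changing the token's overall rate, whereas a 3-s token with nine
syllable-like pulses should keep its ~3 Hz character while its local
intervals vary. Even so, roughly one token in twelve ends up with its
spectral peak outside 3 ± 0.5 Hz — which is precisely why a selection
gate exists: `select_speech_like()` keeps only tokens whose FFT dominant
frequency (mean-removed spectrum, search band [0.5, 10] Hz intersected
with the resolvable range, ties to the lower frequency) falls within the
tolerance. The same gate, applied to recorded speech envelopes extracted
with `extract_envelope()` (full-wave rectification, zero-phase 10 Hz
Butterworth low-pass, rescaled to [0, 1]), selects usable natural tokens.

**SOA-shifted pairs** delay the lagging stream by $|SOA|$ and zero-pad
both tracks to equal length — a physical delayed onset, not a circular
shift — so each track's energy is conserved and total duration is stream
duration plus $|SOA|$.

## Validation problem sizes

The shipped tests and the acceptance script validate at sizes chosen to
give tight Monte-Carlo bounds while remaining quick on a laptop: lapse
and proportion checks at ~10,000 trials (3 binomial SEs), fit-vs-grid
equivalence on 20 simulated subjects (grids of ~10⁵–10⁶ points),
parameter recovery on 200 subjects per repetition level (5/20/80
repetitions per cell), the spectral gate on 200–1000 generated tokens,
and cohort pipelines of 12–20 subjects. Recovery under the canonical
5-repetition design runs at a median relative TBW error around 10% with
no detectable cohort-level bias, improving to ~5% and ~3% at 20 and 80
repetitions.

## Known limitations

- The trial count printed for a two-condition design with five speech
  tokens is ambiguous in parts of the SJ literature (165 vs 110 trials);
  `build_design()` therefore never hard-codes a total — it emits exactly
  `|soas| × |conditions| × n_reps` trials and the presets state their
  conditions explicitly.
- Proportions are fitted by unweighted least squares; cells with few
  valid trials count as much as full cells. `n_valid` is carried through
  the outputs so a weighted variant could be added without schema
  changes.
- The package stops at tidy per-subject parameter tables and
  per-condition summaries; inferential statistics (ANOVAs, post-hoc
  tests) are left to dedicated tools on the emitted tables.
- Only an abstract amplitude channel is modelled. Whether a visual
  stream's size modulation is linear in radius or area, carrier
  rendering, and display timing are outside scope (a WAV-ready 500 Hz
  carrier convention is assumed for audio rendering of envelopes).
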