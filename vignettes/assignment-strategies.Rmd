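---
title: "Syllable-to-target assignment: models, metrics and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syllable-to-target assignment: models, metrics and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(songmatch)
```

## The learning problem

A juvenile songbird switched from a mastered source song to an altered
target must adapt both the spectral structure of its syllables and their
order. Writing $m_1 \dots m_n$ for the motor syllables (with pitches $p_i$
in semitones, for harmonic syllables) and $t_1 \dots t_k$ for the target
syllables (pitches $q_j$), a candidate plan is an injective assignment
$\pi$. Its cost decomposes into a spectral term and a sequence term,

$$C(\pi) = \sum_i |p_i - q_{\pi(i)}| \;+\; \lambda\, S(\pi),$$

where $S(\pi)$ counts the target transitions (bigrams, including the motif
wrap) that are not yet performed when the motor syllables are relabelled by
their assigned targets in source order. Because $S$ couples the assignments
of different syllables, minimizing $C$ is a quadratic assignment problem;
dropping $S$ ($\lambda = 0$) leaves a linear assignment problem (LAP). The
package implements the exact LAP (`solve_lap()`, via `clue`, with an
exhaustive enumerator `solve_lap_bruteforce()` as a testing oracle), an
exhaustive minimizer of the combined cost for small motifs
(`qap_minimize()`, at most 8 targets — the scientific point is that
learners *avoid* this computation, so no general QAP solver is warranted),
and three behavioural strategies (`strategy_predict()`):

* **global** — match by motif position, minimizing rearrangements at the
  price of possibly large spectral work;
* **greedy** — the winner-take-all competitive rule below;
* **chunk** — source bigrams matched to target bigrams by summed spectral
  cost, a local compromise between the two.

### The greedy-competitive ("musical chairs") rule

`musical_chairs()` iterates: each motif syllable selects its spectrally
nearest unoccupied target; conflicts are resolved in favour of the nearer
syllable, losers reselect; occupied targets leave the game; and targets
still vacant after all motif syllables settle recruit the nearest available
call. The result is always injective and target-complete when enough
precursors exist, and its spectral cost is bounded below by the LAP
optimum. Exact ties (within $10^{-9}$ st — measure-zero under pitch jitter,
reachable only in idealized geometries) are broken uniformly at random
under `tie_seed`. Whether the competitive exclusion acts at selection time
or only once a winner has converged is not decidable from behaviour alone;
both variants are implemented (`compete = "selection"`/`"convergence"`) and
produce the same static mapping, differing only in the logged event order.
The default is selection-time exclusion.

### The EM formulation

Viewing every rendition of a target syllable as a data point and every
motor precursor as a 1-D Gaussian component initialized at its own pitch,
greedy-competitive matching corresponds to a *staged* mixture fit
(`em_match_targets()`):

1. components enter in the order the biology dictates — motif syllables
   first, calls after a recruitment lag;
2. each entering component runs fixed-variance EM (mean-shift mode seeking
   with a kernel at the pitch-jitter scale, default bandwidth 0.5 st) on
   the renditions not yet claimed, so its basin of attraction is exactly
   "the nearest remaining mode";
3. renditions within the occupancy radius $\varepsilon$ (default 1.5 st) of
   a converged component are claimed — the occupied chair leaves the game;
4. a plain joint EM (`em_fit()`) polishes all components, and each maps to
   the target pitch nearest its mean (`assign_by_responsibility()`).

A plain joint EM initialized at the precursor pitches is *not* equivalent:
it has no notion of temporal priority, so when a call originates on the
same side as the motif syllable's nearest target the call component can
capture that mode first, which the staged fit (like the behaviour) forbids.
The staging — not the E/M updates — carries the competitive constraint.
`em_fit()` itself is a standard EM with a variance floor
(default $10^{-4}$ st², tolerance $10^{-8}$, at most 500 iterations) whose
log-likelihood trace is asserted monotone in the tests and cross-checked
against `mclust` on fixtures.

## The synthetic study conditions

No recordings are deposited for this paradigm, so all inputs are generated
with known ground truth. The generator's defaults are the study conditions
and are not tuned per experiment:

| parameter | default | rationale |
|---|---|---|
| pitch mismatches | 1–2 st | the tutoring designs use 1 or 2 semitones |
| rendition pitch jitter | 0.25 st (Gaussian in semitone space) | typical rendition-to-rendition variability of harmonic syllables |
| motif renditions/day | 60 | real birds sing far more; 60 keeps runs fast while holding daily binomial error on transition frequencies near ±6% |
| motifs/playback (bout) | 2 | playbacks present two motif renditions |
| within-bout stops | 40–80 ms | safely below the bout threshold |
| bout threshold | 175 ms (150–200 configurable) | typical stop duration in crystallized song |
| calls | one, at −3.5 st | a repertoire call available for recruitment; cohort experiments redraw call origins |
| sample rate | 32 kHz | Nyquist comfortably above the 8th partial of the highest fundamentals |

Harmonic syllables are synthesized as harmonic stacks (8 partials, rolloff
0.75, 5 ms raised-cosine ramps, RMS-normalized); calls add a 20 ms noisy
onset, which the pitch tracker flags aperiodic and the median-pitch rule
discards. Non-harmonic syllables are fixed band-limited noise tokens —
distinguishable by spectrogram template but carrying no phonological
structure of their own. That is a deliberate non-goal: the tasks' mismatches
are pitch-only, so nothing downstream depends on non-harmonic phonology.
Consequently, passing round-trip tests show that the measurement chain
recovers *programmed pitch and syntax* trajectories; they do not exercise
frequency-modulated or broadband phonology, amplitude variation, or
recording noise, all of which real data have.

## The measurement chain

Pitch is tracked once per millisecond (25 ms analysis window, 300–4000 Hz
search band) with the cumulative-mean-normalized difference function and
parabolic lag interpolation (`yin_f0()`); frames whose normalized minimum
exceeds 0.2 are unvoiced. On synthetic stacks the tracker's median error is
well under 0.01 st, so the 0.1 st round-trip tolerance is dominated by
sampling, not tracking. A rendition's pitch is the median over its voiced
frames after dropping the leading contiguous aperiodic run (the operational
reading of "initial noisy segments" — the duration is data-driven, not a
fixed bound). Segmentation thresholds short-time power 35 dB below the
recording peak (merging gaps < 5 ms, discarding runs < 20 ms); with
generated data the pipeline can bypass segmentation and use the annotation
boundaries — both paths are tested. Typing uses 70 ms log-power spectrogram
segments centered on the rendition midpoint and a k-nearest-neighbour vote
(k = 5, Euclidean distance on dB-scaled matrices, ties by smaller mean
distance then label order); spectrally close variants lumped by the
classifier are resolved by sequential context (`refine_by_context()`), with
a nearest-pitch fallback for renditions matching neither context. Templates
are seeded from ground truth on synthetic data; a CSV/JSON store lets users
curate templates for real recordings.

## Trajectory metrics

The fraction of pitch correction is $(p - p_{src})/(p_{tgt} - p_{src})$,
with day values taken as medians over that day's renditions. Fractions are
deliberately *unclamped* — birds overshoot and sometimes move away from the
target — with clamping available as an option. Syntax correction follows
the converging/diverging rule: the daily fraction of focal renditions whose
predecessor (successor) matches the target context, averaged into an
overall fraction. Bout-edge renditions have no predecessor (successor) and
are excluded from the respective fraction — an undefined day is reported
absent, never zero. Within a bout, repeated motifs make the wrap transition
an ordinary adjacency. The signed shift scale resolves each focal
rendition's identity by pitch (nearest declared variant) and scores +1 in
declared-correct, −1 in declared-incorrect transitions, so an unchanged
source song scores 0 and a pitch-shifted syllable sung in its old context
scores negative. Binned curves use 30-sample windows with 25-sample
overlap; the pitch-versus-syntax summary averages syntax correction over
windows whose pitch correction lies in 45–55%. Cohort percentages round
half away from zero (20/26 → 77%, 4/26 → 15%), and the recruitment null
model is $0.5^n$ — the chance that every bird's call lands on the vacant
rather than the occupied target if origins were random and uncompetitive.
Whether published binned syntax curves use the overall mean or a single
transition is ambiguous; this package uses the overall mean everywhere,
and its choice to exclude bout-edge renditions is likewise a documented
reading rather than a stated rule.

## The developmental simulator

`simulate_learning()` fixes the assignment on day 0 by the chosen strategy
and then evolves: pitch approaches its assigned target exponentially
(`pitch_rate`, default 0.2/day — chosen over constant-step drift because it
produces the smooth saturating daily-median trajectories seen in
developmental data), with day-level wobble (0.05 st) on top of rendition
jitter; recruited calls hold their origin pitch for `recruitment_lag`
(5 days) before drifting; and missing target transitions are acquired
sequentially — one at a time, each with per-day probability
`p_transition_acquire` (0.05) — entering the grammar at a usage that ramps
(time constant 5 days) and saturates at `usage_max` (0.9), so acquired
transitions are performed *in combination with* the persisting source
transitions and endpoint syntax match is typically partial. These dynamics
are the package's own minimal parameterization of qualitatively described
behaviour; rates are exposed, and none is fitted to data. Age-dependent
plasticity decline is omitted (endpoint syntax match does not correlate
with switch age in the paradigm). `batch_simulate()` runs independent
birds; `cohort_target_choice()` perturbs each bird's baseline pitches
(0.25 st) before the competition, mirroring the across-bird variation of
the tutoring designs.

Sequence cost counts unacquired target bigrams rather than edit distance
because syntax learning proceeds by acquiring individual transitions;
relabelling the source motif `A B C` under the identity-order mapping for
the permutation task leaves all three target bigrams unacquired, which the
enumeration oracle in the tests confirms.

## Numerical choices and degenerate inputs

Semitone arithmetic refuses non-positive frequencies. Wiener entropy is
clamped at −12 for line spectra and undefined (with a warning) for all-zero
spectra; digital silence yields no segments; an all-aperiodic rendition has
no median pitch; a day without focal renditions is absent from syntax
series; `binned_starts(n)` returns zero windows for $n <$ bin, matching
$\lfloor (n-\text{bin})/(\text{bin}-\text{overlap}) \rfloor + 1$ otherwise
(verified exhaustively for $n \le 200$). LAP ties are canonicalized to the
lexicographically smallest optimal mapping so solver and oracle compare
deterministically. Components that lose all responsibility mass in EM are
clamped at the variance floor and flagged rather than removed. All
stochastic entry points take explicit seeds and restore the caller's RNG
state.

## Problem sizes

Tests and the acceptance script run at desk scale, chosen once: 200 random
cost matrices up to 7×7 against the brute-force oracle; EM recovery at
n = 200 samples per fit over 20 seeds; 200 tie seeds / 100-bird cohorts for
the strategy signatures; and one 5-day × 60-rendition audio round trip
(≈ 90 s of synthetic song) through the full measurement chain.

## Known limitations

* Phonology is one-dimensional (pitch); spectral shape beyond the harmonic
  stack is not modelled, and non-harmonic syllables cannot be targets of
  spectral error.
* The early developmental regime in which proto-syllables duplicate and
  split toward multiple targets is outside the model's scope; the
  competitive rule is only claimed for the serial-tutoring stage.
* The staged-EM correspondence is a reconstruction of a qualitative
  analogy; its agreement with the competitive rule is reported (and
  asserted ≥ 90% on well-separated geometries) rather than derived.
* Simulator rates are plausible defaults, not fits; real inter-bout
  statistics, rendition counts and noise magnitudes differ across birds.
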