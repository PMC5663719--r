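# songmatch

Tools for studying how juvenile zebra finches decide *which of their own
syllables should become which syllable of a new target song*.

## The problem

In serial-tutoring experiments a juvenile first masters a synthetic source
song (e.g. the motif `A B C`) and is then switched to a target that differs
in both **phonology** (the pitch of one or two harmonic syllables is shifted
by 1–2 semitones) and **syntax** (the syllable order is permuted or a
syllable is duplicated), e.g. `A B C → A C⁺ B`. Matching the target requires
assigning each motor syllable to a target syllable. Jointly minimizing the
spectral cost (semitone distance of matched pairs) and the sequence cost
(target transitions that must be newly acquired) is a **quadratic assignment
problem** — computationally intractable in general. Minimizing the spectral
term alone is a **linear assignment problem (LAP)**,

```
minimize  Σᵢ |pitch(motorᵢ) − pitch(target_π(i))|   over injective π,
```

and the package's central model is that learners approximate the LAP with a
*greedy-competitive* ("musical chairs") rule rather than solving anything
globally:

1. every motif syllable selects its spectrally **nearest** unoccupied target
   (winner-take-all; exact ties break at random);
2. if two syllables want one target, the nearer wins and the loser
   reselects;
3. an occupied target is out of the game;
4. targets left vacant **recruit** the nearest available call (a
   vocalization performed outside the song motif).

The same dynamics can be written as a staged Gaussian-mixture EM: each motor
syllable is a component initialized at its own pitch that climbs onto the
nearest mode of the target-pitch distribution (fixed-variance EM = mode
seeking), claimed renditions are excluded (the occupancy constraint), calls
enter late (recruitment lag), and a final plain EM refines all components.

Because the original recordings are not deposited, the package ships a
synthetic data generator whose defaults emulate the study conditions
(harmonic-stack syllables, per-rendition pitch jitter of 0.25 st, ~60 motif
renditions/day), plus the full measurement chain used on real song:
per-millisecond YIN-style pitch tracking, Wiener entropy, amplitude
segmentation, bout grouping (150–200 ms stop threshold), 70 ms log-power
spectrogram nearest-neighbour typing with context refinement, and the
pitch/syntax error-correction trajectory metrics (fractions of correction,
30-sample bins with 25-sample overlap, endpoint summaries, the ±1 syntax
shift scale, cohort percentages, and the 0.5ⁿ call-recruitment null model).

## Worked example

The two-equidistant-target task (`A B → A B⁺ A B⁻`): syllable B is offered
targets two semitones up and down; a "greedy" learner can only match one of
them, so the other must be recruited from a call.

```r
library(songmatch)
tl <- task_library()
res <- musical_chairs(tl$task3, tie_seed = 1, call_pitches = c(call1 = -3.5))
res
#> <assignment_result musical_chairs/selection>
#>   B -> 1, call1 -> 2
#>   spectral cost 7.5
res$log
#>   step   event motor target distance
#> 1    1  select     B    B-2      2.0
#> 2    2 recruit call1    B+2      5.5
```

Under tie seed 1 the motor syllable B claims the downward target `B-2`; the
call is recruited to the vacant `B+2`. Across tie seeds the two targets are
selected in even proportion. A full developmental run:

```r
demo_task5(seed = 1)
#> assignment: B -> B+2, call1 -> B-2, A -> A
#> recruited calls: call1
#>   bird syllable chosen_target pitch_correction syntax_correction
#> B    1        B           B+2        0.9729319                 1
```

Here the simulated learner's syllable B converged on `B+2`
(97% of the 2-semitone pitch error corrected by the endpoint) while the
recruited call differentiated into `B-2`. Contrast the greedy choice with
the optimum on the close-vs-far task (`A B C B⁺¹ → A B⁺² C B⁻¹`), where the
LAP picks the 1-semitone targets too — greedy and optimal agree whenever
targets are well separated:

```r
solve_lap(assignment_problem(tl$task4.1))
#> <assignment_result lap>
#>   B -> 2, B+1 -> 1
#>   spectral cost 2
```

Trajectory metrics operate on annotated rendition streams (simulated, or
measured from audio via `measure_dataset()` + `classify_renditions()`):

```r
traj <- simulate_learning(tl$task1, "greedy", sim_params(seed = 1))
pitch_vs_syntax_curve(traj$renditions, "C", 0, 2, "A", "B")$summary
#> [1] 0   # syntax untouched while pitch is 45-55% corrected
```

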