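task_id: '5'
source:
  name: t5-source
  reference_freq: 600.0
  motifs_per_playback: 2
  motif:
  - label: A
    kind: nonharmonic
    duration: 80.0
  - label: B
    kind: harmonic
    duration: 100.0
    base_pitch: 0.0
target:
  name: t5-target
  reference_freq: 600.0
  motifs_per_playback: 2
  motif:
  - label: A
    kind: nonharmonic
    duration: 80.0
  - label: B+2
    kind: harmonic
    duration: 100.0
    base_pitch: 2.0
  - label: A
    kind: nonharmonic
    duration: 80.0
  - label: B-2
    kind: harmonic
    duration: 100.0
    base_pitch: -2.0
pitch_mismatches:
- source_label: B
  target_label: B+2
  shift: 2.0
- source_label: B
  target_label: B-2
  shift: -2.0
syntax_mismatch: 'insertion: motif doubled with two B variants'

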