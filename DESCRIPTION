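Package: songmatch
Title: Syllable-to-Target Assignment Strategies in Birdsong Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how juvenile songbirds assign their vocal
    gestures to the syllables of a newly introduced target song. Provides a
    synthetic serial-tutoring data generator (harmonic-stack syllables with
    controlled pitch and syntax mismatches), a per-millisecond pitch tracker
    based on the cumulative-mean-normalized difference function, syllable
    segmentation, bout grouping and nearest-neighbour spectrogram typing,
    pitch and syntax error-correction trajectory metrics, and simulators of
    competing target-assignment strategies: global positional alignment,
    greedy-competitive winner-take-all matching ("musical chairs"), chunk
    alignment, optimal linear assignment, and an expectation-maximization
    Gaussian-mixture formulation of greedy-competitive matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
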