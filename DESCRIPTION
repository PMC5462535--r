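Package: avspeechinfo
Title: Information Dynamics of Audio-Visual Speech Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how band-limited neural activity tracks
    continuous audio-visual speech. Implements Gaussian-copula mutual
    information between stimulus features (acoustic envelope, lip
    trajectory) and neural signals, audio-visual information decomposition
    (conditional mutual information and normalized redundancy),
    speech-conditioned directed information between network nodes over
    brain-lag by speech-lag grids, phase-amplitude coupling, and a
    permutation-based random-effects statistical framework (Freedman-Lane
    condition GLMs, cluster-mass enhancement with max-statistic
    family-wise error control, sign-permutation lateralization contrasts,
    neuro-behavioral correlations, repeated-measures ANOVA with
    Huynh-Feldt correction). Includes a synthetic-data generator producing
    condition-structured stimuli, entrained multi-node signals and
    behavioral scores with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
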