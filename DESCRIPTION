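Package: dyadsync
Title: Dyadic Physiological Synchrony and Shared-Emotion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing interpersonal physiological synchrony in
    dyads watching emotion-eliciting videos. Implements preprocessing of
    cardiac (ECG/inter-beat-interval), respiratory and electrodermal
    recordings, artifact and statistical-outlier screening, wavelet
    transform coherence (Morlet, Grinsted-style smoothing, cone-of-influence
    exclusion) with band-restricted averaging and correlational
    alternatives, surrogate-dyad bootstrap null distributions, dyad-level
    emotion and social-bonding indices (dyadic means, absolute differences,
    mutual products, change scores, neutral-baseline correction), and
    likelihood-ratio-driven backward-stepwise selection of linear
    mixed-effects models. A synthetic dyad generator with a controllable
    inter-member coupling parameter makes the full pipeline testable
    end-to-end without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
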