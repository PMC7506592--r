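Package: erpnat
Title: Simulation and Analysis of P1/N170 Responses to Human- and AI-Framed
    Recommendation Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-related potential (ERP) analysis pipeline for a 2x2
    within-subjects paradigm in which a recommendation agent framed as human
    or AI is judged natural or unnatural. Provides a synthetic multichannel
    EEG generator with known ground truth (Gaussian P1/N170 components at
    the text-specific P7 and face-specific P8 sites, ocular artifacts, bad
    channels, 7-point rating data), response-conditional epoching with a
    timing offset correction, moving-average max-minus-min artifact
    rejection with bad-channel interpolation, baseline correction and
    average re-referencing, adaptive-mean P1/N170 amplitude extraction, and
    the inferential layer: Shapiro-Wilk normality gating, Wilcoxon
    signed-rank (tie-corrected normal approximation and exact enumeration),
    paired t, two-way repeated-measures ANOVA with partial eta squared, and
    Bonferroni-corrected planned contrasts. Reads and writes EDF, tabular
    event files, montage JSON, and CSV amplitude/rating tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
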