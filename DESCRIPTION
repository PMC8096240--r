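Package: cpdcontext
Title: Context-Resolved Mapping of UV-Induced Cyclobutane Pyrimidine Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cyclobutane pyrimidine dimer (CPD)
    formation across all 64 NYYN dipyrimidine contexts in a single designed
    DNA probe. Includes a randomized overlap-merge designer that finds a
    minimal sequence containing each NYYN tetramer exactly once under a
    maximum pyrimidine-run constraint, a simulator of 5'-end-labeled
    cleavage gel lanes under Poisson single-hit kinetics, the matching
    Poisson-corrected band quantification pipeline (3'-side relative
    frequencies, control subtraction, cross-loading normalization,
    replicate averaging), flanking-context analyses (dipyrimidine totals
    and ratios, NYYN heatmaps, pyrimidine-tract statistics, condition
    correlations), and UV dosimetry arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
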