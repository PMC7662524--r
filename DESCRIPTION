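Package: repsamotif
Title: Iterative-Selection Motif Discovery and Binding-Site Dissection
    for Bacterial Transcription Factors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the DNA-binding specificity of bacterial
    transcription factors characterized by in vitro iterative selection
    (REPSA/SELEX-style experiments). Provides a selection-round simulator
    with known ground truth, flank-aware read preparation, palindromic
    ZOOPS expectation-maximization motif discovery with position weight
    matrix algebra, exact dynamic-programming p-values for genome-wide
    motif scanning with Benjamini-Hochberg correction and TSS/operon/
    promoter annotation, global 1:1 Langmuir fitting of biolayer
    interferometry sensorgrams (kon, koff, KD, R squared), and two-group
    differential-expression comparison with operon-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
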