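Package: specseqr
Title: Relative Binding Energy Estimation from Spec-Seq Counts and
    Threshold-Based Regulatory Target Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative protein-DNA binding energies from
    bound/unbound sequencing counts of randomized-core binding-site
    libraries (Spec-seq), fits additive energy position weight matrices
    by anchored least-squares regression on low-mismatch variants,
    normalizes energy-logo matrices, and compares replicate or mutant
    energy tables. A biophysical simulator generates equilibrium
    bound/unbound partitions of a library under a ground-truth additive
    energy model, emits sequencing reads, and plants differential
    binding/expression tables so every stage of the downstream
    transcription-factor target classification (lost peaks, peak-to-TSS
    assignment, dependence classes, developmental correlation) can be
    verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
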