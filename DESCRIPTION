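Package: fetvar
Title: Fisher-Exact-Test Variant Calling, Annotation and Prioritization from Pileup Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single-nucleotide variants and small insertions/deletions
    from samtools-style mpileup input using a one-tailed Fisher exact test
    against a sequencing-error null, in three modes: germline (single sample),
    somatic (paired tumor-normal, with Somatic/LOH/Germline/Unknown
    classification and High/Low confidence), and population (multi-sample
    genotyping with minor allele frequency). Calls are written as VCF v4.1.
    A rule-based annotation engine joins calls against local gene models and
    tab-separated annotation tables (functional-impact scores, clinical and
    drug associations) and assigns High/Medium/Low priority. A read-simulation
    benchmark plants variants in a diploid genome built by concatenation,
    synthesizes truth-placed pileups, and scores calls by sensitivity,
    precision and F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    optparse,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
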