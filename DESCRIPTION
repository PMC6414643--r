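Package: ampedit
Title: Combinatorial A-to-I Editing and Splice Isoform Quantification from
    Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies posttranscriptional processing of the serotonin
    receptor 2C (5-Ht2cr) pre-mRNA from amplicon deep-sequencing reads:
    assigns each read to the full-length or truncated (exon Vb lacking)
    splice isoform, calls the joint A-to-I editing state of eleven exonic
    sites per read, builds RPKM-normalized library-by-pattern matrices,
    and tests genotype differences per pattern and per site with
    Student's t-tests and Benjamini-Hochberg false discovery rate
    correction.  Includes a synthetic amplicon-read generator with
    per-read ground truth emulating a twelve-library, two-genotype
    choroid plexus study design, so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
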