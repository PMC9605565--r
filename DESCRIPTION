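Package: editAftermath
Title: On- and Off-Target Outcome Analysis for CRISPR/Cas9 Genome Editing in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the aftermath of CRISPR/Cas9 editing in
    compact fungal genomes from short-read whole-genome sequencing. Provides
    guide enumeration and filtering within coding-sequence windows,
    identification of long essential-gene-free regions, exhaustive off-target
    binding-site scanning under mismatch and PAM constraints, triage of raw
    variant calls down to candidate de novo mutations, read-support-based
    quantification and classification of on-target repair genotypes
    (including structural variants, microhomology signatures and
    telomere-capped chromosome truncations), and a synthetic-data generator
    emulating pooled-colony paired-end sequencing designs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
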