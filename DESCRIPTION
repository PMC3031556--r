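Package: mreseek
Title: Counting and Enrichment Statistics for miRNA Response Elements in
    Coding Sequences and 3' UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scanning mRNA sequences for miRNA response elements
    (MREs), the 7-nucleotide sites complementary to a miRNA family seed
    (nucleotides 2-8 of the mature miRNA). Transcripts with annotated coding
    sequences are partitioned into 5' UTR, CDS and 3' UTR so that sites can
    be counted per region, the setting where regulatory elements such as the
    miR-29 and miR-15 family sites in elastin and collagen mRNAs occur in the
    coding sequence as well as the 3' UTR. Overrepresentation of a motif in a
    transcript is assessed with a Poisson test whose rate is the number of
    possible start positions times the motif probability under an empirical
    nucleotide background; binomial tail tests quantify overlap of gene sets.
    Companion modules screen expression profiles for miRNA activity
    signatures (rank-sum comparison of predicted targets versus non-targets
    with size-matched random-set controls), normalise and test two-group
    microarray matrices with Benjamini-Hochberg correction, and simulate
    transcript corpora with planted motif counts and expression matrices with
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
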