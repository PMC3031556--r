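# Fixtures built in code: a tiny GenBank flat file, hand-annotated
# corpora, and independent (naive) oracles for the scanning and BH steps.

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive position-by-position sliding-window oracle for motif counting
naive_count <- function(sequence, motif) {
  L <- nchar(sequence)
  if (L < 7) return(integer(0))
  starts <- 1:(L - 6)
  starts[substring(sequence, starts, starts + 6) == motif]
}

# brute-force Benjamini-Hochberg step-up: sort, scale, cummin from largest
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

# hand-built three-record corpus: one with 5'UTR/CDS/3'UTR, one CDS-less,
# one starting at position 1 (empty 5' UTR)
toy_corpus <- function() {
  s1 <- paste0(strrep("A", 50), strrep("C", 300), strrep("G", 150))  # L=500
  s2 <- strrep("ACGT", 30)                                          # L=120
  s3 <- paste0(strrep("G", 60), strrep("T", 40))                    # L=100
  transcript_corpus(gene_id = c("gA", "gB", "gC"),
                    transcript_id = c("NM_1.1", "NM_2.1", "NM_3.1"),
                    sequence = c(s1, s2, s3),
                    cds_start = c(51L, NA, 1L),
                    cds_end = c(350L, NA, 60L))
}

genbank_record <- function(locus, accession, gene, seq, cds = "51..350",
                           with_gene = TRUE) {
  seq_lines <- substring(seq, seq(1, nchar(seq), 60), pmin(seq(1, nchar(seq), 60) + 59, nchar(seq)))
  c(sprintf("LOCUS       %s   %d bp  mRNA  linear  ROD 01-JAN-2010", locus, nchar(seq)),
    sprintf("DEFINITION  synthetic record %s.", locus),
    sprintf("ACCESSION   %s", locus),
    sprintf("VERSION     %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    if (with_gene) c("     gene            1..100",
                     sprintf("                     /gene=\"%s\"", gene)),
    if (!is.null(cds)) c(sprintf("     CDS             %s", cds),
                         "                     /codon_start=1"),
    "ORIGIN",
    paste0("        1 ", tolower(seq_lines[1])),
    if (length(seq_lines) > 1) paste0("       61 ", tolower(seq_lines[-1])),
    "//")
}

write_toy_genbank <- function(path) {
  set.seed(42)
  recs <- c(
    genbank_record("NM_0001", "NM_0001.1", "gA", random_dna(500)),
    genbank_record("NM_0002", "NM_0002.1", "gB", random_dna(200),
                   cds = "join(10..50,80..150)"),
    genbank_record("NM_0003", "NM_0003.1", "gC", random_dna(120), cds = NULL),
    genbank_record("NM_0004", "NM_0004.1", "gD", random_dna(100),
                   with_gene = FALSE)
  )
  writeLines(recs, path)
  path
}

write_family_fixture <- function(path) {
  lines <- c(
    "miR family\tSeed+m8\tSpecies ID\tMiRBase ID\tMature sequence",
    "miR-29abc\tAGCACCA\t10090\tmmu-miR-29a\tUAGCACCAUCUGAAAUCGGUUA",
    "miR-29abc\tAGCACCA\t10090\tmmu-miR-29b\tUAGCACCAUUUGAAAUCAGUGUU",
    "miR-15ab\tagcagca\t10090\tmmu-miR-15a\tUAGCAGCACAUAAUGGUUUGUG",
    "let-7\tGAGGUAG\t10090\tmmu-let-7a\tUGAGGUAGUAGGUUGUAUAGUU",
    "miR-bad\tAGXACCA\t10090\tmmu-bad\tUAGXACCAUCUGAAAUCGGUUA",
    "miR-short\tAGCAC\t10090\tmmu-short\tUAGCACAUCUGAAAUCGGUUA"
  )
  writeLines(lines, path)
  path
}
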