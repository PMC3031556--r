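## Transcript corpora: sequences with CDS annotation, partitioned into
## 5' UTR / CDS / 3' UTR.  Coordinates are 1-based inclusive throughout
## (GenBank convention).  mRNA records are single-stranded; no
## reverse-strand scanning happens anywhere in the package.

.REGIONS <- c("FIVE_UTR", "CDS", "THREE_UTR", "FULL")

#' Construct a transcript corpus
#'
#' A corpus is a data frame with one row per transcript: `gene_id`,
#' `transcript_id`, `sequence` (mRNA-sense DNA, alphabet ACGTN) and a
#' 1-based inclusive CDS interval `cds_start`/`cds_end` (`NA` when the
#' record carries no parseable contiguous CDS).
#'
#' @param gene_id,transcript_id Character vectors.
#' @param sequence Character vector of mRNA-sense sequences.
#' @param cds_start,cds_end Integer vectors (NA allowed pairwise).
#' @return A data frame of class `transcript_corpus`.
#' @export
transcript_corpus <- function(gene_id, transcript_id, sequence,
                              cds_start = NA_integer_, cds_end = NA_integer_) {
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence alphabet must be ACGTN; offending transcript(s): ",
         paste(transcript_id[bad], collapse = ", "))
  }
  x <- data.frame(gene_id = as.character(gene_id),
                  transcript_id = as.character(transcript_id),
                  sequence = sequence,
                  cds_start = as.integer(cds_start),
                  cds_end = as.integer(cds_end),
                  stringsAsFactors = FALSE)
  has <- !is.na(x$cds_start) | !is.na(x$cds_end)
  if (any(has & (is.na(x$cds_start) | is.na(x$cds_end)))) {
    stop("cds_start and cds_end must be both present or both absent")
  }
  with_cds <- !is.na(x$cds_start)
  ok <- x$cds_start[with_cds] >= 1L &
    x$cds_start[with_cds] <= x$cds_end[with_cds] &
    x$cds_end[with_cds] <= nchar(x$sequence[with_cds])
  if (any(!ok)) {
    stop("CDS interval outside sequence bounds for transcript(s): ",
         paste(x$transcript_id[with_cds][!ok], collapse = ", "))
  }
  class(x) <- c("transcript_corpus", "data.frame")
  x
}

#' Read transcripts from a GenBank flat file
#'
#' Minimal reader for the GenBank flat-file dialect of mRNA records (the
#' layout of NCBI `rna.gbk` dumps): per record it extracts the accession
#' (VERSION, falling back to LOCUS), the first `/gene` qualifier, the CDS
#' feature location and the ORIGIN sequence.  Only simple contiguous CDS
#' spans (`CDS  a..b`) are supported; records whose CDS uses `join()` or
#' other compound locations keep their sequence but get an absent CDS
#' interval and are counted in `attr(x, "n_flagged_cds")`.  Records with
#' no `/gene` qualifier are skipped with a message.
#'
#' @param path Path to a GenBank flat file.
#' @return A `transcript_corpus`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("unreadable or empty GenBank file: ", path)
  rec_end <- grep("^//", lines)
  if (!length(rec_end)) stop("no record terminator '//' found in ", path)
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)

  gene <- tid <- seqs <- character(0)
  cs <- ce <- integer(0)
  n_flagged <- 0L
  n_skipped <- 0L

  for (r in seq_along(rec_end)) {
    block <- lines[rec_start[r]:rec_end[r]]
    block <- block[nzchar(trimws(block))]
    if (!length(block)) next

    ver <- grep("^VERSION", block, value = TRUE)
    loc <- grep("^LOCUS", block, value = TRUE)
    id <- if (length(ver)) strsplit(trimws(sub("^VERSION", "", ver[1L])),
                                    "[[:space:]]+")[[1L]][1L]
          else if (length(loc)) strsplit(trimws(sub("^LOCUS", "", loc[1L])),
                                         "[[:space:]]+")[[1L]][1L]
          else NA_character_

    g <- regmatches(block, regexpr("/gene=\"[^\"]+\"", block))
    g <- g[nzchar(g)]
    if (!length(g)) {
      message("GenBank record ", r, " (", id, ") has no /gene qualifier; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    g <- sub("\"$", "", sub("^/gene=\"", "", g[1L]))

    cds_line <- grep("^ {2,}CDS +", block, value = TRUE)
    cds_start <- cds_end <- NA_integer_
    if (length(cds_line)) {
      locstr <- trimws(sub("^ +CDS +", "", cds_line[1L]))
      m <- regmatches(locstr, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", locstr))[[1L]]
      if (length(m) == 3L) {
        cds_start <- as.integer(m[2L])
        cds_end <- as.integer(m[3L])
      } else {
        n_flagged <- n_flagged + 1L   # join()/complement(): unsupported
      }
    }

    o <- grep("^ORIGIN", block)
    if (!length(o) || o[1L] == length(block)) {
      message("GenBank record ", id, " has no ORIGIN sequence; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    seq_lines <- block[(o[1L] + 1L):length(block)]
    s <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

    gene <- c(gene, g); tid <- c(tid, id); seqs <- c(seqs, s)
    cs <- c(cs, cds_start); ce <- c(ce, cds_end)
  }
  if (!length(seqs)) stop("no usable records in ", path)
  out <- transcript_corpus(gene, tid, seqs, cs, ce)
  attr(out, "n_flagged_cds") <- n_flagged
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read transcripts from FASTA plus a region sidecar table
#'
#' @param fasta Path to a FASTA file of mRNA-sense sequences; the first
#'   whitespace-delimited token of each header is the transcript ID.
#' @param regions Path to a TSV with columns `transcript_id`, `gene_id`,
#'   `cds_start`, `cds_end`.  Transcripts absent from the sidecar keep an
#'   absent CDS interval (and fall back to their transcript ID as gene ID),
#'   and are counted in `attr(x, "n_unannotated")`.
#' @return A `transcript_corpus`.
#' @export
read_fasta_with_regions <- function(fasta, regions) {
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1L)
  side <- utils::read.delim(regions, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(need %in% names(side))) {
    stop("region sidecar must have columns: ", paste(need, collapse = ", "))
  }
  idx <- match(ids, side$transcript_id)
  gene <- ifelse(is.na(idx), ids, side$gene_id[idx])
  cs <- ifelse(is.na(idx), NA_integer_, as.integer(side$cds_start[idx]))
  ce <- ifelse(is.na(idx), NA_integer_, as.integer(side$cds_end[idx]))
  out <- transcript_corpus(gene, ids, as.character(ss), cs, ce)
  attr(out, "n_unannotated") <- sum(is.na(idx))
  out
}

#' Keep the longest transcript of each gene
#'
#' When a gene has several transcripts, the one with the longest total
#' sequence is retained; ties are broken by the lexicographically smallest
#' transcript ID so the selection is deterministic and order-independent.
#'
#' @param corpus A `transcript_corpus`.
#' @return A `transcript_corpus` with exactly one row per `gene_id`,
#'   ordered by `gene_id`.
#' @export
select_longest_per_gene <- function(corpus) {
  stopifnot(inherits(corpus, "transcript_corpus"))
  o <- order(corpus$gene_id, -nchar(corpus$sequence), corpus$transcript_id)
  x <- corpus[o, , drop = FALSE]
  x <- x[!duplicated(x$gene_id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("transcript_corpus", "data.frame")
  x
}

#' Extract a region of a transcript
#'
#' Regions are defined from the 1-based inclusive CDS interval:
#' `FIVE_UTR` is positions `1..cds_start-1`, `CDS` is
#' `cds_start..cds_end`, `THREE_UTR` is `cds_end+1..length`, and `FULL` is
#' the whole sequence.  Empty regions yield `""`.
#'
#' @param record A single-row `transcript_corpus` (or a list with fields
#'   `sequence`, `cds_start`, `cds_end`).
#' @param region One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"FULL"`.
#' @return The region sequence as a character scalar.
#' @export
region_sequence <- function(record, region = .REGIONS) {
  region <- match.arg(region)
  s <- record$sequence
  if (length(s) != 1L) stop("region_sequence expects a single record")
  if (region == "FULL") return(s)
  if (is.na(record$cds_start)) {
    stop("region '", region, "' requested for a record without CDS annotation (",
         record$transcript_id, ")")
  }
  a <- record$cds_start
  b <- record$cds_end
  switch(region,
         FIVE_UTR = if (a > 1L) substr(s, 1L, a - 1L) else "",
         CDS = substr(s, a, b),
         THREE_UTR = if (b < nchar(s)) substr(s, b + 1L, nchar(s)) else "")
}

#' Write a corpus as FASTA plus region sidecar
#'
#' Inverse of [read_fasta_with_regions()]; a corpus written and re-read
#' round-trips exactly.
#'
#' @param corpus A `transcript_corpus`.
#' @param fasta,regions Output paths.
#' @return `fasta`, invisibly.
#' @export
write_corpus <- function(corpus, fasta, regions) {
  stopifnot(inherits(corpus, "transcript_corpus"))
  con <- file(fasta, "wb")  # binary mode: fixed LF line endings
  on.exit(close(con))
  writeLines(paste0(">", corpus$transcript_id, "\n", corpus$sequence),
             con, sep = "\n")
  ann <- corpus[!is.na(corpus$cds_start),
                c("transcript_id", "gene_id", "cds_start", "cds_end"),
                drop = FALSE]
  utils::write.table(ann, regions, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(fasta)
}
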