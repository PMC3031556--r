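## Exact 7-mer MRE scanning.  Matches are exact string identity to the
## reverse-complemented seed; overlapping occurrences are all counted
## (one per possible start position, mirroring the Poisson null, which
## models a start at every position).  N never matches.

#' Count occurrences of an MRE motif in a sequence
#'
#' Slides a 7-nt window over positions `1..L-6` and records every exact
#' match, including overlapping ones.  `N` characters never match.
#'
#' @param sequence A DNA character scalar (alphabet ACGTN).
#' @param motif A 7-nt DNA motif (character scalar, or a one-row data
#'   frame with a `dna7` column).
#' @return A list with elements `count` (integer) and `positions`
#'   (strictly increasing 1-based start positions).
#' @examples
#' count_occurrences("TGGTGCTGGTGCT", "TGGTGCT")$positions  # 1 7
#' @export
count_occurrences <- function(sequence, motif) {
  motif <- as_motif(motif)
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 7L) {
    return(list(count = 0L, positions = integer(0)))
  }
  ## zero-width lookahead so overlapping matches are all reported
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  pos <- as.integer(m[m > 0L])
  list(count = length(pos), positions = pos)
}

#' Scan one transcript per region
#'
#' Counts motif occurrences in each annotated region (positions reported
#' 1-based and region-local) and in the full sequence, which is scanned
#' independently.  A match straddling a region junction appears only in
#' the `FULL` count; the number of such junction-spanning matches is
#' reported in the `junction` attribute and never silently merged into a
#' region count.
#'
#' @param record A single-row `transcript_corpus`.
#' @param motif A 7-nt DNA motif.
#' @return A data frame with columns `transcript_id`, `gene_id`, `motif`,
#'   `region`, `count` and a `positions` list-column; rows for `FIVE_UTR`,
#'   `CDS`, `THREE_UTR` (when the record has a CDS) and always `FULL`.
#' @export
scan_transcript <- function(record, motif) {
  motif <- as_motif(motif)
  regions <- if (is.na(record$cds_start)) "FULL" else .REGIONS
  res <- lapply(regions, function(rg) {
    count_occurrences(region_sequence(record, rg), motif)
  })
  out <- data.frame(transcript_id = record$transcript_id,
                    gene_id = record$gene_id,
                    motif = motif,
                    region = regions,
                    count = vapply(res, function(x) x$count, integer(1)),
                    stringsAsFactors = FALSE)
  out$positions <- lapply(res, function(x) x$positions)
  attr(out, "junction") <-
    out$count[out$region == "FULL"] - sum(out$count[out$region != "FULL"])
  out
}

#' Scan a corpus of transcripts for a set of motifs
#'
#' Produces the per-gene count table used by the enrichment and
#' multi-MRE filters.  Genes with zero counts are retained (they are
#' needed as denominators downstream).  Records without CDS annotation
#' are scanned as `FULL` only and carry `NA` region counts.
#'
#' @param corpus A `transcript_corpus`, one transcript per gene (see
#'   [select_longest_per_gene()]).
#' @param motifs Character vector of 7-nt DNA motifs (or a data frame
#'   with a `dna7` column, e.g. from [dedup_seeds()]).
#' @return A data frame of class `mre_count_table` with columns
#'   `gene_id`, `transcript_id`, `motif`, `five_utr`, `cds`, `three_utr`,
#'   `full`, `junction`.
#' @export
scan_corpus <- function(corpus, motifs) {
  stopifnot(inherits(corpus, "transcript_corpus"))
  if (is.data.frame(motifs)) motifs <- motifs$dna7
  motifs <- vapply(motifs, as_motif, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(corpus$gene_id)) {
    stop("corpus has multiple transcripts per gene; apply select_longest_per_gene() first")
  }
  rows <- vector("list", length(motifs) * nrow(corpus))
  k <- 0L
  for (mo in motifs) {
    for (i in seq_len(nrow(corpus))) {
      rec <- corpus[i, , drop = FALSE]
      full <- count_occurrences(rec$sequence, mo)$count
      if (is.na(rec$cds_start)) {
        cnt <- c(NA_integer_, NA_integer_, NA_integer_)
        junc <- NA_integer_
      } else {
        cnt <- c(count_occurrences(region_sequence(rec, "FIVE_UTR"), mo)$count,
                 count_occurrences(region_sequence(rec, "CDS"), mo)$count,
                 count_occurrences(region_sequence(rec, "THREE_UTR"), mo)$count)
        junc <- full - sum(cnt)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = rec$gene_id,
                              transcript_id = rec$transcript_id,
                              motif = mo,
                              five_utr = cnt[1L], cds = cnt[2L],
                              three_utr = cnt[3L], full = full,
                              junction = junc,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), transcript_id = character(0),
                      motif = character(0), five_utr = integer(0),
                      cds = integer(0), three_utr = integer(0),
                      full = integer(0), junction = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("mre_count_table", "data.frame")
  out
}

#' Genes with many MREs in CDS plus 3' UTR
#'
#' Filters a count table to genes whose combined CDS + 3' UTR count for a
#' motif reaches `min_total` (the multi-MRE gene list; with the default
#' threshold of 5 this is the filter behind multi-site candidate genes
#' such as the elastin and collagen mRNAs).
#'
#' @param table An `mre_count_table` from [scan_corpus()].
#' @param motif The 7-nt DNA motif to filter on.
#' @param min_total Minimum combined CDS + 3' UTR count (default 5).
#' @return Data frame of retained genes with their counts, sorted by
#'   descending total then `gene_id`.
#' @export
multi_mre_genes <- function(table, motif, min_total = 5L) {
  motif <- as_motif(motif)
  x <- table[table$motif == motif & !is.na(table$cds), , drop = FALSE]
  x$cds_plus_utr3 <- x$cds + x$three_utr
  x <- x[x$cds_plus_utr3 >= min_total, , drop = FALSE]
  x <- x[order(-x$cds_plus_utr3, x$gene_id), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write / read a per-gene count table
#'
#' @param table An `mre_count_table`.
#' @param path TSV path.
#' @return `path` invisibly, or the table for the reader.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("mre_count_table", "data.frame")
  out
}

## -- internal ---------------------------------------------------------------

as_motif <- function(motif) {
  if (is.data.frame(motif)) motif <- motif$dna7
  stopifnot(length(motif) == 1L)
  motif <- toupper(as.character(motif))
  if (nchar(motif) != 7L) {
    stop("MRE motif must be exactly 7 nt, got '", motif, "'")
  }
  check_alphabet(motif, c("A", "C", "G", "T"), what = "motif")
  motif
}
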