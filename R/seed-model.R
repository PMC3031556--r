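## miRNA family seeds and the genomic motifs they recognise.
##
## A miRNA family is defined by its seed, nucleotides 2-8 of the mature
## miRNA (a 7-mer over {A,C,G,U}).  The corresponding miRNA response
## element (MRE) on the target mRNA is the reverse complement of the seed
## written in the DNA alphabet: e.g. the miR-29 seed AGCACCA recognises
## the genomic motif TGGTGCT.

.RNA_ALPHABET <- c("A", "C", "G", "U")

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is defined as nucleotides 2--8 (1-based, inclusive) of the
#' mature miRNA, the principal determinant of target specificity shared by
#' all members of a miRNA family.
#'
#' @param mature_sequence Character vector of mature miRNA sequences
#'   (RNA alphabet; `T` is tolerated and normalised to `U`).
#' @return Character vector of 7-mer seeds (uppercase RNA alphabet).
#' @examples
#' extract_seed("UAGCACCAUCUGAAAUCGGUUA")  # miR-29a -> "AGCACCA"
#' @export
extract_seed <- function(mature_sequence) {
  mature_sequence <- normalize_rna(mature_sequence)
  short <- nchar(mature_sequence) < 8L
  if (any(short)) {
    stop("mature sequence shorter than 8 nt: ",
         paste(mature_sequence[short], collapse = ", "))
  }
  substr(mature_sequence, 2L, 8L)
}

#' Derive the genomic MRE motif recognised by a seed
#'
#' The motif a miRNA seed pairs with on the mRNA (read 5'->3' in mRNA
#' sense) is the reverse complement of the seed, written with `T` in place
#' of `U`.  For the miR-29 seed `AGCACCA` this gives `TGGTGCT`; for the
#' miR-15 seed `AGCAGCA`, `TGCTGCT`.
#'
#' @param seed7 Character vector of 7-nt seeds (RNA alphabet; `T`
#'   tolerated and normalised).  A data frame with a `seed7` column, as
#'   returned by [read_mirna_families()], is also accepted.
#' @return Character vector of 7-nt DNA motifs.
#' @examples
#' seed_to_mre("AGCACCA")  # "TGGTGCT"
#' @export
seed_to_mre <- function(seed7) {
  if (is.data.frame(seed7)) seed7 <- seed7$seed7
  seed7 <- normalize_rna(seed7)
  bad <- nchar(seed7) != 7L
  if (any(bad)) {
    stop("seed must be exactly 7 nt, got: ", paste(seed7[bad], collapse = ", "))
  }
  check_alphabet(seed7, .RNA_ALPHABET, what = "seed")
  ## complement in RNA space, then reverse and write as DNA
  comp <- chartr("ACGU", "UGCA", seed7)
  rc <- vapply(strsplit(comp, "", fixed = TRUE),
               function(x) paste(rev(x), collapse = ""), character(1))
  chartr("U", "T", rc)
}

#' Recover a seed from a genomic MRE motif
#'
#' Inverse of [seed_to_mre()]: reverse complement of the DNA 7-mer,
#' written in the RNA alphabet.
#'
#' @param dna7 Character vector of 7-nt DNA motifs.
#' @return Character vector of 7-nt RNA seeds.
#' @export
mre_to_seed <- function(dna7) {
  dna7 <- toupper(dna7)
  bad <- nchar(dna7) != 7L
  if (any(bad)) {
    stop("motif must be exactly 7 nt, got: ", paste(dna7[bad], collapse = ", "))
  }
  check_alphabet(dna7, c("A", "C", "G", "T"), what = "motif")
  comp <- chartr("ACGT", "TGCA", dna7)
  rc <- vapply(strsplit(comp, "", fixed = TRUE),
               function(x) paste(rev(x), collapse = ""), character(1))
  chartr("T", "U", rc)
}

#' Read a miRNA family table
#'
#' Parses the tab-separated family-definition dialect used by TargetScan's
#' `miR_Family_Info.txt`: one row per family member with columns for the
#' family name, the 7-nt seed (miRNA nucleotides 2--8), a numeric species
#' ID, a member (MiRBase) ID and the mature sequence.  Columns are located
#' by header name where possible, falling back to the canonical column
#' order; extra columns are ignored.
#'
#' Rows with a malformed seed (wrong length or characters outside ACGU
#' after normalisation) are skipped with a warning naming the line.  Rows
#' are collapsed to one entry per (family, species) with member IDs
#' aggregated.
#'
#' @param path Path to the tab-separated family file (header line present).
#' @param species Optional species tag/ID; when given, only matching rows
#'   are kept.  Default `NULL` uses the file as-is.
#' @return A data frame of class `mirna_family_table` with columns
#'   `family_name`, `seed7`, `species_tag`, `mature_sequence` (first
#'   member's), `member_ids` (semicolon-separated) and `dna7` (the genomic
#'   MRE motif from [seed_to_mre()]).  The number of rows skipped as
#'   malformed is available as `attr(x, "n_skipped")`.
#' @export
read_mirna_families <- function(path, species = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("empty family table: ", path)
  cols <- tolower(names(raw))
  pick <- function(patterns, fallback) {
    for (p in patterns) {
      hit <- grep(p, cols)
      if (length(hit)) return(hit[1L])
    }
    fallback
  }
  i_family <- pick("family", 1L)
  i_seed   <- pick(c("seed"), 2L)
  i_spec   <- pick(c("species"), 3L)
  i_member <- pick(c("mirbase.*id", "^mir$"), min(4L, ncol(raw)))
  i_mature <- pick(c("mature"), min(5L, ncol(raw)))

  fam <- data.frame(
    family_name = trimws(raw[[i_family]]),
    seed7 = normalize_rna(trimws(raw[[i_seed]])),
    species_tag = trimws(raw[[i_spec]]),
    member_id = trimws(raw[[i_member]]),
    mature_sequence = normalize_rna(trimws(raw[[i_mature]])),
    stringsAsFactors = FALSE
  )

  ok <- nchar(fam$seed7) == 7L &
    !grepl(paste0("[^", paste(.RNA_ALPHABET, collapse = ""), "]"), fam$seed7)
  if (any(!ok)) {
    warning(sum(!ok), " malformed family row(s) skipped (lines ",
            paste(which(!ok) + 1L, collapse = ", "), " of ", path, ")")
  }
  n_skipped <- sum(!ok)
  fam <- fam[ok, , drop = FALSE]

  if (!is.null(species)) {
    fam <- fam[fam$species_tag == as.character(species), , drop = FALSE]
  }
  if (nrow(fam) == 0L) stop("no valid family rows in ", path)

  key <- paste(fam$family_name, fam$species_tag, sep = "\r")
  first <- !duplicated(key)
  out <- fam[first, c("family_name", "seed7", "species_tag",
                      "mature_sequence"), drop = FALSE]
  out$member_ids <- vapply(split(fam$member_id, key)[unique(key)],
                           paste, character(1), collapse = ";")
  out$dna7 <- seed_to_mre(out$seed7)
  rownames(out) <- NULL
  class(out) <- c("mirna_family_table", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  message(nrow(out), " miRNA families read from ", basename(path))
  out
}

#' Collapse a family table to distinct seeds
#'
#' Families that differ only at position 1 of the mature miRNA (e.g.
#' miR-195 and miR-497) share the same 7-mer seed and hence the same MRE;
#' counting statistics are computed once per distinct seed.  The family
#' names carried by each seed are retained for reporting.
#'
#' @param families A `mirna_family_table` (or any data frame with
#'   `family_name` and `seed7` columns).
#' @return Data frame with one row per distinct `seed7`, columns `seed7`,
#'   `dna7` and `families` (semicolon-separated family names).
#' @export
dedup_seeds <- function(families) {
  stopifnot(is.data.frame(families),
            all(c("family_name", "seed7") %in% names(families)))
  sp <- split(families$family_name, families$seed7)
  out <- data.frame(
    seed7 = names(sp),
    dna7 = seed_to_mre(names(sp)),
    families = vapply(sp, function(x) paste(unique(x), collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a normalised family table
#'
#' @param families A `mirna_family_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mirna_families <- function(families, path) {
  utils::write.table(as.data.frame(families)[, c("family_name", "seed7", "dna7")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -- internal helpers -------------------------------------------------------

normalize_rna <- function(x) chartr("T", "U", toupper(x))

check_alphabet <- function(x, alphabet, what = "sequence") {
  pat <- paste0("[^", paste(alphabet, collapse = ""), "]")
  m <- regmatches(x, regexpr(pat, x))
  if (length(m) && any(nzchar(m))) {
    stop("invalid character '", m[nzchar(m)][1L], "' in ", what)
  }
  invisible(TRUE)
}
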