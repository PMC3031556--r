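## Poisson overrepresentation test for MRE counts.
##
## Null model: the motif starts at any of the L-6 possible positions of an
## mRNA of length L independently, each with probability p equal to the
## product of the background frequencies of the seven motif nucleotides.
## The occurrence count is then approximately Poisson with rate
## lambda = (L - 6) * p (mutual dependence of overlapping occurrences is
## disregarded, a reasonable simplification for rare 7-mers), and the
## reported p-value is the upper tail P(X >= k).  The background is the
## pooled nucleotide composition of all analyzed mRNA sequences.

#' Estimate the nucleotide background of a corpus
#'
#' Pools the A/C/G/T counts over all full-length sequences; `N` characters
#' are excluded from numerator and denominator.
#'
#' @param corpus A `transcript_corpus`.
#' @return A list of class `background_model` with elements `freq` (named
#'   frequencies over A, C, G, T summing to 1), `mode` (`"empirical"`) and
#'   `corpus_size` (non-N nucleotide total).
#' @export
estimate_background <- function(corpus) {
  stopifnot(inherits(corpus, "transcript_corpus"), nrow(corpus) > 0L)
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(corpus$sequence), c("A", "C", "G", "T")))
  total <- sum(counts)
  if (total == 0) stop("corpus contains no non-N nucleotides")
  background_model(counts / total, mode = "empirical", corpus_size = total)
}

#' Construct a background model directly
#'
#' @param freq Named numeric frequencies for A, C, G, T (non-negative,
#'   summing to 1 within 1e-12).
#' @param mode `"empirical"` or `"uniform"`.
#' @param corpus_size Nucleotide total used for estimation (0 when the
#'   model was specified rather than estimated).
#' @return A `background_model`.
#' @export
background_model <- function(freq, mode = c("empirical", "uniform"),
                             corpus_size = 0) {
  mode <- match.arg(mode)
  freq <- freq[c("A", "C", "G", "T")]
  if (anyNA(freq) || any(freq < 0) || abs(sum(freq) - 1) > 1e-12) {
    stop("background frequencies must be named A,C,G,T, non-negative, sum to 1")
  }
  structure(list(freq = freq, mode = mode, corpus_size = corpus_size),
            class = "background_model")
}

#' The uniform background (all frequencies 1/4)
#'
#' @return A `background_model` with mode `"uniform"`.
#' @export
uniform_background <- function() {
  background_model(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   mode = "uniform")
}

#' Per-position start probability of a motif
#'
#' Product over the seven motif positions of the background frequency of
#' the nucleotide at that position.  Under the uniform background every
#' 7-mer has probability (1/4)^7.
#'
#' @param motif A 7-nt DNA motif.
#' @param bg A `background_model`.
#' @return Probability scalar.
#' @export
motif_probability <- function(motif, bg) {
  motif <- as_motif(motif)
  stopifnot(inherits(bg, "background_model"))
  prod(bg$freq[strsplit(motif, "", fixed = TRUE)[[1L]]])
}

#' Poisson upper-tail probability of an MRE count
#'
#' With `L - 6` possible start positions each active with probability
#' `p_start`, the count is modelled as Poisson with rate
#' `lambda = (L - 6) * p_start` and the tail `P(X >= k)` is returned
#' (1 when `k = 0`).  Computed via the complemented Poisson CDF, which is
#' evaluated stably in log space by R's `ppois`.
#'
#' @param k Observed occurrence count (non-negative integer).
#' @param L mRNA length in nt (`L >= 7`).
#' @param p_start Per-position motif start probability.
#' @return A list with elements `lam` and `p_value`.
#' @export
poisson_tail <- function(k, L, p_start) {
  stopifnot(k >= 0, p_start >= 0, p_start <= 1)
  if (L < 7) stop("sequence shorter than the motif: no valid start positions")
  lam <- (L - 6) * p_start
  p <- if (k == 0) 1 else stats::ppois(k - 1, lam, lower.tail = FALSE)
  list(lam = lam, p_value = p)
}

#' Test one gene for MRE overrepresentation
#'
#' Counts motif occurrences over the full mRNA and composes
#' [motif_probability()] and [poisson_tail()].
#'
#' @param record A single-row `transcript_corpus`.
#' @param motif A 7-nt DNA motif.
#' @param bg A `background_model`.
#' @return One-row data frame with `gene_id`, `transcript_id`, `motif`,
#'   `k`, `L`, `p_start`, `lam`, `p_value`, `neg_log10_p`.
#' @export
enrich_gene <- function(record, motif, bg) {
  motif <- as_motif(motif)
  s <- record$sequence
  stopifnot(length(s) == 1L, nzchar(s))
  k <- count_occurrences(s, motif)$count
  p_start <- motif_probability(motif, bg)
  pt <- poisson_tail(k, nchar(s), p_start)
  data.frame(gene_id = record$gene_id, transcript_id = record$transcript_id,
             motif = motif, k = k, L = nchar(s), p_start = p_start,
             lam = pt$lam, p_value = pt$p_value,
             neg_log10_p = -log10(pt$p_value),
             stringsAsFactors = FALSE)
}

#' Test one gene against a whole family table
#'
#' Families are collapsed to distinct seeds before testing (families that
#' share a seed would otherwise be tested twice); one result row per
#' distinct seed, with the family names it represents.
#'
#' @param record A single-row `transcript_corpus`.
#' @param families A `mirna_family_table` (or data frame with
#'   `family_name` and `seed7`).
#' @param bg A `background_model`.
#' @return Data frame of enrichment rows (one per distinct seed) plus a
#'   `families` column, sorted by ascending `p_value`.
#' @export
enrich_families_for_gene <- function(record, families, bg) {
  seeds <- dedup_seeds(families)
  rows <- lapply(seq_len(nrow(seeds)), function(i) {
    r <- enrich_gene(record, seeds$dna7[i], bg)
    r$seed7 <- seeds$seed7[i]
    r$families <- seeds$families[i]
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test every gene of a corpus for one motif
#'
#' @param corpus A `transcript_corpus`, one transcript per gene.
#' @param motif A 7-nt DNA motif.
#' @param bg A `background_model`.
#' @param min_count Keep only genes with at least this many occurrences
#'   (default 0 keeps all; 1 gives the view used for count histograms
#'   restricted to genes carrying the motif).
#' @return Data frame of enrichment rows sorted by ascending `p_value`
#'   (ties by `gene_id`), with a Bonferroni-adjusted convenience column
#'   `p_bonferroni` (adjusted over all tested genes, before any
#'   `min_count` filtering).
#' @export
enrich_corpus_for_motif <- function(corpus, motif, bg, min_count = 0L) {
  stopifnot(inherits(corpus, "transcript_corpus"))
  if (anyDuplicated(corpus$gene_id)) {
    stop("corpus has multiple transcripts per gene; apply select_longest_per_gene() first")
  }
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    enrich_gene(corpus[i, , drop = FALSE], motif, bg)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[out$k >= min_count, , drop = FALSE]
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of -log10 p-values
#'
#' Bins the negative decadic logarithm of enrichment p-values, the
#' display used for family-wide and genome-wide overrepresentation scans.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param binwidth Bin width on the -log10 scale (default 1).
#' @return Data frame with `bin_lower`, `bin_upper`, `n`.
#' @export
neg_log10_histogram <- function(p_values, binwidth = 1) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  v <- -log10(p_values)
  lo <- floor(v / binwidth) * binwidth
  tab <- table(lo)
  data.frame(bin_lower = as.numeric(names(tab)),
             bin_upper = as.numeric(names(tab)) + binwidth,
             n = as.integer(tab))
}

#' Binomial upper-tail probability
#'
#' Exact tail `P(X >= k)` for `X ~ Binomial(n, p_success)`, used to
#' quantify how surprising an observed overlap between two gene or miRNA
#' sets is (e.g. k of n significant-signature families falling in the
#' experimentally down-regulated set when a random family is
#' down-regulated with probability `p_success`).
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p_success Single-trial success probability.
#' @return A list with `k`, `n`, `p_success`, `p_value`.
#' @export
binomial_tail <- function(k, n, p_success) {
  if (p_success < 0 || p_success > 1) stop("p_success must lie in [0, 1]")
  stopifnot(k >= 0, k <= n, n >= 0)
  p <- if (k == 0) 1 else stats::pbinom(k - 1, n, p_success, lower.tail = FALSE)
  list(k = as.integer(k), n = as.integer(n), p_success = p_success,
       p_value = p)
}
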