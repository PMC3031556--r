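## Synthetic data with known truth.
##
## Transcript corpora are built by a scrub-then-plant construction: an
## i.i.d. background is drawn from the requested composition, every
## spurious occurrence of a planted motif is re-drawn to a fixpoint, and
## the requested number of sites is then planted at non-overlapping
## positions inside the designated region.  The construction guarantees
## that a scan recovers the planted counts exactly, so every downstream
## stage can be validated against recorded truth.  All generators are
## pure functions of (parameters, seed).

.ELN_LIKE_COMPOSITION <- c(A = 0.22, C = 0.26, G = 0.34, T = 0.18)

#' Simulate a transcript corpus with planted MRE counts
#'
#' @param n_genes Number of genes (one transcript each).
#' @param length_range Min/max transcript length in nt (drawn uniformly).
#' @param composition Either `"eln_like"` (default: a GC-rich profile in
#'   the style of extracellular-matrix transcripts, which exercises the
#'   empirical-background path distinctly from uniform), `"uniform"`, or
#'   a named A/C/G/T probability vector.
#' @param plant Optional data frame with columns `gene` (index in
#'   `1..n_genes`), `motif` (7-nt DNA), `region` (`FIVE_UTR`, `CDS` or
#'   `THREE_UTR`) and `count`.  The background is scrubbed of all planted
#'   motifs corpus-wide, so scanned counts equal planted counts exactly.
#' @param junction_site If `TRUE`, one extra site of the first planted
#'   motif is placed straddling the CDS/3' UTR junction of gene 1 (for
#'   exercising the junction-count rule); recorded in the truth, never in
#'   the per-region counts.
#' @param seed Integer seed; the generator is deterministic given
#'   (parameters, seed) and does not disturb the caller's RNG.
#' @return A list with elements `corpus` (a [transcript_corpus()]) and
#'   `truth` (planted counts/positions, parameters and seed).
#' @export
simulate_transcripts <- function(n_genes, length_range = c(1500L, 3500L),
                                 composition = "eln_like", plant = NULL,
                                 junction_site = FALSE, seed = 1L) {
  comp <- resolve_composition(composition)
  plant <- validate_plant(plant, n_genes)
  motifs <- unique(plant$motif)

  out <- with_local_seed(seed, {
    lens <- length_range[1L]:length_range[2L]
    L <- lens[sample.int(length(lens), n_genes, replace = TRUE)]
    ## CDS bounds keeping all three regions comfortably non-empty
    cds_start <- pmax(31L, as.integer(round(L * stats::runif(n_genes, 0.08, 0.22))))
    cds_end <- pmin(L - 31L, as.integer(round(L * stats::runif(n_genes, 0.60, 0.85))))
    stopifnot(all(cds_start < cds_end))

    seqs <- character(n_genes)
    planted_pos <- vector("list", nrow(plant))
    junction <- NULL

    for (i in seq_len(n_genes)) {
      letters_i <- sample(names(comp), L[i], replace = TRUE, prob = comp)
      pl <- plant[plant$gene == i, , drop = FALSE]
      reg_bounds <- region_bounds(L[i], cds_start[i], cds_end[i])
      ## capacity check before any work
      for (j in seq_len(nrow(pl))) {
        b <- reg_bounds[[pl$region[j]]]
        reglen <- b[2L] - b[1L] + 1L
        if (pl$count[j] * 14L > reglen) {
          stop("region ", pl$region[j], " of gene ", i,
               " too short for ", pl$count[j], " planted site(s)")
        }
      }
      letters_i <- scrub_motifs(letters_i, motifs, comp)
      ## plant sites: occupied intervals padded by 7 so no window overlaps two
      occupied <- integer(0)
      for (j in seq_len(nrow(pl))) {
        idx <- which(plant$gene == i)[match(j, seq_len(nrow(pl)))]
        b <- reg_bounds[[pl$region[j]]]
        pos <- plant_sites(b, pl$count[j], occupied)
        occupied <- c(occupied, pos)
        for (p in pos) {
          letters_i[p:(p + 6L)] <- strsplit(pl$motif[j], "", fixed = TRUE)[[1L]]
        }
        planted_pos[[idx]] <- pos
      }
      if (junction_site && i == 1L && length(motifs)) {
        jp <- cds_end[1L] - 3L  # straddles the CDS/3'UTR junction
        if (all(abs(jp - occupied) >= 14L)) {
          letters_i[jp:(jp + 6L)] <- strsplit(motifs[1L], "", fixed = TRUE)[[1L]]
          occupied <- c(occupied, jp)
          junction <- list(gene = 1L, motif = motifs[1L], position = jp)
        }
      }
      letters_i <- enforce_planted_counts(letters_i, motifs, occupied, comp)
      seqs[i] <- paste(letters_i, collapse = "")
    }

    gene_id <- sprintf("G%04d", seq_len(n_genes))
    corpus <- transcript_corpus(gene_id,
                                sprintf("T%04d.1", seq_len(n_genes)),
                                seqs, cds_start, cds_end)
    truth_plant <- plant
    truth_plant$gene_id <- gene_id[plant$gene]
    truth_plant$positions <- planted_pos
    list(corpus = corpus,
         truth = list(plant = truth_plant, junction = junction,
                      composition = comp, length_range = length_range,
                      seed = seed))
  })
  out
}

#' Simulate a miRNA family table
#'
#' Generates `n_families` distinct random 7-mer seeds in the tab-separated
#' family-table dialect read by [read_mirna_families()].  The miR-29 seed
#' `AGCACCA` and the miR-15 seed `AGCAGCA` are always included first (so
#' `n_families = 2` yields exactly those two).
#'
#' @param n_families Number of families (2 <= n <= 4^7).
#' @param seed Integer seed.
#' @param path Optional output TSV path; when given the table is written
#'   in the family-file dialect.
#' @return Data frame with columns `family`, `seed`, `species_id`,
#'   `mirbase_id`, `mature_sequence` (the on-disk layout).
#' @export
simulate_family_table <- function(n_families, seed = 1L, path = NULL) {
  stopifnot(n_families >= 2L, n_families <= 4^7)
  ref_seeds <- c("AGCACCA", "AGCAGCA")
  ref_names <- c("miR-29abc", "miR-15ab")
  tab <- with_local_seed(seed, {
    seeds <- ref_seeds
    while (length(seeds) < n_families) {
      need <- n_families - length(seeds)
      cand <- vapply(seq_len(need * 2L), function(i) {
        paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE), collapse = "")
      }, character(1))
      seeds <- unique(c(seeds, cand))
    }
    seeds <- seeds[seq_len(n_families)]
    tails <- vapply(seq_len(n_families), function(i) {
      paste(sample(c("A", "C", "G", "U"), 14L, replace = TRUE), collapse = "")
    }, character(1))
    nm <- c(ref_names, sprintf("sim-miR-%03d", seq_len(max(0L, n_families - 2L))))
    data.frame(family = nm[seq_len(n_families)],
               seed = seeds,
               species_id = "10090",
               mirbase_id = paste0(nm[seq_len(n_families)], "-1"),
               mature_sequence = paste0("U", seeds, tails),
               stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    hdr <- c("miR family", "Seed+m8", "Species ID", "MiRBase ID",
             "Mature sequence")
    con <- file(path, "wb")
    writeLines(c(paste(hdr, collapse = "\t"),
                 do.call(paste, c(tab, sep = "\t"))), con, sep = "\n")
    close(con)
  }
  tab
}

#' Simulate a two-group expression matrix with planted effects
#'
#' Emulates a pooled-sample two-group microarray design (two groups of 3
#' samples by default): per-gene log-normal baseline, group-2 effects for
#' planted differentially expressed genes, an additive repression of each
#' repressed family's targets in group 2, and i.i.d. Gaussian noise on
#' the log2 scale.
#'
#' @param n_genes Number of genes (one probe per gene).
#' @param group_sizes Integer pair, samples per group (default `c(3, 3)`;
#'   groups are labelled `g1` and `g2`, and planted fold changes are
#'   applied to `g2`).
#' @param planted_de Named numeric vector gene ID -> linear fold change
#'   (values > 1 up in group 2, < 1 down in group 2).
#' @param target_map Optional named list family -> target gene IDs.
#' @param repression_effect Named numeric vector family -> effect size in
#'   noise-SD units; the family's targets are shifted down by
#'   `effect * noise_sd` log2 units in group 2.
#' @param noise_sd Log2-scale noise standard deviation (default 0.25).
#' @param absent_fraction Fraction of probes flagged `absent` in every
#'   sample (default 0).
#' @param baseline_mean,baseline_sd Log2 baseline distribution (default
#'   mean 8, sd 2).
#' @param seed Integer seed.
#' @return A list with `matrix` (a raw-intensity [expression_matrix()])
#'   and `truth` (planted effects, parameters, seed).
#' @export
simulate_expression <- function(n_genes, group_sizes = c(3L, 3L),
                                planted_de = NULL, target_map = NULL,
                                repression_effect = NULL, noise_sd = 0.25,
                                absent_fraction = 0, baseline_mean = 8,
                                baseline_sd = 2, seed = 1L) {
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 2L))
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_de)) {
    stopifnot(all(names(planted_de) %in% gene_id), all(planted_de > 0))
  }
  if (!is.null(repression_effect)) {
    stopifnot(!is.null(target_map),
              all(names(repression_effect) %in% names(target_map)))
  }

  with_local_seed(seed, {
    n_samples <- sum(group_sizes)
    groups <- rep(c("g1", "g2"), group_sizes)
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    effect_g2 <- stats::setNames(numeric(n_genes), gene_id)
    if (!is.null(planted_de)) {
      effect_g2[names(planted_de)] <- log2(planted_de)
    }
    if (!is.null(repression_effect)) {
      for (fam in names(repression_effect)) {
        tg <- intersect(target_map[[fam]], gene_id)
        effect_g2[tg] <- effect_g2[tg] - repression_effect[fam] * noise_sd
      }
    }
    log2mat <- matrix(baseline, n_genes, n_samples) +
      outer(unname(effect_g2), as.numeric(groups == "g2")) +
      matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes)
    probe_id <- paste0("p.", gene_id)
    dimnames(log2mat) <- list(probe_id,
                              paste0(groups, ".", sequence(group_sizes)))
    flags <- matrix("present", n_genes, n_samples, dimnames = dimnames(log2mat))
    if (absent_fraction > 0) {
      off <- sample(n_genes, round(absent_fraction * n_genes))
      flags[off, ] <- "absent"
    }
    mat <- expression_matrix(2^log2mat, groups, flags = flags,
                             probe_gene = stats::setNames(gene_id, probe_id))
    list(matrix = mat,
         truth = list(planted_de = planted_de,
                      repression_effect = repression_effect,
                      target_map = target_map, noise_sd = noise_sd,
                      group_sizes = group_sizes,
                      absent_probes = rownames(flags)[flags[, 1L] == "absent"],
                      seed = seed))
  })
}

## -- internal ---------------------------------------------------------------

resolve_composition <- function(composition) {
  if (is.character(composition) && length(composition) == 1L) {
    composition <- switch(composition,
                          eln_like = .ELN_LIKE_COMPOSITION,
                          uniform = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          stop("unknown composition preset: ", composition))
  }
  comp <- composition[c("A", "C", "G", "T")]
  if (anyNA(comp) || any(comp < 0) || abs(sum(comp) - 1) > 1e-9) {
    stop("composition must be named A,C,G,T probabilities summing to 1")
  }
  comp
}

validate_plant <- function(plant, n_genes) {
  if (is.null(plant)) {
    return(data.frame(gene = integer(0), motif = character(0),
                      region = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("gene", "motif", "region", "count") %in% names(plant)))
  plant$gene <- as.integer(plant$gene)
  plant$count <- as.integer(plant$count)
  stopifnot(all(plant$gene >= 1L), all(plant$gene <= n_genes),
            all(plant$count >= 0L),
            all(plant$region %in% c("FIVE_UTR", "CDS", "THREE_UTR")))
  plant$motif <- vapply(plant$motif, as_motif, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(plant[, c("gene", "motif", "region")])) {
    stop("duplicate (gene, motif, region) rows in plant table")
  }
  plant
}

region_bounds <- function(L, cds_start, cds_end) {
  list(FIVE_UTR = c(1L, cds_start - 1L),
       CDS = c(cds_start, cds_end),
       THREE_UTR = c(cds_end + 1L, L))
}

## Re-draw every window matching any motif until none remain.
scrub_motifs <- function(letters_vec, motifs, comp, max_iter = 1000L) {
  if (!length(motifs)) return(letters_vec)
  for (iter in seq_len(max_iter)) {
    s <- paste(letters_vec, collapse = "")
    hits <- unlist(lapply(motifs, function(m) count_occurrences(s, m)$positions))
    if (!length(hits)) return(letters_vec)
    for (p in hits) {
      letters_vec[p:(p + 6L)] <- sample(names(comp), 7L, replace = TRUE,
                                        prob = comp)
    }
  }
  stop("motif scrubbing did not converge")
}

## Choose `count` non-overlapping start positions inside bounds [b1, b2],
## keeping >= 14 nt between starts (and away from `occupied` starts) so
## that no 7-nt window can overlap two planted sites.
plant_sites <- function(bounds, count, occupied) {
  if (count == 0L) return(integer(0))
  starts <- bounds[1L]:(bounds[2L] - 6L)
  chosen <- integer(0)
  for (i in seq_len(count)) {
    ok <- starts[vapply(starts, function(s) {
      all(abs(s - c(chosen, occupied)) >= 14L)
    }, logical(1))]
    if (!length(ok)) stop("could not place planted site: region too crowded")
    chosen <- c(chosen, ok[sample.int(length(ok), 1L)])
  }
  sort(chosen)
}

## After planting, any residual match not at a planted start is broken by
## mutating one background position inside it; iterate to fixpoint.
enforce_planted_counts <- function(letters_vec, motifs, planted_starts, comp,
                                   max_iter = 100L) {
  if (!length(motifs)) return(letters_vec)
  in_site <- unlist(lapply(planted_starts, function(p) p:(p + 6L)))
  for (iter in seq_len(max_iter)) {
    s <- paste(letters_vec, collapse = "")
    extra <- unlist(lapply(motifs, function(m) {
      setdiff(count_occurrences(s, m)$positions, planted_starts)
    }))
    if (!length(extra)) return(letters_vec)
    for (p in extra) {
      window <- p:(p + 6L)
      bgpos <- setdiff(window, in_site)
      if (!length(bgpos)) next  # cannot happen with >= 14 nt site spacing
      q <- bgpos[1L]
      letters_vec[q] <- sample(setdiff(names(comp), letters_vec[q]), 1L)
    }
  }
  stop("planted-count enforcement did not converge")
}
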