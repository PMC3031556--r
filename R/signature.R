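## miRNA activity signatures in expression profiles.
##
## An active miRNA leaves a detectable mark on a transcriptome: its
## predicted targets are collectively shifted down relative to
## non-targets.  The shift is tested with a one-sided Wilcoxon rank-sum
## test (alternative: target values lower), and every family's p-value is
## accompanied by a control built from size-matched random gene sets.

#' Load predicted miRNA targets
#'
#' Reads a two-column table mapping family names to target gene IDs (the
#' layout of per-family target-prediction exports), deduplicates it and
#' intersects each set with the expression universe.
#'
#' @param path TSV with columns `family` (or `family_name`) and `gene_id`
#'   (or `gene`).
#' @param universe Character vector of gene IDs present in the expression
#'   data.
#' @return Named list of class `target_map`: one character vector of gene
#'   IDs per family.  Families whose intersection with the universe is
#'   empty are retained (length-zero, so they are skipped by the screen)
#'   and listed in `attr(x, "empty_families")`.
#' @export
load_target_predictions <- function(path, universe) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("empty target prediction file: ", path)
    return(structure(list(), class = "target_map",
                     empty_families = character(0)))
  }
  fcol <- intersect(c("family", "family_name"), names(raw))[1L]
  gcol <- intersect(c("gene_id", "gene"), names(raw))[1L]
  if (is.na(fcol) || is.na(gcol)) {
    stop("target file must have family and gene columns: ", path)
  }
  sp <- lapply(split(raw[[gcol]], raw[[fcol]]),
               function(g) intersect(unique(g), universe))
  empty <- names(sp)[lengths(sp) == 0L]
  structure(sp, class = "target_map", empty_families = empty)
}

#' Rank-sum signature test for one target set
#'
#' One-sided Wilcoxon rank-sum test of the alternative "target expression
#' values are lower than non-target values".  For tiny samples (both
#' groups together at most `exact_max` values, no ties) the exact null
#' distribution is used; otherwise the normal approximation with midrank
#' tie correction and continuity correction.
#'
#' @param expr Named numeric vector: one value per gene (mean expression
#'   of a condition or a between-condition difference; probe collapse via
#'   [collapse_probes()] must already have happened).
#' @param targets Character vector of target gene IDs (non-empty subset
#'   of `names(expr)`).
#' @param alternative `"less"` (default: targets lower) or `"two.sided"`.
#' @param exact_max Largest combined group size for which the exact test
#'   is used (default 10).
#' @param exact Override the automatic choice (`NA` = automatic).
#' @return A list with `n_targets`, `n_nontargets`, `rank_sum_statistic`
#'   (the Mann-Whitney W of the target group) and `p_value`.
#' @export
rank_sum_signature <- function(expr, targets, alternative = c("less", "two.sided"),
                               exact_max = 10L, exact = NA) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(expr)), all(is.finite(expr)))
  targets <- intersect(targets, names(expr))
  if (length(targets) == 0L) stop("empty target set")
  if (length(targets) >= length(expr)) {
    stop("target set must be a strict subset of the expression universe")
  }
  is_t <- names(expr) %in% targets
  x <- expr[is_t]
  y <- expr[!is_t]
  use_exact <- if (is.na(exact)) (length(x) + length(y)) <= exact_max else exact
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  list(n_targets = length(x), n_nontargets = length(y),
       rank_sum_statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Random-set control for a signature test
#'
#' Draws `n_sets` uniform random gene sets of the given size (without
#' replacement within a set), applies [rank_sum_signature()] to each and
#' summarises the -log10 p-values: the mean and standard error that are
#' plotted alongside each family's observed signature.
#'
#' @param expr Named numeric expression vector.
#' @param set_size Size of each random set (smaller than the universe).
#' @param n_sets Number of random sets (default 10).
#' @param seed Integer seed; the draw is reproducible for a fixed seed
#'   and leaves the caller's RNG state untouched.
#' @return A list with `mean_neg_log10_p`, `se`, `n_random_sets`.
#' @export
random_set_control <- function(expr, set_size, n_sets = 10L, seed = 1L) {
  stopifnot(set_size >= 1L, set_size < length(expr), n_sets >= 1L)
  nl <- with_local_seed(seed, {
    vapply(seq_len(n_sets), function(i) {
      s <- sample(names(expr), set_size)
      -log10(rank_sum_signature(expr, s)$p_value)
    }, numeric(1))
  })
  list(mean_neg_log10_p = mean(nl),
       se = stats::sd(nl) / sqrt(n_sets),
       n_random_sets = as.integer(n_sets))
}

#' Screen an expression profile for miRNA signatures
#'
#' Applies the rank-sum signature test to every family with a non-empty
#' intersected target set and (optionally) attaches a size-matched
#' random-set control per family.
#'
#' @param expr Named numeric expression vector (gene level).
#' @param target_map A `target_map` (or named list family -> gene IDs).
#' @param n_sets Random control sets per family (default 10; 0 disables
#'   the control columns).
#' @param seed Integer seed for the control draws.
#' @return Data frame with one row per tested family: `family_name`,
#'   `n_targets`, `n_nontargets`, `rank_sum_statistic`, `p_value`,
#'   `neg_log10_p` and, when `n_sets > 0`, `control_mean_neg_log10_p`,
#'   `control_se`, `n_random_sets`; sorted by ascending `p_value`.  The
#'   seed is recorded in `attr(x, "seed")`.
#' @export
signature_screen <- function(expr, target_map, n_sets = 10L, seed = 1L) {
  stopifnot(length(target_map) > 0L)
  fams <- names(target_map)[lengths(target_map) > 0L]
  rows <- lapply(seq_along(fams), function(i) {
    fam <- fams[i]
    r <- rank_sum_signature(expr, target_map[[fam]])
    row <- data.frame(family_name = fam, n_targets = r$n_targets,
                      n_nontargets = r$n_nontargets,
                      rank_sum_statistic = r$rank_sum_statistic,
                      p_value = r$p_value,
                      neg_log10_p = -log10(r$p_value),
                      stringsAsFactors = FALSE)
    if (n_sets > 0L) {
      ctl <- random_set_control(expr, r$n_targets, n_sets = n_sets,
                                seed = seed + i)
      row$control_mean_neg_log10_p <- ctl$mean_neg_log10_p
      row$control_se <- ctl$se
      row$n_random_sets <- ctl$n_random_sets
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$family_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

## -- internal ---------------------------------------------------------------

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
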