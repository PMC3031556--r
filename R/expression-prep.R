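## Two-group microarray preprocessing and differential expression.
##
## Workflow: floor raw intensities at 1, log2-transform, align each
## sample's 75th percentile, subtract each probe's median across samples
## as baseline, drop probes never flagged present, Welch t-test per probe
## between the two groups, Benjamini-Hochberg correction, and finally the
## fold-change/FDR filter yielding the up- and down-regulated gene sets.

#' Construct an expression matrix object
#'
#' @param exprs Numeric matrix, probes x samples (rownames = probe IDs,
#'   colnames = sample IDs).
#' @param groups Character/factor vector of length `ncol(exprs)` with
#'   exactly two levels; the fold-change sign convention is positive =
#'   higher in the second level.
#' @param flags Optional character matrix of the same shape with
#'   detection calls in `present` / `marginal` / `absent`.
#' @param probe_gene Optional named character vector mapping probe IDs to
#'   gene IDs.
#' @param normalized Logical flag carried along by [normalize_expression()].
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(exprs, groups, flags = NULL, probe_gene = NULL,
                              normalized = FALSE) {
  stopifnot(is.matrix(exprs), nrow(exprs) > 0L, ncol(exprs) > 0L,
            !is.null(rownames(exprs)), !is.null(colnames(exprs)))
  groups <- as.factor(groups)
  if (length(groups) != ncol(exprs)) {
    stop("groups must have one label per sample column")
  }
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (!is.null(flags)) {
    stopifnot(is.matrix(flags), all(dim(flags) == dim(exprs)))
    bad <- !(flags %in% c("present", "marginal", "absent"))
    if (any(bad)) stop("detection flags must be present/marginal/absent")
  }
  if (!is.null(probe_gene)) {
    probe_gene <- probe_gene[intersect(names(probe_gene), rownames(exprs))]
  }
  structure(list(exprs = exprs, groups = groups, flags = flags,
                 probe_gene = probe_gene, normalized = normalized),
            class = "expression_matrix")
}

#' Normalise a raw expression matrix
#'
#' Three steps, matching the single-colour array scheme: (1) values are
#' floored at 1 and log2-transformed; (2) each sample is shifted so its
#' 75th percentile equals the mean 75th percentile across samples
#' (percentile alignment on the log scale); (3) each probe's median
#' across all samples is subtracted as baseline.
#'
#' @param mat An `expression_matrix` with raw intensities.
#' @return An `expression_matrix` with `normalized = TRUE`; the
#'   pre-baseline log2 matrix is kept as element `log2_aligned` so that
#'   linear-scale group means (for fold changes) remain available.
#' @export
normalize_expression <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  e <- log2(pmax(mat$exprs, 1))
  q75 <- apply(e, 2L, stats::quantile, probs = 0.75, names = FALSE)
  e <- sweep(e, 2L, q75 - mean(q75))
  baseline <- apply(e, 1L, stats::median)
  out <- mat
  out$log2_aligned <- e
  out$exprs <- sweep(e, 1L, baseline)
  out$normalized <- TRUE
  out
}

#' Drop probes never called present
#'
#' Removes probes whose detection flag is `absent` or `marginal` in every
#' sample; a single `present` call keeps the probe.  Without flags the
#' matrix is returned unchanged with a warning.
#'
#' @param mat An `expression_matrix`.
#' @return The filtered `expression_matrix`; the number of removed probes
#'   is reported via `message()`.
#' @export
filter_detected <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (is.null(mat$flags)) {
    warning("no detection flags: matrix returned unfiltered")
    return(mat)
  }
  keep <- rowSums(mat$flags == "present") >= 1L
  message(sum(!keep), " probe(s) absent or marginal in all samples removed")
  out <- mat
  out$exprs <- mat$exprs[keep, , drop = FALSE]
  out$flags <- mat$flags[keep, , drop = FALSE]
  if (!is.null(mat$log2_aligned)) {
    out$log2_aligned <- mat$log2_aligned[keep, , drop = FALSE]
  }
  out
}

#' Per-probe differential expression between the two groups
#'
#' Two-sample t-test on the normalised log2 values of each probe,
#' followed by Benjamini-Hochberg correction across probes.  The default
#' is the pooled equal-variance test: with very small balanced groups
#' (the typical 3 vs 3 pooled-sample design) the Welch-Satterthwaite
#' degrees of freedom collapse towards 2 and the test loses most of its
#' power, while the balanced design makes it robust to the variance
#' assumption; set `var_equal = FALSE` for Welch's test.  Fold
#' changes are computed from the group means on the linear scale (from
#' the percentile-aligned log2 matrix, before baseline subtraction) with
#' the signed convention positive = higher in the second group: a probe
#' twice as high in group 2 gets +2, twice as high in group 1 gets -2.
#'
#' @param mat A normalised `expression_matrix` (see
#'   [normalize_expression()]); both groups need at least 2 samples.
#' @param var_equal Use the pooled equal-variance t-test (default `TRUE`)
#'   or Welch's unequal-variance test (`FALSE`).
#' @return Data frame with `probe_id`, `gene_id` (NA without a map),
#'   `mean_g1`, `mean_g2` (normalised log2 scale), `fold_change`
#'   (signed, linear scale), `p_raw`, `q_bh` and `flag`
#'   (`"zero_variance"` where both groups are constant, forcing p = 1).
#' @export
differential <- function(mat, var_equal = TRUE) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!isTRUE(mat$normalized)) {
    stop("differential() expects a normalised matrix; run normalize_expression()")
  }
  g <- mat$groups
  lv <- levels(g)
  n1 <- sum(g == lv[1L]); n2 <- sum(g == lv[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  e <- mat$exprs
  e1 <- e[, g == lv[1L], drop = FALSE]
  e2 <- e[, g == lv[2L], drop = FALSE]
  m1 <- rowMeans(e1); m2 <- rowMeans(e2)
  v1 <- rowSums((e1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((e2 - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    ## Welch-Satterthwaite degrees of freedom
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  zero_var <- se2 == 0
  tstat <- ifelse(zero_var, 0, (m2 - m1) / sqrt(se2))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), ifelse(zero_var, 1, df)))

  ## linear-scale group means from the percentile-aligned log2 matrix
  la <- if (!is.null(mat$log2_aligned)) mat$log2_aligned else e
  lin1 <- rowMeans(2^la[, g == lv[1L], drop = FALSE])
  lin2 <- rowMeans(2^la[, g == lv[2L], drop = FALSE])
  ratio <- lin2 / lin1
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)

  probe_id <- rownames(e)
  gene_id <- if (!is.null(mat$probe_gene)) {
    unname(mat$probe_gene[probe_id])
  } else rep(NA_character_, length(probe_id))

  out <- data.frame(probe_id = probe_id, gene_id = gene_id,
                    mean_g1 = m1, mean_g2 = m2, fold_change = fc,
                    t_statistic = tstat, p_raw = p,
                    q_bh = stats::p.adjust(p, method = "BH"),
                    flag = ifelse(zero_var, "zero_variance", ""),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- lv
  out
}

#' Significant up- and down-regulated gene sets
#'
#' Partitions probes passing both the FDR and absolute fold-change
#' thresholds by fold-change sign, then deduplicates to gene level (a
#' gene is "up" if any of its passing probes is up).  These set sizes
#' feed the binomial overlap tests.
#'
#' @param results Output of [differential()].
#' @param q_max Benjamini-Hochberg FDR threshold (default 0.05).
#' @param min_abs_fc Minimum absolute linear fold change (default 2).
#' @return A list with `up` and `down` (character vectors of gene IDs,
#'   falling back to probe IDs where unmapped), `n_up`, `n_down`.
#' @export
significant_sets <- function(results, q_max = 0.05, min_abs_fc = 2) {
  pass <- results$q_bh < q_max & abs(results$fold_change) >= min_abs_fc &
    results$flag == ""
  ids <- ifelse(is.na(results$gene_id), results$probe_id, results$gene_id)
  up <- unique(ids[pass & results$fold_change > 0])
  down <- unique(ids[pass & results$fold_change < 0])
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}

#' Collapse probe-level values to gene level
#'
#' When several probes interrogate the same gene, the mean of their
#' values is used.  Probes without a gene mapping are dropped (with a
#' message).
#'
#' @param values Named numeric vector of per-probe values (e.g. a group
#'   mean or a between-group difference), or an `expression_matrix`
#'   (collapses each sample column).
#' @param probe_gene Named character vector probe -> gene (taken from the
#'   object when `values` is an `expression_matrix`).
#' @return Named numeric vector (or matrix) of per-gene means.
#' @export
collapse_probes <- function(values, probe_gene = NULL) {
  if (inherits(values, "expression_matrix")) {
    mat <- values
    if (is.null(probe_gene)) probe_gene <- mat$probe_gene
    if (is.null(probe_gene)) stop("no probe -> gene map available")
    m <- mat$exprs
    mapped <- rownames(m) %in% names(probe_gene)
    if (any(!mapped)) {
      message(sum(!mapped), " unmapped probe(s) dropped in collapse")
    }
    m <- m[mapped, , drop = FALSE]
    gene <- unname(probe_gene[rownames(m)])
    out <- apply(m, 2L, function(col) {
      vapply(split(col, gene), mean, numeric(1))
    })
    return(out)
  }
  stopifnot(!is.null(names(values)), !is.null(probe_gene))
  mapped <- names(values) %in% names(probe_gene)
  if (any(!mapped)) {
    message(sum(!mapped), " unmapped probe(s) dropped in collapse")
  }
  values <- values[mapped]
  gene <- unname(probe_gene[names(values)])
  vapply(split(values, gene), mean, numeric(1))
}

#' Gene-level expression vector for signature analysis
#'
#' Convenience composition: collapses probes to genes and returns either
#' a group-mean vector or the between-group difference (group 2 minus
#' group 1 on the normalised log2 scale), the inputs of
#' [signature_screen()].
#'
#' @param mat A normalised `expression_matrix` with a probe -> gene map.
#' @param what `"difference"` (default), `"mean_g1"` or `"mean_g2"`.
#' @return Named numeric vector, one value per gene.
#' @export
expression_vector <- function(mat, what = c("difference", "mean_g1", "mean_g2")) {
  what <- match.arg(what)
  stopifnot(inherits(mat, "expression_matrix"))
  g <- mat$groups
  lv <- levels(g)
  m1 <- rowMeans(mat$exprs[, g == lv[1L], drop = FALSE])
  m2 <- rowMeans(mat$exprs[, g == lv[2L], drop = FALSE])
  v <- switch(what, difference = m2 - m1, mean_g1 = m1, mean_g2 = m2)
  names(v) <- rownames(mat$exprs)
  collapse_probes(v, mat$probe_gene)
}
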