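make_matrix <- function(vals, n_probes, groups = c("neo", "neo", "neo",
                                                   "w6", "w6", "w6"),
                        flags = NULL, probe_gene = NULL) {
  m <- matrix(vals, nrow = n_probes, ncol = length(groups),
              dimnames = list(paste0("p", seq_len(n_probes)),
                              paste0("s", seq_along(groups))))
  expression_matrix(m, groups, flags = flags, probe_gene = probe_gene)
}

test_that("normalisation floors at 1, aligns 75th percentiles, zeroes baselines", {
  # constant matrix of 1s -> all zeros after log, alignment and baseline
  m <- make_matrix(1, 10)
  nm <- normalize_expression(m)
  expect_true(all(nm$exprs == 0))
  # sub-threshold values floored to 1 before the log: 0.5 behaves like 1
  v <- c(0.5, rep(4, 11))
  nm_half <- normalize_expression(make_matrix(v, 2))
  nm_one <- normalize_expression(make_matrix(replace(v, 1, 1), 2))
  expect_identical(nm_half$exprs, nm_one$exprs)
  expect_identical(nm_half$log2_aligned, nm_one$log2_aligned)
  # scaling one sample by 2x is undone: 75th percentiles align
  set.seed(5)
  base <- matrix(2^rnorm(600, 8, 1), 100)
  scaled <- base
  scaled[, 3] <- scaled[, 3] * 2
  nm3 <- normalize_expression(make_matrix(scaled, 100))
  q75 <- apply(nm3$log2_aligned, 2, quantile, probs = 0.75)
  expect_true(all(abs(q75 - mean(q75)) < 1e-9))
  # per-probe median across samples is zero after baseline subtraction
  med <- apply(nm3$exprs, 1, median)
  expect_true(all(abs(med) < 1e-12))
})

test_that("detection filter keeps probes with at least one present call", {
  flags <- matrix("present", 3, 6)
  flags[1, ] <- "absent"                       # absent everywhere: removed
  flags[2, ] <- c("present", rep("absent", 5)) # one present: kept
  flags[3, ] <- "marginal"                     # marginal everywhere: removed
  m <- make_matrix(2, 3, flags = flags)
  expect_message(f <- filter_detected(m), "2 probe")
  expect_equal(rownames(f$exprs), "p2")
  # no flags: identity with warning
  m0 <- make_matrix(2, 3)
  expect_warning(f0 <- filter_detected(m0), "no detection flags")
  expect_identical(f0$exprs, m0$exprs)
})

test_that("differential testing recovers planted effects and respects nulls", {
  # identical groups: fold change 1, zero-variance flag, p = 1
  m <- make_matrix(rep(c(2, 4, 8), 6), 3)
  d <- differential(normalize_expression(m))
  expect_true(all(d$fold_change == 1))
  expect_true(all(d$flag == "zero_variance"))
  expect_true(all(d$p_raw == 1))
  # planted 2-fold shift with small noise is recovered at q < 0.05
  sim <- simulate_expression(300, planted_de = c(G0010 = 2), noise_sd = 0.05,
                             seed = 41)
  ds <- differential(normalize_expression(sim$matrix))
  expect_lt(ds$q_bh[ds$gene_id == "G0010"], 0.05)
  expect_gt(ds$fold_change[ds$gene_id == "G0010"], 1.5)
  # null p-values roughly uniform
  sim0 <- simulate_expression(2000, noise_sd = 0.3, seed = 43)
  d0 <- differential(normalize_expression(sim0$matrix))
  for (alpha in c(0.05, 0.2)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(d0))
    expect_lt(abs(mean(d0$p_raw < alpha) - alpha), 4 * se + 0.01)
  }
})

test_that("Welch variant is available and penalises unequal variances less df", {
  sim <- simulate_expression(50, noise_sd = 0.2, seed = 47)
  nm <- normalize_expression(sim$matrix)
  dp <- differential(nm, var_equal = TRUE)
  dw <- differential(nm, var_equal = FALSE)
  expect_false(identical(dp$p_raw, dw$p_raw))
  # both agree with stats::t.test on a sampled probe
  e <- nm$exprs[7, ]
  g <- nm$groups
  expect_equal(dw$p_raw[7],
               t.test(e[g == "g2"], e[g == "g1"], var.equal = FALSE)$p.value)
  expect_equal(dp$p_raw[7],
               t.test(e[g == "g2"], e[g == "g1"], var.equal = TRUE)$p.value)
})

test_that("BH correction matches the brute-force step-up rule", {
  # hand case: (0.01, 0.02, 0.03, 0.04) with m = 4 -> all 0.04
  expect_equal(naive_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(53)
  for (i in 1:100) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), naive_bh(p))
  }
  # q-values ordered by p are monotone non-decreasing and >= p
  sim <- simulate_expression(200, planted_de = c(G0001 = 3), noise_sd = 0.2,
                             seed = 59)
  d <- differential(normalize_expression(sim$matrix))
  o <- order(d$p_raw)
  expect_true(all(diff(d$q_bh[o]) >= -1e-15))
  expect_true(all(d$q_bh >= d$p_raw))
})

test_that("significant sets apply FDR and fold-change thresholds at gene level", {
  res <- data.frame(
    probe_id = paste0("p", 1:5),
    gene_id = c("gU", "gU", "gD", "gX", "gY"),
    fold_change = c(2.5, 2.2, -3, 1.8, -2.5),
    q_bh = c(0.04, 0.01, 0.02, 0.04, 0.2),
    flag = ""
  )
  s <- significant_sets(res, q_max = 0.05, min_abs_fc = 2)
  expect_equal(s$up, "gU")           # two probes dedup to one gene
  expect_equal(s$down, "gD")         # gX fails FC, gY fails FDR
  expect_equal(c(s$n_up, s$n_down), c(1L, 1L))
  # planted up/down sets are recovered with matching sizes
  fc <- c(setNames(rep(3, 10), sprintf("G%04d", 1:10)),
          setNames(rep(1 / 3, 15), sprintf("G%04d", 21:35)))
  sim <- simulate_expression(500, planted_de = fc, noise_sd = 0.05, seed = 61)
  d <- differential(normalize_expression(sim$matrix))
  s2 <- significant_sets(d)
  expect_equal(sort(s2$up), sprintf("G%04d", 1:10))
  expect_equal(sort(s2$down), sprintf("G%04d", 21:35))
})

test_that("probe collapse averages multi-probe genes and drops unmapped probes", {
  v <- c(pA1 = 2, pA2 = 4, pB = 7, pOrphan = 9)
  map <- c(pA1 = "gA", pA2 = "gA", pB = "gB")
  expect_message(out <- collapse_probes(v, map), "1 unmapped")
  expect_equal(out, c(gA = 3, gB = 7))
  # expression_vector composes collapse with group means
  sim <- simulate_expression(100, planted_de = c(G0005 = 4), noise_sd = 0.05,
                             seed = 67)
  nm <- normalize_expression(sim$matrix)
  ev <- expression_vector(nm, "difference")
  expect_equal(length(ev), 100L)
  expect_equal(unname(which.max(ev)), match("G0005", names(ev)))
})
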