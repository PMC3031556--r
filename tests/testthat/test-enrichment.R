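test_that("background estimation pools non-N nucleotide frequencies", {
  co <- transcript_corpus("g1", "t1", "ACGTACG")
  bg <- estimate_background(co)
  expect_equal(unname(bg$freq),
               c(2, 2, 2, 1) / 7)
  co2 <- transcript_corpus(c("g1", "g2"), c("t1", "t2"),
                           c("AAAANNN", "AAAAAAA"))
  bg2 <- estimate_background(co2)
  expect_equal(unname(bg2$freq), c(1, 0, 0, 0))
  expect_equal(bg2$corpus_size, 11)  # N excluded from the denominator
  expect_error(estimate_background(transcript_corpus("g", "t", "NNNNNNN")),
               "no non-N")
})

test_that("background estimates converge to the sampling composition", {
  set.seed(7)
  p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  n <- 2e5
  s <- paste(sample(names(p), n, TRUE, prob = p), collapse = "")
  bg <- estimate_background(transcript_corpus("g", "t", s))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(bg$freq - p) < 3 * se))
})

test_that("motif start probability is the product of background frequencies", {
  expect_equal(motif_probability("TGGTGCT", uniform_background()), 0.25^7)
  expect_equal(0.25^7, 6.103515625e-05)
  bg <- background_model(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  # hand product for TGGTGCT: T,G,G,T,G,C,T -> .3*.2*.2*.3*.2*.2*.3
  expect_equal(motif_probability("TGGTGCT", bg), 4.32e-05)
  bg0 <- background_model(c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(motif_probability("TTTTTTT", bg0), 0)
  expect_error(background_model(c(A = 0.5, C = 0.5, G = 0.1, T = 0)), "sum to 1")
})

test_that("Poisson tail has the closed forms and monotonicity of a survival fn", {
  expect_equal(poisson_tail(0, 5000, 0.25^7)$p_value, 1.0)
  # single start position: P(X >= 1) = 1 - exp(-lambda), lambda = 4^-7
  pt1 <- poisson_tail(1, 7, 0.25^7)
  expect_equal(pt1$lam, 0.25^7)
  expect_equal(pt1$p_value, 1 - exp(-0.25^7))
  expect_error(poisson_tail(1, 6, 0.1), "shorter than the motif")
  # non-increasing in k at fixed lambda; non-decreasing in lambda at fixed k
  ps <- vapply(0:10, function(k) poisson_tail(k, 1000, 1e-4)$p_value, 1)
  expect_true(all(diff(ps) < 0))
  pl <- vapply(c(100, 500, 2000, 8000), function(L)
    poisson_tail(3, L, 1e-4)$p_value, 1)
  expect_true(all(diff(pl) > 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("per-gene enrichment composes count, background and Poisson tail", {
  plant <- data.frame(gene = 1, motif = "TGGTGCT", region = "CDS", count = 10)
  sim <- simulate_transcripts(1, length_range = c(3000, 3000),
                              composition = "uniform", plant = plant, seed = 13)
  rec <- sim$corpus[1, ]
  res <- enrich_gene(rec, "TGGTGCT", uniform_background())
  expect_equal(res$k, 10L)
  expect_equal(res$L, 3000L)
  expect_equal(res$p_value, poisson_tail(10, 3000, 0.25^7)$p_value)
  # zero-site gene
  sim0 <- simulate_transcripts(1, plant = data.frame(
    gene = 1, motif = "TGGTGCT", region = "CDS", count = 0), seed = 14)
  expect_equal(enrich_gene(sim0$corpus[1, ], "TGGTGCT",
                           uniform_background())$p_value, 1.0)
  # doubling L at fixed k makes the count less surprising
  r1 <- poisson_tail(5, 2000, 0.25^7)$p_value
  r2 <- poisson_tail(5, 4000, 0.25^7)$p_value
  expect_gt(r2, r1)
})

test_that("family-wide scan ranks the planted seed first and is order-invariant", {
  fam <- simulate_family_table(40, seed = 8)
  fam_df <- data.frame(family_name = fam$family, seed7 = fam$seed)
  plant <- data.frame(gene = 1, motif = "TGGTGCT", region = "CDS", count = 8)
  sim <- simulate_transcripts(1, plant = plant, seed = 15)
  bg <- estimate_background(sim$corpus)
  res <- enrich_families_for_gene(sim$corpus[1, ], fam_df, bg)
  expect_equal(res$seed7[1], "AGCACCA")  # planted miR-29 seed most significant
  expect_lt(res$p_value[1], min(res$p_value[-1]))
  # permuting family order leaves results identical
  res2 <- enrich_families_for_gene(sim$corpus[1, ],
                                   fam_df[rev(seq_len(nrow(fam_df))), ], bg)
  expect_equal(res2, res)
  # motif-free sequence: k = 0 everywhere, all p-values 1
  sim0 <- simulate_transcripts(1, plant = data.frame(
    gene = 1, motif = "TGGTGCT", region = "CDS", count = 0), seed = 16)
  res0 <- enrich_gene(sim0$corpus[1, ], "TGGTGCT", bg)
  expect_equal(res0$p_value, 1.0)
})

test_that("corpus-wide enrichment ranks a heavily planted gene first", {
  plant <- data.frame(gene = 1, motif = "TGGTGCT", region = "CDS", count = 12)
  sim <- simulate_transcripts(30, plant = plant, seed = 17)
  bg <- estimate_background(sim$corpus)
  res <- enrich_corpus_for_motif(sim$corpus, "TGGTGCT", bg)
  expect_equal(nrow(res), 30L)
  expect_equal(res$gene_id[1], "G0001")
  # filtered view keeps exactly the k >= 1 genes; histogram conserves them
  res1 <- enrich_corpus_for_motif(sim$corpus, "TGGTGCT", bg, min_count = 1)
  expect_true(all(res1$k >= 1))
  h <- neg_log10_histogram(res1$p_value)
  expect_equal(sum(h$n), nrow(res1))
  # Bonferroni column is a monotone rescaling capped at 1
  expect_true(all(res$p_bonferroni >= res$p_value & res$p_bonferroni <= 1))
})

test_that("null-corpus enrichment p-values are near-uniform or conservative", {
  sim <- simulate_transcripts(400, length_range = c(800, 1200),
                              composition = "uniform", seed = 19)
  bg <- uniform_background()
  res <- enrich_corpus_for_motif(sim$corpus, "TGGTGCT", bg)
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(res$p_value < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lte(frac, alpha + 3 * se)
  }
})

test_that("binomial tail matches the exact summation oracle", {
  expect_equal(binomial_tail(0, 30, 0.3)$p_value, 1.0)
  # independent oracle: direct summation of the pmf
  brute <- function(k, n, p) sum(dbinom(k:n, n, p))
  for (cfg in list(c(20, 30, 54 / 567), c(16, 17, 78 / 134),
                   c(3, 10, 0.5), c(7, 7, 0.9))) {
    expect_equal(binomial_tail(cfg[1], cfg[2], cfg[3])$p_value,
                 brute(cfg[1], cfg[2], cfg[3]))
  }
  expect_error(binomial_tail(2, 10, 1.2), "0, 1")
  expect_error(binomial_tail(11, 10, 0.5))
})
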