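test_that("prepare_codon_alignment validates frame, stops and ambiguity", {
  tp <- toy_codon_pair()
  aln <- prepare_codon_alignment(tp$a, tp$b)
  expect_equal(aln$n_codons, 12L)
  expect_equal(aln$n_dropped, 0L)
  # an NNN codon drops the column from both sequences
  a2 <- sub("CCC", "NNN", tp$a)
  aln2 <- prepare_codon_alignment(a2, tp$b)
  expect_equal(aln2$n_codons, 11L)
  expect_equal(aln2$n_dropped, 1L)
  # internal stop is invalid; terminal stop is stripped
  expect_error(prepare_codon_alignment("ATGTAACCC", "ATGAAACCC"),
               class = "bgcsel_invalid_cds")
  aln3 <- prepare_codon_alignment("ATGAAATAA", "ATGAAATAA")
  expect_equal(aln3$n_codons, 2L)
  expect_error(prepare_codon_alignment("ATGAA", "ATGAA"), class = "bgcsel_frame")
  expect_error(prepare_codon_alignment("", "ATG"), class = "bgcsel_validation")
})

test_that("FASTA pair reading feeds the alignment builder", {
  tp <- toy_codon_pair()
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">col0", tp$a, ">lyrata", tp$b), f)
  aln <- read_codon_pair_fasta(f)
  expect_equal(aln$id_a, "col0")
  expect_equal(aln$n_codons, 12L)
  writeLines(c(">only_one", tp$a), f)
  expect_error(read_codon_pair_fasta(f), class = "bgcsel_format")
})

test_that("ng86 equals the pathway-enumeration oracle on fixtures", {
  tp <- toy_codon_pair()
  aln <- prepare_codon_alignment(tp$a, tp$b)
  res <- ng86(aln)
  or <- ng86_oracle(aln)
  expect_equal(res$N, or$N, tolerance = 1e-12)
  expect_equal(res$S, or$S, tolerance = 1e-12)
  expect_equal(res$Nd, or$Nd, tolerance = 1e-12)
  expect_equal(res$Sd, or$Sd, tolerance = 1e-12)
  expect_equal(res$dN, or$dN, tolerance = 1e-12)
  expect_equal(res$dS, or$dS, tolerance = 1e-12)
  expect_equal(res$Nd, 1)  # one nonsynonymous difference
  expect_equal(res$Sd, 1)  # one synonymous difference
  # random simulated alignments, including multi-hit codons
  for (seed in 1:4) {
    a <- simulate_codon_pair(80, 0.8, 2, 0.7, seed = seed)
    r <- ng86(a); o <- ng86_oracle(a)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-10)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-10)
    expect_equal(r$S, o$S, tolerance = 1e-10)
    expect_equal(r$N + r$S, 3 * a$n_codons, tolerance = 1e-9)
  }
})

test_that("ng86 degenerate and forced-classification cases", {
  # identical sequences
  aln <- prepare_codon_alignment("ATGAAACCC", "ATGAAACCC")
  res <- ng86(aln)
  expect_equal(res$dN, 0); expect_equal(res$dS, 0)
  expect_true("undefined_omega" %in% res$flags)
  # a single third-position synonymous transition among 100 codons
  a <- paste(rep("ATCGAACTG", 34), collapse = "")  # 102 codons
  b <- sub("GAACTG", "GAGCTG", a)  # GAA -> GAG, Glu, synonymous
  r <- ng86(prepare_codon_alignment(a, b))
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
})

test_that("gy94_loglik matches the independent matrix-exponential oracle", {
  f_eq <- equal_codon_freqs()
  cases <- list(c(t = 0.2, k = 2, w = 0.5), c(t = 0.7, k = 4, w = 1.5),
                c(t = 0.05, k = 1, w = 1))
  for (seed in seq_along(cases)) {
    p <- cases[[seed]]
    aln <- simulate_codon_pair(40, 0.4, 2, 0.5, seed = seed)
    f34 <- f3x4_freqs(aln)
    for (f in list(f_eq, f34)) {
      expect_equal(gy94_loglik(aln, p[["t"]], p[["k"]], p[["w"]], f),
                   gy94_loglik_oracle(aln, p[["t"]], p[["k"]], p[["w"]], f),
                   tolerance = 1e-8)
    }
  }
  # reversibility: swapping the sequences leaves the likelihood unchanged
  aln <- simulate_codon_pair(60, 0.3, 2, 0.4, seed = 9)
  rev <- structure(list(seq_a = aln$seq_b, seq_b = aln$seq_a,
                        n_codons = aln$n_codons, n_dropped = 0L,
                        id_a = "b", id_b = "a"), class = "codon_alignment")
  expect_equal(gy94_loglik(aln, 0.3, 2, 0.4, f_eq),
               gy94_loglik(rev, 0.3, 2, 0.4, f_eq), tolerance = 1e-10)
  # t -> 0 limit for identical sequences: sum of log pi
  same <- prepare_codon_alignment("ATGAAACCCGGG", "ATGAAACCCGGG")
  expect_equal(gy94_loglik(same, 1e-9, 2, 0.5, f_eq),
               4 * log(1 / 61), tolerance = 1e-6)
  expect_error(gy94_loglik(same, 0.1, 2, 0.5, rep(1, 61)),
               class = "bgcsel_validation")
})

test_that("fit_pairwise_ml recovers parameters and honors fix_omega", {
  aln <- simulate_codon_pair(2000, 0.3, 2, 0.2, seed = 31)
  fit <- fit_pairwise_ml(aln, codon_freqs = equal_codon_freqs())
  expect_equal(fit$convergence, 0L)
  expect_lt(abs(fit$omega - 0.2) / 0.2, 0.25)
  expect_lt(abs(fit$t - 0.3) / 0.3, 0.25)
  expect_lt(abs(fit$kappa - 2) / 2, 0.35)
  # nested models: free likelihood is never below the null
  null <- fit_pairwise_ml(aln, fix_omega = 1, codon_freqs = equal_codon_freqs())
  expect_gte(fit$logL + 1e-6, null$logL)
  expect_equal(null$omega, 1)
  # identical sequences sit at the t boundary; fixing omega changes nothing
  same <- prepare_codon_alignment(strrep("ATGGAT", 20), strrep("ATGGAT", 20))
  b1 <- fit_pairwise_ml(same)
  b2 <- fit_pairwise_ml(same, fix_omega = 1)
  expect_true("boundary" %in% b1$flags)
  expect_equal(b1$logL, b2$logL, tolerance = 1e-9)
  # estimates invariant to sequence order
  revn <- structure(list(seq_a = aln$seq_b, seq_b = aln$seq_a,
                         n_codons = aln$n_codons, n_dropped = 0L,
                         id_a = "b", id_b = "a"), class = "codon_alignment")
  fit_rev <- fit_pairwise_ml(revn, codon_freqs = equal_codon_freqs())
  expect_equal(fit_rev$omega, fit$omega, tolerance = 1e-4)
  expect_equal(fit_rev$logL, fit$logL, tolerance = 1e-6)
})

test_that("lrt_omega: degenerate input, clamping, and the 0.001 flag", {
  same <- prepare_codon_alignment(strrep("ATGGATCAA", 15), strrep("ATGGATCAA", 15))
  r <- lrt_omega(same)
  expect_equal(r$lrt_stat, 0)
  expect_equal(r$p_value, 1)
  # strong purifying signal is detected far below the 0.001 threshold
  aln <- simulate_codon_pair(1500, 0.3, 2, 0.1, seed = 77)
  r2 <- lrt_omega(aln, n_starts = 1)
  expect_lt(r2$p_value, 1e-3)
  expect_true(r2$significant_001)
  expect_lt(r2$omega, 0.3)
  expect_equal(r2$omega, r2$dN / r2$dS, tolerance = 1e-6)
})

test_that("NG86 and ML omega agree at low divergence", {
  # the two estimators are interchangeable in the low-divergence regime
  rel_diff <- vapply(1:5, function(seed) {
    aln <- simulate_codon_pair(1200, 0.15, 2, 0.4, seed = 100 + seed)
    w_ml <- fit_pairwise_ml(aln, n_starts = 1)$omega
    w_ng <- ng86(aln)$omega
    abs(w_ml - w_ng) / w_ml
  }, numeric(1))
  expect_lt(median(rel_diff), 0.25)
})
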