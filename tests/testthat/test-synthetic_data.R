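# The panel generator checks use a scaled-down configuration (N = 100,
# 20 kb, theta = 20) so the whole file runs in seconds; the closed-form
# neutral expectations hold for any configuration.
small_cfg <- function(seed, opts = list()) {
  args <- utils::modifyList(
    list(pop_size = 100L, chrom_length = 20000L, mu = 5e-6,
         rec = 1e-5, n_sample = 50L, seed = seed),
    opts)
  do.call(sweep_sim_config, args)
}

test_that("simulate_panel is a pure function of (config, seed)", {
  s1 <- simulate_panel(small_cfg(11))
  s2 <- simulate_panel(small_cfg(11))
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_panel(small_cfg(12))
  expect_false(identical(s1$matrix$pos, s3$matrix$pos))
  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_panel(small_cfg(11))); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate configurations behave per contract", {
  # no mutation: no segregating sites
  none <- simulate_panel(small_cfg(1, list(mu = 0)))
  expect_equal(n_sites(none$matrix), 0L)
  # sampling more than the population errors
  expect_error(simulate_panel(small_cfg(1, list(n_sample = 200L))),
               class = "bgcsel_sampling")
  # an unfixable sweep exhausts its restarts
  expect_error(
    simulate_panel(sweep_sim_config(pop_size = 50L, chrom_length = 1000L,
                                    mu = 1e-5, rec = 0, s = 1e-9,
                                    n_sample = 10L, burn_in = 10L,
                                    max_restarts = 0L, seed = 3)),
    class = "bgcsel_fixation_failure")
  expect_error(sweep_sim_config(s = -1), class = "bgcsel_validation")
  expect_error(sweep_sim_config(focal_pos = 1e9), class = "bgcsel_validation")
})

test_that("neutral segregating sites match the Watterson expectation", {
  cfg <- small_cfg(1)
  theta <- 2 * cfg$pop_size * cfg$mu * cfg$chrom_length
  expected <- theta * sum(1 / seq_len(cfg$n_sample - 1))
  S <- vapply(1:50, function(sd) n_sites(simulate_panel(small_cfg(sd))$matrix),
              integer(1))
  expect_lt(abs(mean(S) - expected) / expected, 0.15)
})

test_that("panel output satisfies snp_matrix invariants and round-trips", {
  sim <- simulate_panel(small_cfg(21))
  m <- sim$matrix
  expect_true(all(diff(m$pos) > 0))
  expect_true(all(m$geno %in% c(0L, 1L)))
  # every emitted site is segregating in the sample
  f <- rowMeans(m$geno)
  expect_true(all(f > 0 & f < 1))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_snp_tsv(m, tf)
  expect_identical(load_variants(tf)$geno, m$geno)
})

test_that("sweep runs carry truth records and reduce focal diversity", {
  sw <- simulate_panel(small_cfg(31, list(s = 2, fix_freq = 0.5, post_fix = 0L)))
  expect_false(is.na(sw$truth$fixation_gen))
  traj <- sw$truth$trajectory
  expect_gte(traj[length(traj)], 0.5)
  expect_equal(traj[1], 1 / 100)
  # paired diversity contrast around the focal position over seed pairs;
  # a completed sweep gives the cleanest trough at this scale
  pis <- t(sapply(1:20, function(sd) {
    neu <- simulate_panel(small_cfg(sd))$matrix
    swp <- simulate_panel(small_cfg(1000 + sd, list(s = 2, post_fix = 0L)))$matrix
    c(neu = nucleotide_diversity(neu, 8000, 12000),
      swp = nucleotide_diversity(swp, 8000, 12000))
  }))
  expect_lt(mean(pis[, "swp"]), mean(pis[, "neu"]))
})

test_that("codon-pair simulator: identity at t = 0, divergence grows with t", {
  a0 <- simulate_codon_pair(200, 0, 2, 0.5, seed = 1)
  expect_identical(a0$seq_a, a0$seq_b)
  expect_identical(simulate_codon_pair(100, 0.3, 2, 0.5, seed = 4)$seq_a,
                   simulate_codon_pair(100, 0.3, 2, 0.5, seed = 4)$seq_a)
  pdiff <- function(t, seed) {
    a <- simulate_codon_pair(300, t, 2, 1, seed = seed)
    ca <- substring(a$seq_a, seq(1, nchar(a$seq_a), 3), seq(3, nchar(a$seq_a), 3))
    cb <- substring(a$seq_b, seq(1, nchar(a$seq_b), 3), seq(3, nchar(a$seq_b), 3))
    mean(ca != cb)
  }
  d <- sapply(c(0.05, 0.2, 0.8), function(t) mean(sapply(1:15, pdiff, t = t)))
  expect_true(all(diff(d) > 0))
  expect_error(simulate_codon_pair(10, -1, 2, 1), class = "bgcsel_validation")
})

test_that("mk-table simulator hits its stated expectations", {
  s1 <- simulate_mk_table(mk_sim_config(seed = 8))
  s2 <- simulate_mk_table(mk_sim_config(seed = 8))
  expect_identical(s1$poly, s2$poly)
  expect_identical(s1$div$Dn, s2$div$Dn)
  # neutral construction: E[Dn/Ds] matches E[Pn/Ps]
  cfg <- mk_sim_config(true_alpha = 0, theta = 0.5, lambda = 0.5, seed = 1)
  tabs <- lapply(1:40, function(sd)
    simulate_mk_table(mk_sim_config(true_alpha = 0, theta = 0.5, lambda = 0.5,
                                    seed = sd)))
  pn <- sapply(tabs, function(x) sum(x$poly$class == "nonsynonymous"))
  ps <- sapply(tabs, function(x) sum(x$poly$class == "synonymous"))
  dn <- sapply(tabs, function(x) x$div$Dn)
  ds <- sapply(tabs, function(x) x$div$Ds)
  expect_lt(abs(mean(dn) / mean(ds) - mean(pn) / mean(ps)), 0.07)
  expect_error(mk_sim_config(true_alpha = 1.2), class = "bgcsel_validation")
})
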