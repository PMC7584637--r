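test_that("r_squared matches hand values and the naive Pearson oracle", {
  expect_equal(r_squared(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(r_squared(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  # hand-computable: Sxy = 7/8, Sxx = Syy = 15/8, r = 7/15
  expect_equal(r_squared(c(0, 0, 0, 1, 1, 1, 1, 1),
                         c(0, 0, 1, 1, 1, 1, 1, 0)), 49 / 225,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    if (i %% 5 == 0) a[sample(n, 2)] <- NA  # exercise pairwise deletion
    ok <- !is.na(a) & !is.na(b)
    if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2) next
    expect_equal(r_squared(a, b), naive_r2(a, b), tolerance = 1e-12)
    # symmetry and label-swap invariance
    expect_equal(r_squared(b, a), r_squared(a, b), tolerance = 1e-12)
    expect_equal(r_squared(1 - a, b), r_squared(a, b), tolerance = 1e-12)
  }
  expect_error(r_squared(c(0, 0, 0), c(0, 1, 0)), class = "bgcsel_undefined_ld")
})

test_that("fisher_association matches the enumeration oracle", {
  # [[2,0],[0,2]] -> 1/3 by direct enumeration over the support {0,1,2}
  expect_equal(fisher_association(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_2x2_oracle(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  # balanced table: no association
  a <- rep(c(0, 1), each = 10)
  b <- rep(c(0, 1, 0, 1), each = 5)
  expect_equal(fisher_association(a, b), 1.0)
  set.seed(7)
  for (i in 1:50) {
    x <- rbinom(20, 1, 0.5); y <- rbinom(20, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    p <- fisher_association(x, y)
    tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
    expect_equal(p, fisher_2x2_oracle(unclass(tab)), tolerance = 1e-9)
    expect_gt(p, 0); expect_lte(p, 1)
    # invariance under swapping rows/columns of the table
    expect_equal(fisher_association(1 - x, y), p, tolerance = 1e-12)
    expect_equal(fisher_association(x, 1 - y), p, tolerance = 1e-12)
  }
})

test_that("build_neighborhoods merges tandem loci and inherits labels", {
  # single locus: span = body +/- flank
  one <- locus_table("g1", "chr1", 1000, 2000)
  gn1 <- build_neighborhoods(one, flank_bp = 50000)
  expect_equal(nrow(gn1), 1L)
  expect_equal(gn1$start, 0)  # clamped at 0
  expect_equal(gn1$end, 52000)
  # two loci 1 Mb apart stay separate
  two <- locus_table(c("g1", "g2"), "chr1", c(1000, 1001000), c(2000, 1002000))
  expect_equal(nrow(build_neighborhoods(two, tandem_merge_bp = 50000)), 2L)
  # conflicting labels in a merged pair error out
  bad <- locus_table(c("g1", "g2"), "chr1", c(1000, 3000), c(2000, 4000),
                     c("clustered", "non_clustered"))
  expect_error(build_neighborhoods(bad), class = "bgcsel_label_conflict")
})

test_that("the 13 focal loci collapse to 9 neighborhoods (4 + 5)", {
  loci <- read_loci_bed(osc_bed_path())
  gn <- build_neighborhoods(loci, flank_bp = 50000, tandem_merge_bp = 50000)
  expect_equal(nrow(gn), 9L)
  expect_equal(sum(gn$group_label == "clustered"), 4L)
  expect_equal(sum(gn$group_label == "non_clustered"), 5L)
  # the two tandem sets merged into single neighborhoods
  sizes <- lengths(gn$focal_loci)
  expect_setequal(sizes[sizes > 1], c(2L, 4L))
  # span covers every focal gene body with the flank
  for (i in seq_len(nrow(gn))) {
    body <- loci[loci$locus_id %in% gn$focal_loci[[i]], ]
    expect_true(all(body$start - 50000 >= gn$start[i] - 1e-9))
    expect_true(all(body$end + 50000 <= gn$end[i] + 1e-9))
  }
})

test_that("window_ld_pairs matches an all-pairs brute-force recomputation", {
  m <- random_panel(60, 30, seed = 11)
  gn <- list(gn_id = "w", chrom = "chr1", start = 0, end = 2e6)
  tab <- window_ld_pairs(m, gn, r2_threshold = 0.1, maf_min = 0.05)
  # brute force over all pairs after the same MAF filter
  mf <- filter_sites(m, maf_min = 0.05, max_missing = 1)
  hits <- 0L
  for (i in seq_len(n_sites(mf) - 1)) for (j in (i + 1):n_sites(mf)) {
    r2 <- tryCatch(r_squared(mf$geno[i, ], mf$geno[j, ]), error = function(e) NA)
    if (!is.na(r2) && r2 > 0.1) hits <- hits + 1L
  }
  expect_equal(nrow(tab), hits)
  expect_true(all(tab$site_i < tab$site_j))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_equal(tab$distance_bp, abs(tab$pos_j - tab$pos_i))
  # per-row fisher p agrees with the direct call
  k <- which.max(tab$r2)
  expect_equal(tab$fisher_p[k],
               fisher_association(mf$geno[tab$site_i[k], ], mf$geno[tab$site_j[k], ]))
})

test_that("degenerate windows and identical/orthogonal sites behave per contract", {
  # 3 identical sites -> C(3,2) pairs, all r2 = 1
  g <- matrix(rep(c(0L, 0L, 1L, 1L), 3), 3, 4, byrow = TRUE)
  m <- snp_matrix(rep("c", 3), c(10L, 20L, 30L), rep("A", 3), rep("G", 3), g,
                  sprintf("s%d", 1:4))
  tab <- window_ld_pairs(m, list(gn_id = "x", chrom = "c", start = 0, end = 100),
                         maf_min = 0)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$r2 == 1))
  expect_equal(gn_ld_count(tab), 3L)
  # mutually orthogonal balanced sites -> nothing retained
  g2 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  m2 <- snp_matrix(rep("c", 2), c(10L, 20L), rep("A", 2), rep("G", 2), g2,
                   sprintf("s%d", 1:4))
  expect_equal(gn_ld_count(window_ld_pairs(
    m2, list(gn_id = "x", chrom = "c", start = 0, end = 100), maf_min = 0)), 0L)
  # < 2 usable sites -> empty table, not an error
  expect_equal(gn_ld_count(window_ld_pairs(
    m2, list(gn_id = "x", chrom = "c", start = 500, end = 600), maf_min = 0)), 0L)
})

test_that("gn_ld_count is monotone non-increasing in the threshold", {
  m <- random_panel(50, 25, seed = 3)
  gn <- list(gn_id = "w", chrom = "chr1", start = 0, end = 2e6)
  counts <- vapply(c(0, 0.05, 0.1, 0.3, 0.6, 0.9), function(th)
    gn_ld_count(window_ld_pairs(m, gn, r2_threshold = th,
                                compute_fisher = FALSE)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("compare_gn_groups implements the pooled Student t-test", {
  cmp <- compare_gn_groups(c(10, 14, 9, 12, 3, 4, 5, 2, 6),
                           c(rep("clustered", 4), rep("non_clustered", 5)))
  expect_equal(cmp$df, 7L)
  tt <- t.test(c(10, 14, 9, 12), c(3, 4, 5, 2, 6), var.equal = TRUE)
  expect_equal(cmp$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_two_sided, tt$p.value, tolerance = 1e-12)
  # identical constant groups: t = 0, p = 1
  cmp0 <- compare_gn_groups(rep(3, 6), rep(c("clustered", "non_clustered"), each = 3))
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_two_sided, 1)
  expect_equal(cmp0$df, 4L)
  # zero variance with different means is degenerate
  expect_error(compare_gn_groups(c(10, 10, 0, 0),
                                 rep(c("clustered", "non_clustered"), each = 2)),
               class = "bgcsel_degenerate_variance")
})

test_that("ld_decay_loess recovers a smooth generating curve and clamps", {
  # constant response
  tab <- data.frame(distance_bp = seq(100, 10000, length.out = 50),
                    r2 = rep(0.4, 50))
  dec <- ld_decay_loess(tab)
  expect_true(all(abs(dec$r2_smooth - 0.4) < 1e-8))
  # noiseless hyperbolic decay sampled at 200 distances
  d <- seq(100, 50000, length.out = 200)
  tab2 <- data.frame(distance_bp = d, r2 = 1 / (1 + d / 10000))
  dec2 <- ld_decay_loess(tab2, span = 0.2)
  interior <- dec2$distance_bp > quantile(d, 0.05) &
    dec2$distance_bp < quantile(d, 0.95)
  truth <- 1 / (1 + dec2$distance_bp / 10000)
  expect_true(max(abs(dec2$r2_smooth - truth)[interior]) < 0.02)
  expect_true(all(dec2$r2_smooth >= 0 & dec2$r2_smooth <= 1))
  # too few pairs
  expect_error(ld_decay_loess(tab2[1:5, ]), class = "bgcsel_insufficient_data")
})
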