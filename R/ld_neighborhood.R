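# Linkage-disequilibrium enrichment across focal genomic neighborhoods.
#
# The whole-cluster selection scan: a genomic neighborhood (GN) is a focal
# gene (or merged tandem set) extended by a fixed flank on each side
# (50 kb by convention). Within each GN every unordered pair of biallelic
# sites is scored by r^2 (squared allele-frequency correlation); pairs with
# r^2 above a threshold (0.1 by convention) are counted, and the per-GN
# counts of clustered vs non-clustered focal genes are compared by a
# pooled-variance Student t-test. Elevated counts around a cluster are the
# hitch-hiking signature of a recent selective sweep.

#' Squared allele-frequency correlation between two sites
#'
#' r^2 = D^2 / (p_a (1-p_a) p_b (1-p_b)) with D = p_ab - p_a p_b, computed
#' on haplotype counts after pairwise deletion of missing calls. For
#' haploid-coded 0/1 vectors this equals the squared Pearson correlation.
#'
#' @param hap_a,hap_b Integer 0/1 vectors (NA = missing) of equal length.
#' @return r^2 in \[0, 1\].
#' @export
r_squared <- function(hap_a, hap_b) {
  cc <- ld_complete(hap_a, hap_b)
  a <- cc$a; b <- cc$b
  pa <- mean(a); pb <- mean(b)
  pab <- mean(a & b)
  d <- pab - pa * pb
  d * d / (pa * (1 - pa) * pb * (1 - pb))
}

ld_complete <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b))
    bgcsel_stop("validation", "haplotype vectors differ in length")
  ok <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[ok]; b <- hap_b[ok]
  if (length(a) < 2L)
    bgcsel_stop("undefined_ld", "fewer than 2 complete haplotype pairs")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    bgcsel_stop("undefined_ld", "site monomorphic after pairwise deletion")
  list(a = a, b = b)
}

#' Fisher's exact test of association between two sites
#'
#' Two-sided exact p on the 2x2 haplotype count table (sum of hypergeometric
#' point probabilities not exceeding the observed table's probability).
#'
#' @inheritParams r_squared
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_association <- function(hap_a, hap_b) {
  cc <- ld_complete(hap_a, hap_b)
  tab <- table(factor(cc$a, levels = 0:1), factor(cc$b, levels = 0:1))
  fisher.test(tab)$p.value
}

#' Build genomic neighborhoods from a locus table
#'
#' Loci on the same chromosome whose gene bodies lie within
#' `tandem_merge_bp` of each other are merged (transitively) into one
#' neighborhood, mirroring the treatment of tandem-duplicated focal genes
#' as a single locus. The neighborhood span is the union of merged gene
#' bodies extended by `flank_bp` on each side (clamped at 0).
#'
#' @param loci A [locus_table()].
#' @param flank_bp Flank size in bp on each side (default 50000).
#' @param tandem_merge_bp Maximum gap between gene bodies merged as a tandem
#'   set (default 50000).
#' @return A `data.frame` of class `gn_table` with columns `gn_id`, `chrom`,
#'   `start`, `end` (span, 0-based half-open), `group_label`, and a
#'   list-column `focal_loci`.
#' @export
build_neighborhoods <- function(loci, flank_bp = 50000, tandem_merge_bp = 50000) {
  if (!inherits(loci, "locus_table")) loci <- do.call(locus_table, as.list(loci))
  if (flank_bp <= 0)
    bgcsel_stop("validation", "flank_bp must be positive")
  o <- order(loci$chrom, loci$start)
  loci <- loci[o, , drop = FALSE]
  # transitive merge along each chromosome
  grp <- integer(nrow(loci)); g <- 0L
  last_chrom <- ""; last_end <- -Inf
  for (i in seq_len(nrow(loci))) {
    if (loci$chrom[i] != last_chrom ||
        loci$start[i] - last_end > tandem_merge_bp) {
      g <- g + 1L
      last_end <- loci$end[i]
    } else {
      last_end <- max(last_end, loci$end[i])
    }
    grp[i] <- g
    last_chrom <- loci$chrom[i]
  }
  out <- lapply(split(seq_len(nrow(loci)), grp), function(idx) {
    lab <- unique(loci$group_label[idx][!is.na(loci$group_label[idx])])
    if (length(lab) > 1L)
      bgcsel_stop("label_conflict",
                  "merged loci %s carry conflicting group labels",
                  paste(loci$locus_id[idx], collapse = "+"))
    data.frame(gn_id = paste(loci$locus_id[idx], collapse = "+"),
               chrom = loci$chrom[idx[1L]],
               start = max(0, min(loci$start[idx]) - flank_bp),
               end = max(loci$end[idx]) + flank_bp,
               group_label = if (length(lab)) lab else NA_character_,
               stringsAsFactors = FALSE)
  })
  gn <- do.call(rbind, out)
  rownames(gn) <- NULL
  gn$focal_loci <- unname(lapply(split(loci$locus_id, grp), identity))
  class(gn) <- c("gn_table", "data.frame")
  gn
}

#' Enumerate thresholded LD pairs within one neighborhood
#'
#' Evaluates r^2 for every unordered pair of usable sites inside the
#' neighborhood span and retains pairs with `r2 > r2_threshold`. Sites are
#' first filtered to biallelic with MAF >= `maf_min`; pairs that are
#' monomorphic after pairwise deletion of missing calls are skipped.
#'
#' @param m A `snp_matrix`.
#' @param gn One row of a `gn_table` (or any list with `gn_id`, `chrom`,
#'   `start`, `end`).
#' @param r2_threshold Retention threshold on r^2 (default 0.1; pairs must
#'   exceed it strictly).
#' @param maf_min Site MAF filter applied within the span (default 0.05).
#' @param compute_fisher Attach a two-sided Fisher exact p to each retained
#'   pair (default `TRUE`; disable in large calibration loops where only
#'   the count is used).
#' @param top_k Optional per-site cap: keep for each site only its `top_k`
#'   strongest retained pairs (default `NULL` = no cap; the full pair set is
#'   the statistic of record).
#' @return A `data.frame` of class `ld_pair_table` with columns `site_i`,
#'   `site_j`, `pos_i`, `pos_j`, `distance_bp`, `r2`, `fisher_p`;
#'   attributes `gn_id` and `r2_threshold`.
#' @export
window_ld_pairs <- function(m, gn, r2_threshold = 0.1, maf_min = 0.05,
                            compute_fisher = TRUE, top_k = NULL) {
  span_keep <- m$chrom == gn$chrom & m$pos > gn$start & m$pos <= gn$end
  sub <- subset_sites(m, span_keep)
  sub <- filter_sites(sub, maf_min = maf_min, biallelic_only = TRUE,
                      max_missing = 1)
  empty <- function() {
    structure(data.frame(site_i = integer(), site_j = integer(),
                         pos_i = integer(), pos_j = integer(),
                         distance_bp = integer(), r2 = numeric(),
                         fisher_p = numeric()),
              gn_id = gn$gn_id, r2_threshold = r2_threshold,
              class = c("ld_pair_table", "data.frame"))
  }
  s <- n_sites(sub)
  if (s < 2L) return(empty())
  # r^2 for 0/1 haplotypes is the squared Pearson correlation; pairwise
  # deletion of missing calls matches use = "pairwise.complete.obs".
  g <- t(sub$geno)
  r2 <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
  ij <- which(upper.tri(r2) & !is.na(r2) & r2 > r2_threshold, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(empty())
  i <- ij[, 1L]; j <- ij[, 2L]
  fp <- rep(NA_real_, length(i))
  if (compute_fisher)
    fp <- vapply(seq_along(i), function(k)
      fisher_association(sub$geno[i[k], ], sub$geno[j[k], ]), numeric(1))
  tab <- data.frame(site_i = i, site_j = j,
                    pos_i = sub$pos[i], pos_j = sub$pos[j],
                    distance_bp = abs(sub$pos[j] - sub$pos[i]),
                    r2 = r2[cbind(i, j)], fisher_p = fp)
  if (!is.null(top_k)) {
    keep <- logical(nrow(tab))
    for (site in unique(c(tab$site_i, tab$site_j))) {
      rows <- which(tab$site_i == site | tab$site_j == site)
      keep[rows[order(-tab$r2[rows])][seq_len(min(top_k, length(rows)))]] <- TRUE
    }
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, gn_id = gn$gn_id, r2_threshold = r2_threshold,
            class = c("ld_pair_table", "data.frame"))
}

#' Count retained LD pairs in a neighborhood
#'
#' The per-neighborhood scan statistic: the number of site pairs whose r^2
#' exceeded the threshold.
#'
#' @param table An `ld_pair_table` from [window_ld_pairs()].
#' @return Non-negative integer.
#' @export
gn_ld_count <- function(table) nrow(table)

#' Compare LD-pair counts between clustered and non-clustered neighborhoods
#'
#' Pooled-variance two-sample two-sided Student t-test on per-neighborhood
#' LD-pair counts, df = n1 + n2 - 2.
#'
#' @param counts Numeric vector of per-GN LD-pair counts.
#' @param group_label Character vector parallel to `counts`, values
#'   `"clustered"` / `"non_clustered"`.
#' @return A list of class `gn_group_comparison`: `n_clustered`,
#'   `n_nonclustered`, `mean_clustered`, `mean_nonclustered`,
#'   `t_statistic`, `df`, `p_two_sided`.
#' @export
compare_gn_groups <- function(counts, group_label) {
  x <- counts[group_label == "clustered"]
  y <- counts[group_label == "non_clustered"]
  if (length(x) < 2L || length(y) < 2L)
    bgcsel_stop("validation", "need at least 2 neighborhoods per group")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var_or_zero(x) + (n2 - 1) * var_or_zero(y)) / df
  if (sp2 <= 0) {
    if (mean(x) != mean(y))
      bgcsel_stop("degenerate_variance", "zero pooled variance in group comparison")
    tstat <- 0  # identical constant groups: no evidence either way
  } else {
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  structure(list(n_clustered = n1, n_nonclustered = n2,
                 mean_clustered = mean(x), mean_nonclustered = mean(y),
                 t_statistic = tstat, df = df,
                 p_two_sided = 2 * pt(-abs(tstat), df)),
            class = "gn_group_comparison")
}

var_or_zero <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' @export
print.gn_group_comparison <- function(x, ...) {
  cat(sprintf(paste0("LD-pair count comparison: clustered (n=%d, mean=%.2f)",
                     " vs non-clustered (n=%d, mean=%.2f)\n",
                     "  pooled t = %.3f, df = %d, two-sided p = %.4g\n"),
              x$n_clustered, x$mean_clustered, x$n_nonclustered,
              x$mean_nonclustered, x$t_statistic, x$df, x$p_two_sided))
  invisible(x)
}

#' LOESS decay curve of r^2 with inter-site distance
#'
#' Local linear regression (tricube weights, degree 1) of r^2 on distance,
#' evaluated on an evenly spaced distance grid and clamped to \[0, 1\].
#'
#' @param table An `ld_pair_table` (>= 10 pairs).
#' @param span LOESS span in (0, 1\] (default 0.75).
#' @param grid_n Number of grid points (default 100).
#' @return `data.frame` with columns `distance_bp`, `r2_smooth`.
#' @export
ld_decay_loess <- function(table, span = 0.75, grid_n = 100L) {
  if (span <= 0 || span > 1)
    bgcsel_stop("validation", "span must be in (0, 1]")
  if (nrow(table) < 10L)
    bgcsel_stop("insufficient_data",
                "need >= 10 LD pairs for a decay curve, got %d", nrow(table))
  fit <- loess(r2 ~ distance_bp, data = table, span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(table$distance_bp), max(table$distance_bp),
              length.out = grid_n)
  yhat <- predict(fit, newdata = data.frame(distance_bp = grid))
  data.frame(distance_bp = grid, r2_smooth = pmin(1, pmax(0, yhat)))
}
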