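# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive each quantity through a different route than
# the package implementation (naive formulas, enumeration, Matrix::expm).

GC_TAB <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")

# squared Pearson correlation from first principles
naive_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  (num / den)^2
}

# two-sided Fisher p by direct enumeration of the hypergeometric support
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- NG86 oracle: per-position site fractions and recursive pathway
# enumeration (uniform over stop-free orderings) ----

syn_fraction_oracle <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  s <- 0L
  for (p in 1:3) for (n in NT) {
    if (n == b[p]) next
    alt <- b; alt[p] <- n
    ac <- paste(alt, collapse = "")
    if (GC_TAB[[ac]] != "*" && GC_TAB[[ac]] == GC_TAB[[codon]]) s <- s + 1L
  }
  s / 3
}

path_counts_oracle <- function(c1, c2) {
  walk <- function(cur) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(d)) return(list(c(nd = 0, sd = 0)))
    out <- list()
    for (p in d) {
      b <- strsplit(cur, "")[[1]]
      b[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(b, collapse = "")
      if (GC_TAB[[nxt]] == "*") next
      step <- if (GC_TAB[[cur]] == GC_TAB[[nxt]]) c(nd = 0, sd = 1) else c(nd = 1, sd = 0)
      for (tail in walk(nxt)) out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(c1)
  if (!length(paths)) return(c(nd = NA_real_, sd = NA_real_))
  colMeans(do.call(rbind, paths))
}

ng86_oracle <- function(aln) {
  ca <- substring(aln$seq_a, seq(1, nchar(aln$seq_a), 3), seq(3, nchar(aln$seq_a), 3))
  cb <- substring(aln$seq_b, seq(1, nchar(aln$seq_b), 3), seq(3, nchar(aln$seq_b), 3))
  S <- sum((vapply(ca, syn_fraction_oracle, 0) +
              vapply(cb, syn_fraction_oracle, 0)) / 2)
  N <- 3 * length(ca) - S
  nd <- sd_ <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pc <- path_counts_oracle(ca[i], cb[i])
    nd <- nd + pc[["nd"]]; sd_ <- sd_ + pc[["sd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = nd, Sd = sd_, dN = jc(nd / N), dS = jc(sd_ / S))
}

# ---- GY94 oracle: rate matrix built from scratch + Matrix::expm ----

sense_codons_oracle <- function() names(GC_TAB)[GC_TAB != "*"]

gy94_Q_oracle <- function(kappa, omega, pi) {
  sense <- sense_codons_oracle()
  n <- length(sense)
  sm <- do.call(rbind, strsplit(sense, ""))
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(sm[i, ] != sm[j, ])
    if (length(d) != 1L) next
    ts <- (sm[i, d] %in% c("A", "G")) == (sm[j, d] %in% c("A", "G"))
    syn <- GC_TAB[[sense[i]]] == GC_TAB[[sense[j]]]
    Q[i, j] <- pi[j] * (if (ts) kappa else 1) * (if (syn) 1 else omega)
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

gy94_loglik_oracle <- function(aln, t, kappa, omega, pi) {
  sense <- sense_codons_oracle()
  Q <- gy94_Q_oracle(kappa, omega, pi)
  P <- as.matrix(Matrix::expm(Q * t))
  ca <- substring(aln$seq_a, seq(1, nchar(aln$seq_a), 3), seq(3, nchar(aln$seq_a), 3))
  cb <- substring(aln$seq_b, seq(1, nchar(aln$seq_b), 3), seq(3, nchar(aln$seq_b), 3))
  ia <- match(ca, sense); ib <- match(cb, sense)
  sum(log(pi[ia] * P[cbind(ia, ib)]))
}

# ---- fixture builders ----

# the 12-codon toy pair: one synonymous (AAA->AAG) and one nonsynonymous
# (TTT->TCT) single-nucleotide difference
toy_codon_pair <- function() {
  a <- "ATGAAACCCGGGTTTACAGATCAGCTGATCGAAGCT"
  b <- "ATGAAGCCCGGGTCTACAGATCAGCTGATCGAAGCT"
  list(a = a, b = b)
}

write_test_vcf <- function(path, records,
                           samples = c("accA", "accB")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

random_panel <- function(n_sites, n_samples, seed, miss_frac = 0) {
  set.seed(seed)
  geno <- matrix(rbinom(n_sites * n_samples, 1, runif(n_sites, 0.05, 0.95)),
                 n_sites, n_samples)
  if (miss_frac > 0)
    geno[sample(length(geno), round(miss_frac * length(geno)))] <- NA
  snp_matrix(chrom = rep("chr1", n_sites),
             pos = sort(sample.int(1e6, n_sites)),
             ref = rep("A", n_sites), alt = rep("G", n_sites),
             geno = geno,
             sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

osc_bed_path <- function() {
  system.file("extdata", "osc_loci_tair10.bed", package = "bgcsel",
              mustWork = TRUE)
}
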