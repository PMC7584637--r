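# Pairwise dN/dS: codon alignments, Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, and the single-ratio Goldman-Yang codon model
# with a likelihood-ratio test of omega = 1.

# --- codon bookkeeping -----------------------------------------------------

# Sense-codon tables derived from the standard genetic code, built once.
codon_data <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    codons <- names(gc_tab)
    sense <- codons[gc_tab != "*"]
    aa <- unname(gc_tab[sense])
    nt <- c("A", "C", "G", "T")
    split3 <- function(x) matrix(unlist(strsplit(x, "")), ncol = 3, byrow = TRUE)
    sm <- split3(sense)
    is_ts <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
    # single-nucleotide-difference pairs among sense codons
    pi_ <- pj <- integer(0); ts <- syn <- logical(0)
    for (i in seq_along(sense)) for (j in seq_along(sense)) {
      if (i == j) next
      d <- which(sm[i, ] != sm[j, ])
      if (length(d) == 1L) {
        pi_ <- c(pi_, i); pj <- c(pj, j)
        ts <- c(ts, is_ts(sm[i, d], sm[j, d]))
        syn <- c(syn, aa[i] == aa[j])
      }
    }
    # NG86 synonymous site fraction per codon: at each position, the share
    # of the 3 alternative nucleotides giving the same amino acid (changes
    # to stop codons count as nonsynonymous, denominator stays 3).
    syn_sites <- vapply(seq_along(sense), function(i) {
      s <- 0
      for (p in 1:3) for (n in nt) {
        if (n == sm[i, p]) next
        alt <- sm[i, ]; alt[p] <- n
        altc <- paste(alt, collapse = "")
        if (gc_tab[[altc]] != "*" && gc_tab[[altc]] == aa[i]) s <- s + 1 / 3
      }
      s
    }, numeric(1))
    cache <<- list(sense = sense, aa = aa, n = length(sense),
                   pair_i = pi_, pair_j = pj, pair_ts = ts, pair_syn = syn,
                   syn_sites = syn_sites, gc_tab = gc_tab)
    cache
  }
})

is_stop_codon <- function(codon) codon_data()$gc_tab[codon] == "*"

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# --- alignment construction ------------------------------------------------

#' Build a cleaned pairwise codon alignment
#'
#' Validates frame, drops codon columns containing gaps or ambiguous
#' nucleotides from both sequences, strips a terminal stop codon, and
#' rejects alignments with internal stops after cleaning.
#'
#' @param cds_a,cds_b Aligned coding sequences (equal-length character
#'   strings; `-` for gaps, non-ACGT treated as ambiguous).
#' @param id_a,id_b Optional source identifiers.
#' @return An object of class `codon_alignment` with fields `seq_a`,
#'   `seq_b`, `n_codons`, `n_dropped`, `id_a`, `id_b`.
#' @export
prepare_codon_alignment <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  cds_a <- toupper(as.character(cds_a)); cds_b <- toupper(as.character(cds_b))
  if (nchar(cds_a) == 0L || nchar(cds_b) == 0L)
    bgcsel_stop("validation", "empty sequence")
  if (nchar(cds_a) != nchar(cds_b))
    bgcsel_stop("frame", "aligned sequences differ in length (%d vs %d)",
                nchar(cds_a), nchar(cds_b))
  if (nchar(cds_a) %% 3L != 0L)
    bgcsel_stop("frame", "alignment length %d not divisible by 3", nchar(cds_a))
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  n_dropped <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) > 0L &&
      (is_stop_codon(ca[length(ca)]) || is_stop_codon(cb[length(cb)]))) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  if (length(ca) == 0L)
    bgcsel_stop("validation", "no usable codon columns after cleaning")
  if (any(is_stop_codon(ca)) || any(is_stop_codon(cb)))
    bgcsel_stop("invalid_cds", "internal stop codon in %s",
                if (any(is_stop_codon(ca))) id_a else id_b)
  structure(list(seq_a = paste(ca, collapse = ""),
                 seq_b = paste(cb, collapse = ""),
                 n_codons = length(ca), n_dropped = n_dropped,
                 id_a = id_a, id_b = id_b),
            class = "codon_alignment")
}

#' Read a CDS pair from a FASTA file
#'
#' The file must contain exactly two records (the two orthologous coding
#' sequences, pre-aligned).
#'
#' @param path FASTA path.
#' @return A `codon_alignment` via [prepare_codon_alignment()].
#' @export
read_codon_pair_fasta <- function(path) {
  if (!file.exists(path))
    bgcsel_stop("io", "file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 2L)
    bgcsel_stop("format", "FASTA %s: expected exactly 2 records, found %d",
                path, length(ss))
  prepare_codon_alignment(as.character(ss[[1L]]), as.character(ss[[2L]]),
                          names(ss)[1L], names(ss)[2L])
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s vs %s: %d codons (%d columns dropped)\n",
              x$id_a, x$id_b, x$n_codons, x$n_dropped))
  invisible(x)
}

aln_codon_indices <- function(aln) {
  cd <- codon_data()
  ia <- match(split_codons(aln$seq_a), cd$sense)
  ib <- match(split_codons(aln$seq_b), cd$sense)
  cbind(ia, ib)
}

# 61 x 61 table of aligned codon-pair counts
codon_pair_counts <- function(aln) {
  cd <- codon_data()
  idx <- aln_codon_indices(aln)
  counts <- matrix(0, cd$n, cd$n)
  tab <- table(idx[, 1L], idx[, 2L])
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  counts
}

# --- NG86 ------------------------------------------------------------------

# Average (nonsyn, syn) difference counts over all mutational pathways
# between two codons; pathways through stop codons are excluded and the
# average renormalized over the remaining orderings.
ng86_pathways <- function(codon1, codon2) {
  cd <- codon_data()
  b1 <- strsplit(codon1, "")[[1L]]; b2 <- strsplit(codon2, "")[[1L]]
  d <- which(b1 != b2)
  k <- length(d)
  if (k == 0L) return(c(nd = 0, sd = 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  acc <- matrix(NA_real_, length(perms), 2L)
  for (p in seq_along(perms)) {
    cur <- b1; nd <- sd <- 0; valid <- TRUE
    for (step in d[perms[[p]]]) {
      nxt <- cur; nxt[step] <- b2[step]
      c_from <- paste(cur, collapse = ""); c_to <- paste(nxt, collapse = "")
      if (is_stop_codon(c_to)) { valid <- FALSE; break }
      if (cd$gc_tab[[c_from]] == cd$gc_tab[[c_to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) acc[p, ] <- c(nd, sd)
  }
  ok <- !is.na(acc[, 1L])
  if (!any(ok)) {
    # degenerate: every ordering crosses a stop; fall back to counting the
    # raw per-position classifications along an arbitrary ordering
    acc <- acc[1L, , drop = FALSE]
    cur <- b1; nd <- sd <- 0
    for (step in d) {
      nxt <- cur; nxt[step] <- b2[step]
      c_from <- paste(cur, collapse = ""); c_to <- paste(nxt, collapse = "")
      same <- !is_stop_codon(c_to) && !is_stop_codon(c_from) &&
        cd$gc_tab[[c_from]] == cd$gc_tab[[c_to]]
      if (same) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    return(c(nd = nd, sd = sd))
  }
  c(nd = mean(acc[ok, 1L]), sd = mean(acc[ok, 2L]))
}

#' Nei-Gojobori (NG86) pairwise dN/dS
#'
#' Counting estimator: synonymous site fractions are summed per codon
#' (averaged over the two sequences) to give S, with N = 3 x n_codons - S;
#' observed differences are averaged over all mutational pathways (routes
#' through stop codons excluded, with renormalization); proportions are
#' Jukes-Cantor corrected, d = -3/4 log(1 - 4p/3).
#'
#' @param aln A `codon_alignment`.
#' @return A `dnds_result` with `method = "NG86"`, fields `dN`, `dS`,
#'   `omega`, `N`, `S`, `Nd`, `Sd` and a `flags` character vector
#'   (`"saturated"` when a proportion reaches 3/4, `"undefined_omega"`
#'   when dS = 0).
#' @export
ng86 <- function(aln) {
  cd <- codon_data()
  idx <- aln_codon_indices(aln)
  S <- sum((cd$syn_sites[idx[, 1L]] + cd$syn_sites[idx[, 2L]]) / 2)
  N <- 3 * aln$n_codons - S
  diff_rows <- which(idx[, 1L] != idx[, 2L])
  Nd <- Sd <- 0
  if (length(diff_rows)) {
    key <- paste(idx[diff_rows, 1L], idx[diff_rows, 2L])
    for (k in unique(key)) {
      rows <- diff_rows[key == k]
      pc <- ng86_pathways(cd$sense[idx[rows[1L], 1L]], cd$sense[idx[rows[1L], 2L]])
      Nd <- Nd + pc[["nd"]] * length(rows)
      Sd <- Sd + pc[["sd"]] * length(rows)
    }
  }
  pN <- Nd / N; pS <- Sd / S
  flags <- character(0)
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  if (is.na(dN) || is.na(dS)) flags <- c(flags, "saturated")
  omega <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else {
    flags <- c(flags, "undefined_omega"); NA_real_
  }
  dnds_result(method = "NG86", dN = dN, dS = dS, omega = omega,
              flags = flags, N = N, S = S, Nd = Nd, Sd = Sd)
}

dnds_result <- function(method, dN = NA_real_, dS = NA_real_, omega = NA_real_,
                        logL_free = NA_real_, logL_null = NA_real_,
                        lrt_stat = NA_real_, p_value = NA_real_,
                        t = NA_real_, kappa = NA_real_, flags = character(0),
                        ...) {
  structure(list(method = method, dN = dN, dS = dS, omega = omega,
                 logL_free = logL_free, logL_null = logL_null,
                 lrt_stat = lrt_stat, p_value = p_value,
                 t = t, kappa = kappa, flags = flags, ...),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dnds_result %s> dN=%.4g dS=%.4g omega=%.4g", x$method,
              x$dN, x$dS, x$omega))
  if (!is.na(x$lrt_stat))
    cat(sprintf(" LRT=%.3f p=%.3g", x$lrt_stat, x$p_value))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}
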