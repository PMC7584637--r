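# Biallelic SNP panels for inbred (selfing) accessions.
#
# Genotypes are haploid-coded: 0 = reference allele, 1 = alternate allele,
# NA = missing. Heterozygous diploid calls in a VCF are, by default, set to
# missing -- the panel model is a selfing line collection where residual
# heterozygosity is treated as no-call. Internal coordinates are 1-based
# site positions; interval inputs (BED) are 0-based half-open and converted
# at the boundary.

#' Construct a SNP matrix
#'
#' A `snp_matrix` holds a sites-by-samples panel of haploid-coded biallelic
#' genotypes with per-site chromosome, position and allele metadata. It is
#' the substrate of all linkage-disequilibrium computations.
#'
#' @param chrom Character vector, chromosome per site.
#' @param pos Integer vector, 1-based position (bp) per site; strictly
#'   increasing within each chromosome.
#' @param ref,alt Character vectors of reference/alternate alleles per site.
#'   `alt` may contain comma-separated alternates; such sites are flagged
#'   multiallelic and can be dropped by [filter_sites()].
#' @param geno Integer matrix, sites x samples, entries in \{0, 1, NA\}.
#' @param sample_ids Character vector of accession names (columns of `geno`).
#' @return An object of class `snp_matrix`.
#' @seealso [load_variants()], [filter_sites()], [allele_frequency()]
#' @export
snp_matrix <- function(chrom, pos, ref, alt, geno, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- length(pos)
  if (n_sites > 0L) {  # scalars recycle across sites
    if (length(chrom) == 1L) chrom <- rep_len(chrom, n_sites)
    if (length(ref) == 1L) ref <- rep_len(ref, n_sites)
    if (length(alt) == 1L) alt <- rep_len(alt, n_sites)
  }
  if (length(chrom) != n_sites || length(ref) != n_sites ||
      length(alt) != n_sites || nrow(geno) != n_sites)
    bgcsel_stop("validation", "site metadata and genotype rows disagree in length")
  if (ncol(geno) != length(sample_ids))
    bgcsel_stop("validation", "sample_ids and genotype columns disagree in length")
  bad <- !(geno %in% c(0L, 1L, NA_integer_))
  if (any(bad))
    bgcsel_stop("validation", "genotype codes must be 0, 1 or NA")
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      if (anyDuplicated(p))
        bgcsel_stop("duplicate_site", "duplicated position on chromosome %s", ch)
      bgcsel_stop("validation", "positions not strictly increasing on chromosome %s", ch)
    }
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, sample_ids = as.character(sample_ids)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), length(x$sample_ids), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites in a SNP matrix
#' @param m A `snp_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(m) length(m$pos)

subset_sites <- function(m, keep) {
  snp_matrix(m$chrom[keep], m$pos[keep], m$ref[keep], m$alt[keep],
             m$geno[keep, , drop = FALSE], m$sample_ids)
}

is_multiallelic <- function(m) grepl(",", m$alt, fixed = TRUE)

#' Load a variant panel from VCF or TSV
#'
#' Reads biallelic SNP genotypes into a [snp_matrix()]. VCF `GT` fields are
#' collapsed to haploid codes: `0/0` (or `0|0`, `0`) -> 0, `1/1` -> 1,
#' missing (`./.`) -> NA. Heterozygous calls are handled per `het_policy`
#' (default: set missing, the appropriate model for selfing accessions).
#' The TSV dialect is tab-separated with header
#' `chrom pos ref alt <sample...>` and genotype codes `0`/`1`/`NA`.
#'
#' @param path Path to a `.vcf`, `.vcf.gz` or `.tsv` file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param het_policy What to do with heterozygous diploid calls:
#'   `"missing"` (default), `"ref"` or `"alt"`.
#' @return A `snp_matrix`, sites sorted by (chrom, pos).
#' @export
load_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          het_policy = c("missing", "ref", "alt")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (!file.exists(path))
    bgcsel_stop("io", "file not found: %s", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.vcf$", base, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") load_vcf(path, het_policy) else load_snp_tsv(path)
}

load_vcf <- function(path, het_policy) {
  con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L)
    bgcsel_stop("format", "VCF %s: missing #CHROM header line", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L)
    bgcsel_stop("format", "VCF %s: no sample columns", path)
  sample_ids <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(snp_matrix(character(), integer(), character(), character(),
                      matrix(integer(), 0L, length(sample_ids)), sample_ids))
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(hdr))) {
    bad <- which(nf != length(hdr))[1L]
    bgcsel_stop("format", "VCF %s: malformed record at data line %d", path, bad)
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 2L)))
  if (anyNA(pos))
    bgcsel_stop("format", "VCF %s: non-numeric POS at data line %d",
                path, which(is.na(pos))[1L])
  ref <- vapply(rows, `[[`, "", 4L)
  alt <- vapply(rows, `[[`, "", 5L)
  fmt <- strsplit(vapply(rows, `[[`, "", 9L), ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), 0L)
  if (anyNA(gt_idx))
    bgcsel_stop("format", "VCF %s: record without GT field at data line %d",
                path, which(is.na(gt_idx))[1L])
  geno <- matrix(NA_integer_, length(rows), length(sample_ids))
  for (i in seq_along(rows)) {
    calls <- vapply(strsplit(rows[[i]][-(1:9)], ":", fixed = TRUE),
                    `[[`, "", gt_idx[i])
    geno[i, ] <- collapse_gt(calls, het_policy, path, i)
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    bgcsel_stop("duplicate_site", "VCF %s: duplicated site %s",
                path, key[duplicated(key)][1L])
  o <- order(chrom, pos)
  snp_matrix(chrom[o], pos[o], ref[o], alt[o], geno[o, , drop = FALSE], sample_ids)
}

# Collapse diploid GT strings to haploid codes; allele indices > 1
# (extra alternates) are set missing, the site stays flagged via its ALT.
collapse_gt <- function(calls, het_policy, path, line) {
  al <- strsplit(calls, "[/|]")
  vapply(al, function(a) {
    a <- a[a != ""]
    if (length(a) == 0L || any(a == "."))
      return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai))
      bgcsel_stop("format", "VCF %s: unparseable GT at data line %d", path, line)
    if (any(ai > 1L)) return(NA_integer_)
    if (length(unique(ai)) == 1L) return(ai[1L])
    switch(het_policy, missing = NA_integer_, ref = 0L, alt = 1L)
  }, integer(1))
}

load_snp_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, comment.char = "",
                   na.strings = character(0))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)[1:4]))
    bgcsel_stop("format", "TSV %s: header must start with 'chrom pos ref alt'", path)
  sample_ids <- names(df)[-(1:4)]
  if (length(sample_ids) == 0L)
    bgcsel_stop("format", "TSV %s: no sample columns", path)
  pos <- suppressWarnings(as.integer(df$pos))
  if (nrow(df) > 0L && anyNA(pos))
    bgcsel_stop("format", "TSV %s: non-numeric pos at data line %d",
                path, which(is.na(pos))[1L])
  geno <- matrix(NA_integer_, nrow(df), length(sample_ids))
  if (nrow(df) > 0L) {
    g <- as.matrix(df[, -(1:4), drop = FALSE])
    bad <- !(g %in% c("0", "1", "NA"))
    if (any(bad))
      bgcsel_stop("format", "TSV %s: invalid genotype code at data line %d",
                  path, which(rowSums(matrix(bad, nrow(df))) > 0)[1L])
    geno <- matrix(suppressWarnings(as.integer(g)), nrow(df))
  }
  key <- paste(df$chrom, pos)
  if (anyDuplicated(key))
    bgcsel_stop("duplicate_site", "TSV %s: duplicated site %s",
                path, key[duplicated(key)][1L])
  o <- order(df$chrom, pos)
  snp_matrix(df$chrom[o], pos[o], df$ref[o], df$alt[o],
             geno[o, , drop = FALSE], sample_ids)
}

#' Write a SNP matrix in the package TSV dialect
#'
#' Tab-separated, header `chrom pos ref alt <sample...>`, codes `0`/`1`/`NA`.
#' [load_variants()] round-trips this format exactly.
#'
#' @param m A `snp_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(m, path) {
  g <- m$geno
  gc <- matrix(as.character(g), nrow = nrow(g), ncol = ncol(g))
  gc[is.na(g)] <- "NA"
  df <- data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  gdf <- as.data.frame(gc, stringsAsFactors = FALSE)
  names(gdf) <- m$sample_ids
  write.table(cbind(df, gdf), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Alternate-allele frequency at a site
#'
#' @param m A `snp_matrix`.
#' @param site_index Integer site index (row of the panel).
#' @return Frequency of the alternate allele among non-missing calls,
#'   in \[0, 1\].
#' @export
allele_frequency <- function(m, site_index) {
  if (site_index < 1L || site_index > n_sites(m))
    bgcsel_stop("validation", "site index %d out of range", site_index)
  g <- m$geno[site_index, ]
  g <- g[!is.na(g)]
  if (length(g) == 0L)
    bgcsel_stop("undefined_frequency",
                "all calls missing at site %d: frequency undefined", site_index)
  mean(g)
}

#' Filter panel sites on MAF, allele count and missingness
#'
#' Retains sites whose minor allele frequency among non-missing calls is at
#' least `maf_min`, optionally drops multiallelic sites, and drops sites
#' with a missing-call fraction above `max_missing`. Idempotent.
#'
#' @param m A `snp_matrix`.
#' @param maf_min Minimum minor allele frequency in \[0, 0.5\] (default 0.05,
#'   the conventional panel filter).
#' @param biallelic_only Drop sites with more than one alternate allele
#'   (default `TRUE`).
#' @param max_missing Maximum tolerated missing-call fraction (default 0.1).
#' @return A filtered `snp_matrix`.
#' @export
filter_sites <- function(m, maf_min = 0.05, biallelic_only = TRUE,
                         max_missing = 0.1) {
  if (maf_min < 0 || maf_min > 0.5)
    bgcsel_stop("validation", "maf_min must be in [0, 0.5]")
  if (n_sites(m) == 0L) return(m)
  g <- m$geno
  n_called <- rowSums(!is.na(g))
  miss_frac <- 1 - n_called / ncol(g)
  alt_f <- rowMeans(g, na.rm = TRUE)
  maf <- pmin(alt_f, 1 - alt_f)
  keep <- n_called > 0L & miss_frac <= max_missing & maf >= maf_min
  keep[is.na(keep)] <- FALSE
  if (biallelic_only) keep <- keep & !is_multiallelic(m)
  subset_sites(m, keep)
}
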