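# Focal-locus tables: gene bodies (0-based half-open) with an optional
# clustered / non_clustered group label, read from 4-5 column BED.

#' Construct a locus table
#'
#' @param locus_id Unique locus names.
#' @param chrom Chromosome per locus.
#' @param start,end 0-based half-open gene-body interval (bp).
#' @param group_label Optional per-locus label, `"clustered"` or
#'   `"non_clustered"` (NA allowed).
#' @return A `data.frame` of class `locus_table`.
#' @export
locus_table <- function(locus_id, chrom, start, end, group_label = NA_character_) {
  if (anyDuplicated(locus_id))
    bgcsel_stop("duplicate_locus", "duplicated locus_id: %s",
                locus_id[duplicated(locus_id)][1L])
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end))
    bgcsel_stop("validation", "locus interval must satisfy start < end")
  lab <- rep_len(as.character(group_label), length(locus_id))
  known <- is.na(lab) | lab %in% c("clustered", "non_clustered")
  if (!all(known))
    bgcsel_stop("validation", "group_label must be 'clustered' or 'non_clustered'")
  structure(data.frame(locus_id = as.character(locus_id),
                       chrom = as.character(chrom),
                       start = start, end = end, group_label = lab,
                       stringsAsFactors = FALSE),
            class = c("locus_table", "data.frame"))
}

#' Read loci from a BED file
#'
#' Expects 4 or 5 tab-separated columns: chrom, start, end, name and an
#' optional group label (`clustered` / `non_clustered`). BED coordinates are
#' 0-based half-open and kept as such.
#'
#' @param path Path to the BED file.
#' @return A [locus_table()].
#' @export
read_loci_bed <- function(path) {
  if (!file.exists(path))
    bgcsel_stop("io", "file not found: %s", path)
  df <- read.table(path, header = FALSE, sep = "\t", colClasses = "character",
                   comment.char = "#")
  if (ncol(df) < 4L)
    bgcsel_stop("format", "BED %s: need at least 4 columns (chrom start end name)", path)
  lab <- if (ncol(df) >= 5L) df[[5L]] else NA_character_
  locus_table(df[[4L]], df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]), lab)
}
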