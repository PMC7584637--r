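# McDonald-Kreitman test family: standard MKT, the FWW low-frequency
# correction, and the extended variant (eMKT) that estimates and removes
# the weakly deleterious nonsynonymous polymorphism count from frequency
# classes. Contrast of within-species polymorphism (Pn, Ps) with
# between-species divergence (Dn, Ds); alpha = 1 - (Ds Pn)/(Dn Ps) is the
# inferred fraction of adaptive nonsynonymous substitutions.

#' Construct a polymorphism table
#'
#' @param site_id Site identifiers.
#' @param class `"synonymous"` or `"nonsynonymous"` per site.
#' @param frequency Derived- (or minor-) allele fraction per site, strictly
#'   inside (0, 1): fixed differences belong in the divergence counts, not
#'   here.
#' @param frequency_type `"derived"` or `"minor"`, recorded in results.
#' @return A `data.frame` of class `polymorphism_table`.
#' @export
polymorphism_table <- function(site_id, class, frequency,
                               frequency_type = c("derived", "minor")) {
  frequency_type <- match.arg(frequency_type)
  if (!all(class %in% c("synonymous", "nonsynonymous")))
    bgcsel_stop("validation", "class must be 'synonymous' or 'nonsynonymous'")
  frequency <- as.numeric(frequency)
  if (any(frequency <= 0 | frequency >= 1))
    bgcsel_stop("validation", "frequencies must lie strictly inside (0, 1)")
  structure(data.frame(site_id = as.character(site_id),
                       class = as.character(class), frequency = frequency,
                       stringsAsFactors = FALSE),
            frequency_type = frequency_type,
            class = c("polymorphism_table", "data.frame"))
}

#' Read a polymorphism table from TSV
#'
#' Tab-separated with header `site_id class frequency`.
#' @param path TSV path.
#' @param frequency_type Passed to [polymorphism_table()].
#' @return A `polymorphism_table`.
#' @export
read_polymorphism_tsv <- function(path, frequency_type = "derived") {
  if (!file.exists(path)) bgcsel_stop("io", "file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("site_id", "class", "frequency")
  if (!all(need %in% names(df)))
    bgcsel_stop("format", "TSV %s: need columns %s", path,
                paste(need, collapse = ", "))
  polymorphism_table(df$site_id, df$class, df$frequency, frequency_type)
}

#' Construct divergence counts
#'
#' @param Dn,Ds Nonnegative integer counts of nonsynonymous / synonymous
#'   fixed differences.
#' @param Ln,Ls Optional site totals.
#' @return A list of class `divergence_counts`.
#' @export
divergence_counts <- function(Dn, Ds, Ln = NA_real_, Ls = NA_real_) {
  if (Dn < 0 || Ds < 0)
    bgcsel_stop("validation", "divergence counts must be nonnegative")
  structure(list(Dn = as.numeric(Dn), Ds = as.numeric(Ds),
                 Ln = Ln, Ls = Ls),
            class = "divergence_counts")
}

poly_counts <- function(poly) {
  c(Pn = sum(poly$class == "nonsynonymous"),
    Ps = sum(poly$class == "synonymous"))
}

mkt_core <- function(Pn_used, Ps_used, Dn, Ds, variant, cutoff,
                     P_wd = NA_real_, Pn_for_alpha = Pn_used,
                     frequency_type = NA_character_) {
  flags <- character(0)
  if (Ps_used == 0 || Dn == 0) {
    flags <- c(flags, "undefined_alpha")
    alpha <- NA_real_; ni <- NA_real_
  } else {
    ni <- (Pn_for_alpha / Ps_used) / (Dn / Ds)
    alpha <- 1 - ni
  }
  tab <- matrix(round(c(Pn_for_alpha, Ps_used, Dn, Ds)), 2, byrow = TRUE)
  fisher_p <- fisher.test(tab)$p.value
  structure(list(variant = variant, Pn_used = Pn_used, Ps_used = Ps_used,
                 Dn = Dn, Ds = Ds, alpha = alpha, neutrality_index = ni,
                 fisher_p = fisher_p, P_wd = P_wd, cutoff = cutoff,
                 frequency_type = frequency_type, flags = flags),
            class = "mkt_result")
}

#' @export
print.mkt_result <- function(x, ...) {
  cat(sprintf("<mkt_result %s> Pn=%g Ps=%g Dn=%g Ds=%g alpha=%.4g p=%.3g",
              x$variant, x$Pn_used, x$Ps_used, x$Dn, x$Ds,
              x$alpha, x$fisher_p))
  if (!is.na(x$P_wd)) cat(sprintf(" P_wd=%.3g", x$P_wd))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

check_mkt_pre <- function(poly, div) {
  pc <- poly_counts(poly)
  if (sum(pc) == 0)
    bgcsel_stop("empty_polymorphism", "no polymorphic sites")
  if (div$Dn + div$Ds == 0)
    bgcsel_stop("validation", "no divergence counts")
  pc
}

#' Standard McDonald-Kreitman test
#'
#' alpha = 1 - (Ds Pn)/(Dn Ps); neutrality index NI = (Pn/Ps)/(Dn/Ds);
#' two-sided Fisher exact p on the 2x2 table \[\[Pn, Ps\], \[Dn, Ds\]\].
#' When Ps = 0 or Dn = 0 alpha is undefined (flagged) but the Fisher p is
#' still returned.
#'
#' @param poly A [polymorphism_table()].
#' @param div A [divergence_counts()].
#' @return An `mkt_result`.
#' @export
standard_mkt <- function(poly, div) {
  pc <- check_mkt_pre(poly, div)
  mkt_core(pc[["Pn"]], pc[["Ps"]], div$Dn, div$Ds, "standard", cutoff = 0,
           frequency_type = attr(poly, "frequency_type") %||% NA_character_)
}

#' FWW-corrected McDonald-Kreitman test
#'
#' Removes polymorphic sites with frequency below `cutoff` from both
#' classes (discarding the weakly deleterious, mostly rare, variants) and
#' applies the standard formulas to the reduced counts.
#'
#' @inheritParams standard_mkt
#' @param cutoff Frequency cutoff (default 0.05).
#' @return An `mkt_result` with `variant = "FWW"`.
#' @export
fww_mkt <- function(poly, div, cutoff = 0.05) {
  check_mkt_pre(poly, div)
  kept <- poly[poly$frequency >= cutoff, , drop = FALSE]
  if (nrow(kept) == 0L)
    bgcsel_stop("empty_polymorphism",
                "all polymorphic sites removed at cutoff %g", cutoff)
  pc <- c(Pn = sum(kept$class == "nonsynonymous"),
          Ps = sum(kept$class == "synonymous"))
  res <- mkt_core(pc[["Pn"]], pc[["Ps"]], div$Dn, div$Ds, "FWW",
                  cutoff = cutoff,
                  frequency_type = attr(poly, "frequency_type") %||% NA_character_)
  res
}

#' Extended McDonald-Kreitman test (eMKT)
#'
#' Splits polymorphisms at `cutoff` into rare and common classes, estimates
#' the weakly deleterious nonsynonymous count
#' `P_wd = max(0, Pn_rare - Ps_rare * Pn_common / Ps_common)`, subtracts it
#' from Pn, and computes alpha = 1 - (Ds Pn_neutral)/(Dn Ps) on the full
#' synonymous count.
#'
#' @inheritParams fww_mkt
#' @return An `mkt_result` with `variant = "eMKT"` and `P_wd` filled.
#' @export
extended_mkt <- function(poly, div, cutoff = 0.05) {
  pc <- check_mkt_pre(poly, div)
  rare <- poly$frequency < cutoff
  Pn_rare <- sum(rare & poly$class == "nonsynonymous")
  Ps_rare <- sum(rare & poly$class == "synonymous")
  Pn_common <- sum(!rare & poly$class == "nonsynonymous")
  Ps_common <- sum(!rare & poly$class == "synonymous")
  if (Ps_common == 0)
    bgcsel_stop("undefined_correction",
                "no common synonymous polymorphisms: eMKT correction undefined")
  P_wd <- max(0, Pn_rare - Ps_rare * (Pn_common / Ps_common))
  Pn_neutral <- pc[["Pn"]] - P_wd
  mkt_core(pc[["Pn"]], pc[["Ps"]], div$Dn, div$Ds, "eMKT", cutoff = cutoff,
           P_wd = P_wd, Pn_for_alpha = Pn_neutral,
           frequency_type = attr(poly, "frequency_type") %||% NA_character_)
}
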