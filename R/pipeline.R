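# Orchestration: neighborhood LD scan, per-gene dN/dS batch, and MKT batch
# over standard text inputs, with deterministic outputs and a small CLI
# dispatcher. Plots are deliberately not produced here; every downstream
# consumer reads the TSV/JSON artifacts.

#' Assemble a run configuration
#'
#' Bundles input paths and the analysis parameters with their conventional
#' defaults: 50 kb flanks, r^2 > 0.1, MAF >= 0.05, MKT frequency cutoff
#' 0.05.
#'
#' @param panel Path to a SNP panel (VCF or TSV dialect).
#' @param loci Path to a 4-5 column BED of focal loci.
#' @param cds_manifest Path to a TSV manifest with columns `gene`, `fasta`.
#' @param mkt_manifest Path to a TSV manifest with columns `gene`, `poly`
#'   (polymorphism TSV path), `dn`, `ds`.
#' @param out_dir Output directory (created if needed).
#' @param flank_bp,tandem_merge_bp,r2_threshold,maf_min,loess_span,mkt_cutoff
#'   Analysis parameters; see the owning functions.
#' @param seed Integer seed recorded in provenance and used for any
#'   stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = NULL, loci = NULL, cds_manifest = NULL,
                       mkt_manifest = NULL, out_dir = ".",
                       flank_bp = 50000, tandem_merge_bp = 50000,
                       r2_threshold = 0.1, maf_min = 0.05,
                       loess_span = 0.75, mkt_cutoff = 0.05, seed = 1L) {
  structure(list(panel = panel, loci = loci, cds_manifest = cds_manifest,
                 mkt_manifest = mkt_manifest, out_dir = out_dir,
                 flank_bp = flank_bp, tandem_merge_bp = tandem_merge_bp,
                 r2_threshold = r2_threshold, maf_min = maf_min,
                 loess_span = loess_span, mkt_cutoff = mkt_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

out_path <- function(cfg, name) {
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  file.path(cfg$out_dir, name)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the genomic-neighborhood LD scan
#'
#' Loads the panel and loci, builds neighborhoods with tandem merging,
#' enumerates thresholded LD pairs per neighborhood, and writes: per-GN
#' pair tables (`ld_pairs_<gn>.tsv`), a per-GN count summary
#' (`gn_ld_counts.tsv`), the clustered vs non-clustered comparison
#' (`gn_group_comparison.tsv`, when labels are present), and a LOESS decay
#' curve per neighborhood with >= 10 pairs (`ld_decay_<gn>.tsv`).
#'
#' @param cfg A [run_config()] with `panel` and `loci` set.
#' @return Invisibly, a list: `gn` table, `counts` data.frame,
#'   `comparison` (or NULL), `files` written.
#' @export
run_ld_scan <- function(cfg) {
  if (is.null(cfg$panel) || is.null(cfg$loci))
    bgcsel_stop("config", "run_ld_scan requires 'panel' and 'loci' paths")
  m <- load_variants(cfg$panel)
  m <- filter_sites(m, maf_min = cfg$maf_min)
  loci <- read_loci_bed(cfg$loci)
  gn <- build_neighborhoods(loci, flank_bp = cfg$flank_bp,
                            tandem_merge_bp = cfg$tandem_merge_bp)
  files <- character(0)
  counts <- integer(nrow(gn))
  if (n_sites(m) == 0L)
    bgcsel_warn("empty panel after filtering; emitting empty outputs")
  for (i in seq_len(nrow(gn))) {
    tab <- window_ld_pairs(m, gn[i, ], r2_threshold = cfg$r2_threshold,
                           maf_min = cfg$maf_min)
    counts[i] <- gn_ld_count(tab)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", gn$gn_id[i])
    f <- out_path(cfg, sprintf("ld_pairs_%s.tsv", safe))
    write_tsv(data.frame(gn_id = rep(gn$gn_id[i], nrow(tab)),
                         as.data.frame(tab)), f)
    files <- c(files, f)
    if (nrow(tab) >= 10L) {
      dec <- ld_decay_loess(tab, span = cfg$loess_span)
      fd <- out_path(cfg, sprintf("ld_decay_%s.tsv", safe))
      write_tsv(dec, fd)
      files <- c(files, fd)
    }
  }
  summary_df <- data.frame(gn_id = gn$gn_id, chrom = gn$chrom,
                           span_start = gn$start, span_end = gn$end,
                           group_label = gn$group_label, ld_pairs = counts)
  fs <- out_path(cfg, "gn_ld_counts.tsv")
  write_tsv(summary_df, fs)
  files <- c(files, fs)
  comparison <- NULL
  labs <- gn$group_label
  if (all(!is.na(labs)) && length(unique(labs)) == 2L &&
      min(table(labs)) >= 2L) {
    comparison <- compare_gn_groups(counts, labs)
    fc <- out_path(cfg, "gn_group_comparison.tsv")
    write_tsv(data.frame(n_clustered = comparison$n_clustered,
                         n_nonclustered = comparison$n_nonclustered,
                         mean_clustered = comparison$mean_clustered,
                         mean_nonclustered = comparison$mean_nonclustered,
                         t_statistic = comparison$t_statistic,
                         df = comparison$df,
                         p_two_sided = comparison$p_two_sided), fc)
    files <- c(files, fc)
  }
  invisible(list(gn = gn, counts = summary_df, comparison = comparison,
                 files = files))
}

#' Run the per-gene dN/dS batch
#'
#' For each manifest row, reads the CDS pair, computes the NG86 counting
#' estimate and the GY94 ML fit with its LRT against omega = 1, and writes
#' `dnds_results.tsv` (one row per gene and method). Per-gene failures are
#' recorded as flagged rows; the batch continues.
#'
#' @param cfg A [run_config()] with `cds_manifest` set.
#' @return Invisibly, the results data.frame.
#' @export
run_dnds_batch <- function(cfg) {
  if (is.null(cfg$cds_manifest))
    bgcsel_stop("config", "run_dnds_batch requires 'cds_manifest'")
  man <- read.table(cfg$cds_manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(man) > 0 && !all(c("gene", "fasta") %in% names(man)))
    bgcsel_stop("format", "CDS manifest needs columns 'gene' and 'fasta'")
  rows <- list()
  for (i in seq_len(nrow(man))) {
    gene <- man$gene[i]
    row <- tryCatch({
      aln <- read_codon_pair_fasta(man$fasta[i])
      ngr <- ng86(aln)
      mlr <- lrt_omega(aln)
      rbind(
        data.frame(gene = gene, method = "NG86", dN = ngr$dN, dS = ngr$dS,
                   omega = ngr$omega, logL_free = NA, logL_null = NA,
                   lrt = NA, p = NA, sig_001 = NA,
                   flags = paste(ngr$flags, collapse = ";")),
        data.frame(gene = gene, method = "ML", dN = mlr$dN, dS = mlr$dS,
                   omega = mlr$omega, logL_free = mlr$logL_free,
                   logL_null = mlr$logL_null, lrt = mlr$lrt_stat,
                   p = mlr$p_value, sig_001 = mlr$significant_001,
                   flags = paste(mlr$flags, collapse = ";")))
    }, bgcsel_error = function(e) {
      data.frame(gene = gene, method = NA, dN = NA, dS = NA, omega = NA,
                 logL_free = NA, logL_null = NA, lrt = NA, p = NA,
                 sig_001 = NA, flags = paste0("error:", conditionMessage(e)))
    })
    rows[[length(rows) + 1L]] <- row
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), method = character(), dN = numeric(),
               dS = numeric(), omega = numeric(), logL_free = numeric(),
               logL_null = numeric(), lrt = numeric(), p = numeric(),
               sig_001 = logical(), flags = character())
  write_tsv(res, out_path(cfg, "dnds_results.tsv"))
  invisible(res)
}

#' Run the MKT batch (standard, FWW, eMKT)
#'
#' For each manifest row (`gene`, `poly` TSV path, `dn`, `ds`), runs the
#' three test variants and writes `mkt_results.tsv`. Per-gene failures are
#' recorded as flagged rows; the batch continues.
#'
#' @param cfg A [run_config()] with `mkt_manifest` set.
#' @return Invisibly, the results data.frame.
#' @export
run_mkt_batch <- function(cfg) {
  if (is.null(cfg$mkt_manifest))
    bgcsel_stop("config", "run_mkt_batch requires 'mkt_manifest'")
  man <- read.table(cfg$mkt_manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(man) > 0 && !all(c("gene", "poly", "dn", "ds") %in% names(man)))
    bgcsel_stop("format", "MKT manifest needs columns gene, poly, dn, ds")
  rows <- list()
  as_row <- function(gene, r) {
    data.frame(gene = gene, variant = r$variant, Pn_used = r$Pn_used,
               Ps_used = r$Ps_used, Dn = r$Dn, Ds = r$Ds, alpha = r$alpha,
               neutrality_index = r$neutrality_index, fisher_p = r$fisher_p,
               P_wd = r$P_wd, cutoff = r$cutoff,
               flags = paste(r$flags, collapse = ";"))
  }
  for (i in seq_len(nrow(man))) {
    gene <- man$gene[i]
    row <- tryCatch({
      poly <- read_polymorphism_tsv(man$poly[i])
      div <- divergence_counts(man$dn[i], man$ds[i])
      rbind(as_row(gene, standard_mkt(poly, div)),
            as_row(gene, fww_mkt(poly, div, cutoff = cfg$mkt_cutoff)),
            as_row(gene, extended_mkt(poly, div, cutoff = cfg$mkt_cutoff)))
    }, bgcsel_error = function(e) {
      data.frame(gene = gene, variant = NA, Pn_used = NA, Ps_used = NA,
                 Dn = NA, Ds = NA, alpha = NA, neutrality_index = NA,
                 fisher_p = NA, P_wd = NA, cutoff = NA,
                 flags = paste0("error:", conditionMessage(e)))
    })
    rows[[length(rows) + 1L]] <- row
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), variant = character(), Pn_used = numeric(),
               Ps_used = numeric(), Dn = numeric(), Ds = numeric(),
               alpha = numeric(), neutrality_index = numeric(),
               fisher_p = numeric(), P_wd = numeric(), cutoff = numeric(),
               flags = character())
  write_tsv(res, out_path(cfg, "mkt_results.tsv"))
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `ldscan`, `dnds`, `mktest`, `simulate`. Flags are
#' `--key value` pairs matching [run_config()] fields (`--panel`,
#' `--loci`, `--cds-manifest`, `--mkt-manifest`, `--out`, `--seed`, ...)
#' plus, for `simulate`, `--what panel|codons|mktable`. Returns an exit
#' status (0 on success) rather than quitting, so it is testable
#' in-process; the installed `bgcsel` script wraps it with `quit()`.
#'
#' @param args Character vector of CLI arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
bgcsel_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L)
      bgcsel_stop("config", "usage: bgcsel <ldscan|dnds|mktest|simulate> [--flags]")
    cmd <- args[1L]
    opts <- parse_cli_flags(args[-1L])
    if (!is.null(opts$config)) {
      # plain-text key = value file; explicit flags take precedence
      opts <- utils::modifyList(parse_config_file(opts$config), opts)
    }
    cfg <- run_config(panel = opts$panel, loci = opts$loci,
                      cds_manifest = opts[["cds-manifest"]],
                      mkt_manifest = opts[["mkt-manifest"]],
                      out_dir = opts$out %||% ".",
                      flank_bp = as.numeric(opts[["flank-bp"]] %||% 50000),
                      r2_threshold = as.numeric(opts[["r2-threshold"]] %||% 0.1),
                      maf_min = as.numeric(opts[["maf-min"]] %||% 0.05),
                      mkt_cutoff = as.numeric(opts[["mkt-cutoff"]] %||% 0.05),
                      seed = as.integer(opts$seed %||% 1L))
    switch(cmd,
      ldscan = run_ld_scan(cfg),
      dnds = run_dnds_batch(cfg),
      mktest = run_mkt_batch(cfg),
      simulate = cli_simulate(opts, cfg),
      bgcsel_stop("config", "unknown subcommand '%s'", cmd))
    0L
  }, error = function(e) {
    message("bgcsel error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_config_file <- function(path) {
  if (!file.exists(path))
    bgcsel_stop("config", "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  opts <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=[:space:]]+")[[1L]]
    if (length(kv) != 2L)
      bgcsel_stop("config", "config file %s: malformed line '%s'", path, ln)
    opts[[kv[1L]]] <- kv[2L]
  }
  opts
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      bgcsel_stop("config", "unexpected argument '%s'", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args))
      bgcsel_stop("config", "flag --%s needs a value", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_simulate <- function(opts, cfg) {
  what <- opts$what %||% "panel"
  seed <- as.integer(opts$seed %||% 1L)
  if (what == "panel") {
    scfg <- sweep_sim_config(s = as.numeric(opts$s %||% 0), seed = seed)
    sim <- simulate_panel(scfg)
    write_snp_tsv(sim$matrix, out_path(cfg, "sim_panel.tsv"))
    jsonlite::write_json(sim$truth, out_path(cfg, "sim_panel_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (what == "codons") {
    aln <- simulate_codon_pair(as.integer(opts[["n-codons"]] %||% 500),
                               t = as.numeric(opts$t %||% 0.3),
                               kappa = as.numeric(opts$kappa %||% 2),
                               omega = as.numeric(opts$omega %||% 0.5),
                               seed = seed)
    writeLines(c(paste0(">", aln$id_a), aln$seq_a,
                 paste0(">", aln$id_b), aln$seq_b),
               out_path(cfg, "sim_codons.fasta"))
  } else if (what == "mktable") {
    sim <- simulate_mk_table(mk_sim_config(
      true_alpha = as.numeric(opts$alpha %||% 0), seed = seed))
    write_tsv(sim$poly, out_path(cfg, "sim_mk_poly.tsv"))
    jsonlite::write_json(c(sim$truth, Dn = sim$div$Dn, Ds = sim$div$Ds),
                         out_path(cfg, "sim_mk_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    bgcsel_stop("config", "unknown simulate target '%s'", what)
  }
  invisible(NULL)
}
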