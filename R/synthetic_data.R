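# Seeded generators emulating the statistical structure of the analysis
# inputs: a forward Wright-Fisher sweep/neutral SNP-panel simulator, a GY94
# codon-pair simulator, and a polymorphism/divergence count simulator.
# Every generator is a pure function of (config, seed) through R's
# Mersenne-Twister stream.

#' Configuration for the Wright-Fisher panel simulator
#'
#' Defaults describe a deliberately scaled-down population (hundreds of
#' haploids, a 100 kb region, inflated per-site rates) whose sampled
#' panels reach mutation-drift equilibrium in seconds while preserving the
#' qualitative LD structure of a large selfing population; this is a scaled
#' model, not a literal demography.
#'
#' @param pop_size Haploid population size N (default 200).
#' @param chrom_length Region length L in bp (default 1e5).
#' @param mu Per-site per-generation mutation rate (default 1e-6, so the
#'   population theta = 2 N mu L = 40).
#' @param rec Per-bp per-generation crossover rate; crossovers per meiosis
#'   are Poisson with mean `rec * chrom_length` (default 2e-5, i.e. two
#'   crossovers per meiosis across the region, effective rho = 2 N rec L = 800).
#' @param s Selection coefficient of the focal allele; 0 = neutral run.
#' @param focal_pos Focal position in bp (default region midpoint).
#' @param n_sample Haplotypes sampled into the output panel (default 150).
#' @param burn_in Burn-in generations before sampling (or before sweep
#'   introduction); default 10 N.
#' @param post_fix Generations of neutral evolution after fixation before
#'   sampling (default 0.1 N), so flanking LD is elevated but not absolute.
#' @param max_restarts Restarts allowed when the focal allele is lost
#'   (default 200).
#' @param fix_freq Focal-allele population frequency at which the sweep run
#'   stops (default 1 = complete sweep). Values < 1 sample an ongoing
#'   sweep; the canonical sweep scenario of this package uses
#'   `s = 4, fix_freq = 0.5, post_fix = 0`, the phase in which
#'   hitch-hiking LD is maximal.
#' @param seed Integer seed (default 1).
#' @return A list of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(pop_size = 200L, chrom_length = 100000L,
                             mu = 1e-6, rec = 2e-5, s = 0,
                             focal_pos = NULL, n_sample = 150L,
                             burn_in = NULL, post_fix = NULL,
                             max_restarts = 200L, fix_freq = 1,
                             seed = 1L) {
  focal_pos <- focal_pos %||% as.integer(chrom_length / 2)
  burn_in <- burn_in %||% 10L * pop_size
  post_fix <- post_fix %||% as.integer(0.1 * pop_size)
  if (pop_size < 2L) bgcsel_stop("validation", "pop_size must be >= 2")
  if (s < 0 || mu < 0 || rec < 0)
    bgcsel_stop("validation", "s, mu and rec must be nonnegative")
  if (focal_pos < 0 || focal_pos >= chrom_length)
    bgcsel_stop("validation", "focal_pos must lie in [0, chrom_length)")
  structure(list(pop_size = as.integer(pop_size),
                 chrom_length = as.integer(chrom_length),
                 mu = mu, rec = rec, s = s,
                 focal_pos = as.integer(focal_pos),
                 n_sample = as.integer(n_sample),
                 burn_in = as.integer(burn_in),
                 post_fix = as.integer(post_fix),
                 max_restarts = as.integer(max_restarts),
                 fix_freq = fix_freq,
                 seed = as.integer(seed)),
            class = "sweep_sim_config")
}

#' Simulate a SNP panel under neutrality or a selective sweep
#'
#' Forward Wright-Fisher simulation with multiplicative fitness 1+s for
#' the focal allele, single-crossover recombination, and infinite-sites
#' mutation. For `s > 0` the focal mutation is introduced after burn-in
#' and the sweep phase restarts from the saved equilibrium state on loss
#' (bounded by `max_restarts`); the panel is sampled `post_fix`
#' generations after fixation.
#'
#' @param cfg A [sweep_sim_config()].
#' @return A list: `matrix` (a [snp_matrix()] of the sampled haplotypes,
#'   chromosome `"sim1"`), and `truth` (`fixation_gen`, focal-allele
#'   `trajectory`, `n_restarts`).
#' @export
simulate_panel <- function(cfg) {
  if (!inherits(cfg, "sweep_sim_config"))
    bgcsel_stop("validation", "cfg must be a sweep_sim_config")
  if (cfg$n_sample > cfg$pop_size)
    bgcsel_stop("sampling", "n_sample exceeds pop_size")
  res <- with_seed(cfg$seed, {
    tryCatch(
      wf_sim_cpp(cfg$pop_size, cfg$chrom_length, cfg$mu, cfg$rec, cfg$s,
                 cfg$focal_pos, cfg$n_sample, cfg$burn_in, cfg$post_fix,
                 cfg$max_restarts, max_sweep_gens = 200L * cfg$pop_size, fix_freq = cfg$fix_freq),
      error = function(e) {
        if (grepl("failed to fix", conditionMessage(e)))
          bgcsel_stop("fixation_failure", "%s", conditionMessage(e))
        if (grepl("n_sample", conditionMessage(e)))
          bgcsel_stop("sampling", "%s", conditionMessage(e))
        stop(e)
      })
  })
  n_s <- length(res$pos)
  m <- snp_matrix(chrom = rep("sim1", n_s), pos = res$pos,
                  ref = rep("A", n_s), alt = rep("T", n_s),
                  geno = res$geno,
                  sample_ids = sprintf("acc%03d", seq_len(cfg$n_sample)))
  list(matrix = m,
       truth = list(fixation_gen = res$fixation_gen,
                    trajectory = res$trajectory,
                    n_restarts = res$n_restarts))
}

#' Nucleotide diversity (pi) of a panel window
#'
#' Mean pairwise difference per bp: sum over sites of
#' `2 f (1-f) n/(n-1)` divided by the window length.
#'
#' @param m A `snp_matrix`.
#' @param start,end Optional 0-based half-open window (defaults: whole
#'   observed position range).
#' @param length_bp Window length used as denominator (default `end - start`).
#' @return Per-bp nucleotide diversity.
#' @export
nucleotide_diversity <- function(m, start = NULL, end = NULL,
                                 length_bp = NULL) {
  start <- start %||% (min(m$pos) - 1L)
  end <- end %||% max(m$pos)
  length_bp <- length_bp %||% (end - start)
  keep <- m$pos > start & m$pos <= end
  if (!any(keep)) return(0)
  g <- m$geno[keep, , drop = FALSE]
  n <- rowSums(!is.na(g))
  f <- rowMeans(g, na.rm = TRUE)
  ok <- n > 1
  sum(2 * f[ok] * (1 - f[ok]) * n[ok] / (n[ok] - 1)) / length_bp
}

#' Simulate a codon-pair alignment under the GY94 model
#'
#' Draws an ancestor from `codon_freqs` and evolves two independent
#' lineages for `t/2` each under the same scaled rate matrix as
#' [gy94_loglik()].
#'
#' @param n_codons Number of codon sites.
#' @param t Total divergence (expected substitutions per codon between the
#'   two sequences).
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS ratio.
#' @param codon_freqs Sense-codon frequencies (default equal, 1/61).
#' @param seed Integer seed or NULL.
#' @return A `codon_alignment`.
#' @export
simulate_codon_pair <- function(n_codons, t, kappa, omega,
                                codon_freqs = NULL, seed = NULL) {
  if (n_codons < 1 || t < 0 || kappa <= 0 || omega <= 0)
    bgcsel_stop("validation", "invalid GY94 simulation parameters")
  codon_freqs <- validate_codon_freqs(codon_freqs %||% equal_codon_freqs())
  cd <- codon_data()
  with_seed(seed, {
    anc <- sample.int(cd$n, n_codons, replace = TRUE, prob = codon_freqs)
    if (t == 0) {
      ca <- cb <- anc
    } else {
      eig <- gy94_eigen(kappa, omega, codon_freqs)
      P <- gy94_prob(eig, t / 2)
      P <- P / rowSums(P)
      evolve <- function(from) {
        out <- integer(length(from))
        for (state in unique(from)) {
          rows <- which(from == state)
          out[rows] <- sample.int(cd$n, length(rows), replace = TRUE,
                                  prob = P[state, ])
        }
        out
      }
      ca <- evolve(anc); cb <- evolve(anc)
    }
    structure(list(seq_a = paste(cd$sense[ca], collapse = ""),
                   seq_b = paste(cd$sense[cb], collapse = ""),
                   n_codons = n_codons, n_dropped = 0L,
                   id_a = "sim_a", id_b = "sim_b"),
              class = "codon_alignment")
  })
}

#' Configuration for the polymorphism/divergence simulator
#'
#' The generator emulates per-gene McDonald-Kreitman inputs: Poisson
#' polymorphism and divergence counts whose class-proportional intensities
#' give an expected adaptive fraction `true_alpha`, plus an optional
#' weakly deleterious nonsynonymous load segregating at rare frequencies.
#'
#' @param true_alpha Expected adaptive fraction of nonsynonymous
#'   substitutions, < 1 (default 0).
#' @param Ln,Ls Nonsynonymous / synonymous site totals (defaults 1000, 400,
#'   a typical ~3:1 gene-length split).
#' @param theta Per-site polymorphism intensity (default 0.05).
#' @param lambda Per-site divergence intensity (default 0.1).
#' @param constraint Fraction of nonsynonymous mutations that are neutral
#'   (escape purifying selection); default 0.25.
#' @param deleterious_fraction Fraction of nonsynonymous polymorphisms that
#'   are weakly deleterious (default 0).
#' @param del_beta Shape parameters of the Beta frequency distribution of
#'   deleterious variants (default c(0.5, 12): strongly rare-skewed).
#' @param n_chroms Sample depth defining the neutral frequency grid
#'   (default 100).
#' @param seed Integer seed (default 1).
#' @return A list of class `mk_sim_config`.
#' @export
mk_sim_config <- function(true_alpha = 0, Ln = 1000, Ls = 400, theta = 0.05,
                          lambda = 0.1, constraint = 0.25,
                          deleterious_fraction = 0,
                          del_beta = c(0.5, 12), n_chroms = 100L, seed = 1L) {
  if (true_alpha >= 1) bgcsel_stop("validation", "true_alpha must be < 1")
  if (theta <= 0 || lambda <= 0)
    bgcsel_stop("validation", "intensities must be positive")
  if (deleterious_fraction < 0 || deleterious_fraction >= 1)
    bgcsel_stop("validation", "deleterious_fraction must be in [0, 1)")
  structure(list(true_alpha = true_alpha, Ln = Ln, Ls = Ls, theta = theta,
                 lambda = lambda, constraint = constraint,
                 deleterious_fraction = deleterious_fraction,
                 del_beta = del_beta, n_chroms = as.integer(n_chroms),
                 seed = as.integer(seed)),
            class = "mk_sim_config")
}

# Neutral sample frequencies follow the standard neutral SFS, P(i) ~ 1/i
# over i = 1..n-1 copies in a sample of n chromosomes.
r_neutral_freq <- function(k, n_chroms) {
  i <- seq_len(n_chroms - 1L)
  sample(i, k, replace = TRUE, prob = 1 / i) / n_chroms
}

#' Simulate a polymorphism table and divergence counts
#'
#' Draws `Ps ~ Pois(theta Ls)`, neutral `Pn ~ Pois(theta Ln constraint)`,
#' `Ds ~ Pois(lambda Ls)` and `Dn` as a neutral part
#' `Pois(lambda Ln constraint)` plus an adaptive part
#' `Pois(lambda Ln constraint alpha/(1-alpha))`, so the expected
#' McDonald-Kreitman alpha equals `true_alpha`. Weakly deleterious
#' nonsynonymous polymorphisms (if requested) are added with
#' Beta-distributed rare-skewed frequencies.
#'
#' @param cfg An [mk_sim_config()].
#' @return A list: `poly` (a [polymorphism_table()]), `div`
#'   (a [divergence_counts()]), and `truth` (`true_alpha`, `n_deleterious`).
#' @export
simulate_mk_table <- function(cfg) {
  if (!inherits(cfg, "mk_sim_config"))
    bgcsel_stop("validation", "cfg must be an mk_sim_config")
  with_seed(cfg$seed, {
    mu_pn <- cfg$theta * cfg$Ln * cfg$constraint
    Ps <- rpois(1L, cfg$theta * cfg$Ls)
    Pn_neu <- rpois(1L, mu_pn)
    Pn_del <- if (cfg$deleterious_fraction > 0)
      rpois(1L, mu_pn * cfg$deleterious_fraction / (1 - cfg$deleterious_fraction))
    else 0L
    Ds <- rpois(1L, cfg$lambda * cfg$Ls)
    Dn <- rpois(1L, cfg$lambda * cfg$Ln * cfg$constraint) +
      rpois(1L, cfg$lambda * cfg$Ln * cfg$constraint *
              cfg$true_alpha / (1 - cfg$true_alpha))
    freqs <- c(r_neutral_freq(Ps, cfg$n_chroms),
               r_neutral_freq(Pn_neu, cfg$n_chroms),
               if (Pn_del > 0)
                 pmin(pmax(rbeta(Pn_del, cfg$del_beta[1L], cfg$del_beta[2L]),
                           1 / (2 * cfg$n_chroms)), 1 - 1 / (2 * cfg$n_chroms)))
    classes <- c(rep("synonymous", Ps),
                 rep("nonsynonymous", Pn_neu + Pn_del))
    n_tot <- Ps + Pn_neu + Pn_del
    poly <- polymorphism_table(sprintf("s%04d", seq_len(n_tot)),
                               classes, freqs, frequency_type = "derived")
    list(poly = poly, div = divergence_counts(Dn, Ds, cfg$Ln, cfg$Ls),
         truth = list(true_alpha = cfg$true_alpha, n_deleterious = Pn_del))
  })
}
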