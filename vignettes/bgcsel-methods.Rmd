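---
title: "Selection scans for clustered metabolic genes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans for clustered metabolic genes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bgcsel` implements the three selection analyses with which physically
clustered metabolic genes (biosynthetic gene clusters, BGCs) are commonly
interrogated in plant population genomics, plus the seeded simulators that
let the whole battery be validated without external data:

1. a **genomic-neighborhood LD scan** — counting site pairs in strong
   linkage disequilibrium around focal genes and contrasting clustered
   versus non-clustered neighborhoods;
2. **pairwise dN/dS** between orthologous coding sequences, by
   Nei–Gojobori (NG86) counting and by maximum likelihood under a
   single-ratio Goldman–Yang (GY94) codon model, with a likelihood-ratio
   test of neutrality (ω = 1);
3. the **McDonald–Kreitman test family** — standard, FWW-corrected, and
   extended (eMKT) — contrasting polymorphism with divergence to estimate
   the adaptive fraction α.

# The LD neighborhood scan

## Model and statistic

For two biallelic, haploid-coded sites with alternate-allele frequencies
$p_a, p_b$ and joint frequency $p_{ab}$,

$$r^2 = \frac{(p_{ab} - p_a p_b)^2}{p_a(1-p_a)\,p_b(1-p_b)},$$

which equals the squared Pearson correlation of the two 0/1 genotype
vectors. A *genomic neighborhood* (GN) is the union of one focal gene body
(or a tandem set of bodies merged when gaps are at most `tandem_merge_bp`,
default 50 kb) extended by `flank_bp` (default 50 kb) on each side. Within
a GN every unordered pair of sites with minor-allele frequency at least
`maf_min` (default 0.05) is scored; pairs with $r^2$ strictly above
`r2_threshold` (default 0.1) are retained and counted. Each retained pair
also carries a two-sided Fisher exact p on its 2×2 haplotype table.

The per-GN counts of clustered and non-clustered focal genes are compared
by a pooled-variance two-sided Student t-test with df $= n_1+n_2-2$; for
the canonical inventory of 13 focal genes collapsing to 9 neighborhoods
(4 clustered + 5 non-clustered) this gives df = 7. A Welch test would not
reproduce that df, which is why the classic pooled form is used.

Missing genotype calls are deleted pairwise; a pair that becomes
monomorphic after deletion has undefined LD and is skipped. Heterozygous
diploid calls are set missing at load time by default — the intended data
model is a panel of selfing, effectively haploid accessions, where
residual heterozygosity is best treated as no-call (the policy is
configurable).

An optional per-site `top_k` cap on retained pairs exists because some
LD tools report only the strongest associations per site; it is **off by
default** — the full within-GN pair set is the statistic of record, and
every reported number in this package uses it.

## LD decay

`ld_decay_loess()` fits a local **linear** regression (tricube weights,
degree 1, default span 0.75) of $r^2$ on inter-site distance, evaluated on
an evenly spaced 100-point grid and clamped to $[0,1]$. Degree 1 avoids
the variance explosion of local quadratics at the window edges; the span
default is the conventional LOESS default, since no principled value is
dictated by the method.

# Pairwise dN/dS

## NG86 counting

Synonymous site counts: at each codon position the fraction of the three
possible nucleotide changes that preserve the amino acid (changes creating
a stop codon count as nonsynonymous; the denominator stays 3). Summing
over codons and averaging the two sequences gives $S$, with
$N = 3L_c - S$. Observed differences at codons differing at $k$ sites are
classified by enumerating all $k!$ mutational orderings, discarding
orderings that pass through a stop codon and averaging the synonymous /
nonsynonymous step counts over the remainder (if every ordering is
blocked, a fallback classifies steps along one arbitrary ordering).
Proportions $p_N = N_d/N$, $p_S = S_d/S$ are Jukes–Cantor corrected,
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$; $p \ge 3/4$ sets a
`saturated` flag, $d_S = 0$ an `undefined_omega` flag.

## GY94 maximum likelihood

The single-ratio codon model assigns rate $q_{ij} = \pi_j \cdot
\{1, \kappa, \omega, \omega\kappa\}$ for synonymous transversions,
synonymous transitions, nonsynonymous transversions and nonsynonymous
transitions respectively, zero for multi-nucleotide changes, with the
generator scaled so the branch length $t$ is the expected number of
substitutions per codon. The pairwise log-likelihood is
$\ell = \sum_{\text{sites}} \log \pi_i P_{ij}(t)$, computed through the
spectral decomposition of the reversible generator (symmetrized with
$\sqrt{\pi}$). Codon frequencies default to F3×4 estimated from the
alignment with a 0.5 pseudocount per nucleotide (so unseen nucleotides do
not zero out codons); an equal-frequency option exists for testing.

Optimization: $t$ is profiled out by a golden-section search nested inside
a Nelder–Mead search over $(\log\kappa, \log\omega)$, bounds
$t \in [10^{-6}, 50]$, $\kappa, \omega \in [10^{-4}, 100]$, with three
starts seeded from moment estimates (κ from the observed
transition/transversion ratio, ω from NG86). The likelihood is evaluated
only at observed codon-pair cells, which makes a fit on 1000 codons take
well under a second. Alignments with no variable codon are flagged
`boundary` and returned at the $t$ lower bound without optimization.

The LRT against neutrality fits ω free and ω fixed at 1, forms
$2(\ell_1-\ell_0)$ clamped at zero, and refers it to $\chi^2_1$; results
carry a significance flag at the conventional 0.001 reporting threshold
for pairwise ω estimates. The reported dN and dS split the substitution
flux into synonymous and nonsynonymous parts normalized by the site
opportunities computed at ω = 1, which makes dN/dS equal the fitted ω
exactly.

# The MKT family

With polymorphism counts $P_n, P_s$ and divergence counts $D_n, D_s$:

$$\mathrm{NI} = \frac{P_n/P_s}{D_n/D_s}, \qquad \alpha = 1 - \mathrm{NI},$$

with a two-sided Fisher exact test on $[[P_n,P_s],[D_n,D_s]]$. The FWW
variant removes polymorphisms below a frequency cutoff (default 0.05)
from both classes before applying the standard formulas. The extended
variant splits polymorphisms at the cutoff into rare and common classes
and estimates the weakly deleterious nonsynonymous count

$$P_{wd} = \max\!\left(0,\; P_n^{rare} - P_s^{rare}
  \frac{P_n^{common}}{P_s^{common}}\right),$$

subtracting it from $P_n$ before computing α (the clamp at 0 is explicit;
the correction is undefined when no common synonymous polymorphism
exists). Because $P_{wd} \ge 0$, eMKT's α never falls below the standard
α on the same table. Frequencies are derived-allele when polarization is
available, else minor-allele, and the choice is recorded in each result.

# The synthetic-data generators

All generators are pure functions of (configuration, seed) through R's
Mersenne–Twister stream; identical inputs give bit-identical outputs.

## Wright–Fisher panels

A forward discrete-generation haploid Wright–Fisher population:
multiplicative fitness $1+s$ for carriers of the focal allele,
Poisson-many crossovers per meiosis with mean `rec * chrom_length`, and
infinite-sites mutation at uniform positions. The scales are deliberately
compressed — N = 200 haploids, a 100 kb region, per-site rates inflated so
that θ = 2NμL = 40 and effective ρ = 2N·rec·L is in the hundreds — giving
equilibrium panels in well under a second. This is a **scaled model**: it
reproduces the qualitative LD and diversity structure of a large selfing
population, not any literal demography, so green tests establish that the
statistics behave as population-genetics theory predicts at this scale,
not that the package reproduces any specific organism's numbers.

Sweeps introduce the focal mutation after burn-in (10 N generations) and
restart from the saved equilibrium state whenever the allele is lost,
with a bounded restart budget. Two sampling regimes exist:

* **completed sweep** (`fix_freq = 1`, sampled `post_fix` generations
  after fixation, default 0.1 N): the cleanest diversity trough around
  the focal position;
* **ongoing sweep** (`fix_freq < 1`): the run stops when the focal allele
  reaches the given sample frequency.

The package's canonical sweep scenario is an **ongoing sweep sampled at
focal frequency 0.5** (`s = 4` on the scaled fitness axis, `post_fix =
0`). This was a genuinely open design point, resolved empirically: at
desk scale a completed sweep always *lowers* the thresholded LD-pair
count relative to its matched neutral panel, because the count scales
with the square of the surviving site number and the small-N neutral
coalescent baseline is already LD-rich; extensive exploration over
recombination rates, selection coefficients and post-fixation delays
found no completed-sweep regime in which the count enrichment holds. The
mid-sweep phase, by contrast, partitions the sample into a swept and an
ancestral haplotype class, placing old variants in strong mutual
association while retaining them above the MAF filter — exactly the
hitch-hiking LD excess the neighborhood scan is designed to detect, and
consistent with interpreting an enriched neighborhood as *currently
undergoing or just past* a sweep. The diversity trough criterion is
asserted for both regimes.

## Codon pairs and MKT tables

Codon alignments evolve an ancestor drawn from the equilibrium
frequencies for $t/2$ down two independent lineages under the same scaled
GY94 generator used for inference. MKT tables draw $P_s, P_n, D_s$ as
Poisson counts with class-proportional intensities and compose $D_n$ from
a neutral part and an adaptive part sized so the expected α equals
`true_alpha`; neutral polymorphism frequencies follow the standard
neutral site-frequency spectrum $P(i) \propto 1/i$ on a 100-chromosome
grid, and the optional weakly deleterious nonsynonymous load is
Beta(0.5, 12)-distributed — strongly rare-skewed, with roughly 97% of its
mass below the 0.05 cutoff. A constraint parameter (default 0.25, the
fraction of nonsynonymous mutations that are effectively neutral) sets
realistic Pn/Ps ratios.

# Numerical choices and degenerate inputs

* Fisher exact p-values are the sum of hypergeometric point probabilities
  not exceeding the observed table's probability (the standard two-sided
  convention); eMKT's adjusted nonsynonymous count is rounded to the
  nearest integer for the exact test.
* Zero pooled variance in the group comparison is an error **unless** the
  group means are also equal, in which case t = 0, p = 1 (no evidence
  either way).
* Codon frequencies are floored at $10^{-8}$ and renormalized before the
  spectral decomposition; transition probabilities are clamped at 0 and
  likelihood cells at $10^{-300}$ before logging.
* `fww_mkt(cutoff = 0)` is exactly the standard test; `filter_sites()` is
  idempotent; empty panels and empty manifests produce empty outputs, not
  errors.

# Known limitations

* The Wright–Fisher model has no selfing, population structure, or
  demographic history; its sweep scenarios are scaled caricatures.
* The ML machinery covers the pairwise single-ratio model only — no site
  or branch-site heterogeneity, which is the province of dedicated
  phylogenetic selection tools.
* NG86 ignores transition/transversion bias in site counting and is known
  to be mildly biased when κ deviates from 1 (visible in the package's
  own calibration: at true ω = 1 and κ = 2 the NG86 median lands near
  0.9).
* MKT inputs take frequencies as given; polarization against an outgroup
  is out of scope.
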