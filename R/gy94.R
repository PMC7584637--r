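# Single-ratio Goldman-Yang (GY94) codon model for pairwise ML estimation
# of omega and the likelihood-ratio test against omega = 1.
#
# Rates between sense codons differing at one nucleotide are
# pi_j * {1, kappa, omega, omega*kappa} for {syn transversion, syn
# transition, nonsyn transversion, nonsyn transition}; multi-nucleotide
# changes are instantaneously impossible. The matrix is scaled so the
# expected number of substitutions per codon equals the branch length t.

# Unscaled symmetric exchangeability parts: rate q_ij = x_ij * pi_j with
# x_ij in {1, kappa} times {1, omega}.
gy94_rate_parts <- function(kappa, omega) {
  cd <- codon_data()
  fac <- ifelse(cd$pair_ts, kappa, 1) * ifelse(cd$pair_syn, 1, omega)
  list(i = cd$pair_i, j = cd$pair_j, fac = fac)
}

# Build the scaled generator; also return the syn fraction of total flux
# (used for the dN/dS decomposition).
gy94_q <- function(kappa, omega, codon_freqs) {
  cd <- codon_data()
  rp <- gy94_rate_parts(kappa, omega)
  Q <- matrix(0, cd$n, cd$n)
  Q[cbind(rp$i, rp$j)] <- rp$fac * codon_freqs[rp$j]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(codon_freqs * diag(Q))
  if (rate <= 0)
    bgcsel_stop("validation", "degenerate rate matrix")
  flux <- codon_freqs[rp$i] * rp$fac * codon_freqs[rp$j]
  list(Q = Q / rate, rho_syn = sum(flux[cd$pair_syn]) / sum(flux))
}

# Spectral decomposition via the GTR symmetrization trick:
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric, so
# P(t) = diag(1/sqrt(pi)) V exp(L t) V' diag(sqrt(pi)).
gy94_eigen <- function(kappa, omega, codon_freqs) {
  qq <- gy94_q(kappa, omega, codon_freqs)
  sp <- sqrt(codon_freqs)
  B <- outer(sp, 1 / sp) * qq$Q  # B_ij = sp_i Q_ij / sp_j (symmetric)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(left = e$vectors / sp, right = t(e$vectors * sp), lambda = e$values,
       rho_syn = qq$rho_syn)
}

gy94_prob <- function(eig, t) {
  P <- (eig$left * rep(exp(eig$lambda * t), each = nrow(eig$left))) %*% eig$right
  pmax(P, 0)
}

validate_codon_freqs <- function(codon_freqs) {
  cd <- codon_data()
  if (length(codon_freqs) != cd$n || any(!is.finite(codon_freqs)) ||
      any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-6)
    bgcsel_stop("validation",
                "codon_freqs must be a %d-vector of nonnegative values summing to 1",
                cd$n)
  # floor zero frequencies so the symmetrization stays defined
  f <- pmax(codon_freqs, 1e-8)
  f / sum(f)
}

#' Empirical F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies pooled over both sequences,
#' multiplied across the three codon positions, with stop codons removed
#' and the vector renormalized (the codeml default frequency model).
#'
#' @param aln A `codon_alignment`.
#' @return Numeric 61-vector over sense codons.
#' @export
f3x4_freqs <- function(aln) {
  cd <- codon_data()
  nt <- c("A", "C", "G", "T")
  chars <- rbind(matrix(strsplit(aln$seq_a, "")[[1L]], ncol = 3, byrow = TRUE),
                 matrix(strsplit(aln$seq_b, "")[[1L]], ncol = 3, byrow = TRUE))
  posf <- sapply(1:3, function(p) {
    f <- table(factor(chars[, p], levels = nt))
    f <- f + 0.5  # pseudocount keeps unseen nucleotides usable
    as.numeric(f / sum(f))
  })
  sm <- matrix(unlist(strsplit(cd$sense, "")), ncol = 3, byrow = TRUE)
  f <- posf[match(sm[, 1], nt), 1] * posf[match(sm[, 2], nt), 2] *
    posf[match(sm[, 3], nt), 3]
  f / sum(f)
}

#' Equal sense-codon frequencies (1/61 each)
#' @return Numeric 61-vector.
#' @export
equal_codon_freqs <- function() {
  cd <- codon_data()
  rep(1 / cd$n, cd$n)
}

#' GY94 pairwise log-likelihood
#'
#' Log-likelihood of an aligned codon pair under the single-ratio GY94
#' model: sum over codon sites of log( pi_i P_ij(t) ), with the generator
#' scaled so t is the expected number of substitutions per codon.
#'
#' @param aln A `codon_alignment`.
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio, > 0.
#' @param codon_freqs Equilibrium sense-codon frequencies (61-vector
#'   summing to 1).
#' @return Log-likelihood (scalar).
#' @export
gy94_loglik <- function(aln, t, kappa, omega, codon_freqs) {
  if (t < 0 || kappa <= 0 || omega <= 0)
    bgcsel_stop("validation", "need t >= 0 and kappa, omega > 0")
  codon_freqs <- validate_codon_freqs(codon_freqs)
  counts <- codon_pair_counts(aln)
  gy94_loglik_counts(counts, t, kappa, omega, codon_freqs)
}

gy94_loglik_counts <- function(counts, t, kappa, omega, codon_freqs,
                               eig = NULL) {
  if (is.null(eig)) eig <- gy94_eigen(kappa, omega, codon_freqs)
  P <- gy94_prob(eig, t)
  lik <- codon_freqs * P
  nz <- counts > 0
  sum(counts[nz] * log(pmax(lik[nz], 1e-300)))
}

# Sparse-cell evaluation: the alignment only touches a few hundred of the
# 61^2 codon-pair cells, and P_ij(t) = sum_k left_ik exp(lambda_k t) right_kj,
# so the per-cell spectral weights can be assembled once per (kappa, omega)
# and the likelihood evaluated at any t with a single 61 x M product.
gy94_cells <- function(counts) {
  nz <- which(counts > 0, arr.ind = TRUE)
  list(i = nz[, 1L], j = nz[, 2L], n = counts[nz])
}

gy94_cell_weights <- function(eig, cells) {
  # W[k, m] = left[i_m, k] * right[k, j_m]
  t(eig$left[cells$i, , drop = FALSE]) * eig$right[, cells$j, drop = FALSE]
}

gy94_loglik_cells <- function(cells, W, eig, t, codon_freqs) {
  p <- as.vector(crossprod(W, exp(eig$lambda * t)))
  sum(cells$n * log(pmax(codon_freqs[cells$i] * p, 1e-300)))
}

#' Maximum-likelihood fit of the pairwise GY94 model
#'
#' Maximizes the [gy94_loglik()] over branch length t, kappa, and
#' (unless fixed) omega. Optimization is on log-transformed parameters
#' with a 3-start strategy; the branch length is profiled out by a 1-D
#' search nested inside the (kappa, omega) search. Bounds:
#' t in \[1e-6, 50\], kappa and omega in \[1e-4, 100\].
#'
#' @param aln A `codon_alignment`.
#' @param fix_omega Optional fixed omega (e.g. 1 for the neutral null).
#' @param codon_freqs Codon frequencies; default F3x4 estimated from the
#'   alignment ([f3x4_freqs()]).
#' @param n_starts Number of optimizer starts (default 3).
#' @return List with `t`, `kappa`, `omega`, `logL`, `convergence`
#'   (0 = converged), `flags`.
#' @export
fit_pairwise_ml <- function(aln, fix_omega = NULL, codon_freqs = NULL,
                            n_starts = 3L) {
  codon_freqs <- validate_codon_freqs(codon_freqs %||% f3x4_freqs(aln))
  counts <- codon_pair_counts(aln)
  n_diff <- sum(counts) - sum(diag(counts))
  flags <- character(0)
  if (n_diff == 0) {
    # no variable codons: likelihood is maximized at the t lower bound and
    # is flat in kappa and omega
    om <- fix_omega %||% 1
    ll <- gy94_loglik_counts(counts, 1e-6, 1, om, codon_freqs)
    return(list(t = 1e-6, kappa = 1, omega = om, logL = ll,
                convergence = 0L, flags = "boundary"))
  }
  lt_lo <- log(1e-6); lt_hi <- log(50)
  lk_lo <- log(1e-4); lk_hi <- log(100)
  cells <- gy94_cells(counts)

  profile_t <- function(kappa, omega) {
    eig <- gy94_eigen(kappa, omega, codon_freqs)
    W <- gy94_cell_weights(eig, cells)
    op <- optimize(function(lt)
      gy94_loglik_cells(cells, W, eig, exp(lt), codon_freqs),
      interval = c(lt_lo, lt_hi), maximum = TRUE, tol = 1e-6)
    list(lt = op$maximum, ll = op$objective)
  }

  mom <- gy94_moment_starts(aln)
  starts <- list(c(lk = mom$lk, lw = mom$lw),
                 c(lk = mom$lk + 0.7, lw = mom$lw - 0.7),
                 c(lk = mom$lk - 0.7, lw = mom$lw + 0.7))[seq_len(max(1L, n_starts))]
  best <- NULL
  for (st in starts) {
    if (is.null(fix_omega)) {
      obj <- function(par) {
        par <- pmin(pmax(par, lk_lo), lk_hi)
        -profile_t(exp(par[1L]), exp(par[2L]))$ll
      }
      op <- optim(st, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-9, maxit = 300))
      par <- pmin(pmax(op$par, lk_lo), lk_hi)
      kappa <- exp(par[1L]); omega <- exp(par[2L]); conv <- op$convergence
    } else {
      op <- optimize(function(lk) -profile_t(exp(lk), fix_omega)$ll,
                     interval = c(lk_lo, lk_hi), tol = 1e-7)
      kappa <- exp(op$minimum); omega <- fix_omega; conv <- 0L
    }
    pr <- profile_t(kappa, omega)
    cand <- list(t = exp(pr$lt), kappa = kappa, omega = omega, ll = pr$ll,
                 conv = conv)
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }
  if (best$conv != 0L) flags <- c(flags, "non_convergence")
  if (best$t <= 1.5e-6 || best$t >= 49) flags <- c(flags, "boundary")
  list(t = unname(best$t), kappa = unname(best$kappa),
       omega = unname(best$omega), logL = unname(best$ll),
       convergence = best$conv, flags = flags)
}

# Crude moment starting values: kappa from the observed transition /
# transversion difference ratio (tv opportunity is ~2x ts), omega from the
# NG86 point estimate. Good starts cut optimizer cost substantially.
gy94_moment_starts <- function(aln) {
  nt <- c("A", "C", "G", "T")
  a <- strsplit(aln$seq_a, "")[[1L]]; b <- strsplit(aln$seq_b, "")[[1L]]
  d <- which(a != b)
  ts <- sum((a[d] %in% c("A", "G")) == (b[d] %in% c("A", "G")))
  tv <- length(d) - ts
  k0 <- if (tv > 0) 2 * ts / tv else 4
  w0 <- tryCatch(ng86(aln)$omega, error = function(e) NA_real_)
  if (!is.finite(w0)) w0 <- 0.5
  list(lk = log(min(max(k0, 0.5), 20)), lw = log(min(max(w0, 0.05), 5)))
}

# dN and dS per site implied by fitted (t, kappa, omega, pi): substitution
# flux is split into syn/nonsyn parts and divided by the syn/nonsyn site
# opportunity computed at omega = 1, so that dN/dS = omega exactly.
ml_dn_ds <- function(t, kappa, omega, codon_freqs) {
  rho <- gy94_q(kappa, omega, codon_freqs)$rho_syn
  rho0 <- gy94_q(kappa, 1, codon_freqs)$rho_syn
  dS <- t * rho / (3 * rho0)
  dN <- t * (1 - rho) / (3 * (1 - rho0))
  c(dN = dN, dS = dS)
}

#' Likelihood-ratio test of omega = 1
#'
#' Fits the pairwise GY94 model twice -- omega free and omega fixed at 1 --
#' and compares 2(lnL_free - lnL_null) to a chi-squared distribution with
#' one degree of freedom (statistic clamped at 0). The result flags
#' significance at the 0.001 level, the conventional reporting threshold
#' for pairwise omega estimates.
#'
#' @param aln A `codon_alignment`.
#' @param codon_freqs Codon frequencies (default F3x4 from the alignment).
#' @param n_starts Optimizer starts per fit (default 3).
#' @return A `dnds_result` with `method = "ML"`: `omega`, `dN`, `dS`,
#'   `logL_free`, `logL_null`, `lrt_stat`, `p_value`, `t`, `kappa`,
#'   `significant_001`, `flags`.
#' @export
lrt_omega <- function(aln, codon_freqs = NULL, n_starts = 3L) {
  codon_freqs <- validate_codon_freqs(codon_freqs %||% f3x4_freqs(aln))
  free <- fit_pairwise_ml(aln, codon_freqs = codon_freqs, n_starts = n_starts)
  null <- fit_pairwise_ml(aln, fix_omega = 1, codon_freqs = codon_freqs,
                          n_starts = n_starts)
  lrt <- max(0, 2 * (free$logL - null$logL))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  dd <- ml_dn_ds(free$t, free$kappa, free$omega, codon_freqs)
  dnds_result(method = "ML", dN = dd[["dN"]], dS = dd[["dS"]],
              omega = free$omega, logL_free = free$logL,
              logL_null = null$logL, lrt_stat = lrt, p_value = p,
              t = free$t, kappa = free$kappa,
              flags = unique(c(free$flags, null$flags)),
              significant_001 = p < 0.001)
}
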