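#' Coefficients for the neutrality test statistics
#'
#' Harmonic sums and the variance coefficients of Tajima's D (b1, b2, c1,
#' c2, e1, e2) and of Fu and Li's D* in its outgroup-free, corrected form
#' (cn, dn, uDstar, vDstar).
#'
#' @param n2 number of sequences (>= 3).
#' @return named list of coefficients.
#' @export
neutrality_coefficients <- function(n2) {
  n <- as.numeric(n2)
  if (n < 3) stop("need at least 3 sequences")
  i <- seq_len(n2 - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  an1 <- a1 + 1 / n                     # harmonic number of n
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDstar <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
               2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uDstar <- (n / (n - 1)) * (a1 - n / (n - 1)) - vDstar
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2, cn = cn, dn = dn, uDstar = uDstar, vDstar = vDstar)
}

#' Tajima's D
#'
#' Contrast between the pairwise-difference estimator of theta (k) and the
#' segregating-sites estimator (S/a1), standardised by its variance under
#' neutrality.
#'
#' @param k mean pairwise differences per sequence.
#' @param S number of segregating sites.
#' @param n2 number of sequences.
#' @return D, or `NA` when S = 0 (the statistic is undefined).
#' @export
tajimas_d <- function(k, S, n2) {
  if (S == 0) return(NA_real_)
  cf <- neutrality_coefficients(n2)
  (k - S / cf$a1) / sqrt(cf$e1 * S + cf$e2 * S * (S - 1))
}

#' Fu and Li's D* (no outgroup)
#'
#' Contrasts the total number of mutations eta with the number of singleton
#' mutations eta_s, in the outgroup-free form with corrected coefficients.
#'
#' @param eta total number of mutations.
#' @param eta_s number of singleton mutations.
#' @param n2 number of sequences.
#' @return D*, or `NA` when eta = 0.
#' @export
fu_li_dstar <- function(eta, eta_s, n2) {
  if (eta == 0) return(NA_real_)
  n <- as.numeric(n2)
  cf <- neutrality_coefficients(n2)
  (n / (n - 1) * eta - cf$a1 * eta_s) /
    sqrt(cf$uDstar * eta + cf$vDstar * eta^2)
}

# log of unsigned Stirling numbers of the first kind, row n: |s(n, k)|,
# k = 1..n, computed by the triangular recurrence in log space.
log_stirling_first_row <- function(n) {
  ls <- -Inf
  ls[1] <- 0                            # |s(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in seq_len(n - 1L)) {          # row m -> row m+1
    new <- numeric(m + 1L)
    prev <- c(-Inf, ls)                 # |s(m, k-1)| shifted
    grow <- log(m) + c(ls, -Inf)        # m * |s(m, k)|
    hi <- pmax(prev, grow)
    new <- hi + log1p(exp(pmin(prev, grow) - hi))
    new[is.nan(new)] <- -Inf
    new[m + 1L] <- 0                    # |s(m+1, m+1)| = 1
    new[1L] <- lgamma(m + 1L)           # |s(m+1, 1)| = m!
    ls <- new
  }
  ls
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability distribution of the number of distinct alleles K in a sample
#' of `n2` sequences under the infinite-alleles neutral model with scaled
#' mutation rate `theta`:
#' `P(K = k) = |s(n2, k)| theta^k / (theta (theta+1) ... (theta+n2-1))`
#' with unsigned Stirling numbers of the first kind, evaluated in log space.
#'
#' @param n2 sample size.
#' @param theta scaled mutation rate (> 0).
#' @return numeric vector of length `n2`; element k is P(K = k).
#' @export
ewens_allele_distribution <- function(n2, theta) {
  if (theta <= 0) stop("theta must be > 0")
  ls <- log_stirling_first_row(n2)
  k <- seq_len(n2)
  logp <- ls + k * log(theta) - sum(log(theta + (k - 1)))
  exp(logp - max(logp)) / sum(exp(logp - max(logp)))
}

#' Fu's FS statistic
#'
#' Uses the Ewens sampling formula with theta estimated by the mean
#' pairwise difference count k to compute `S' = P(K >= k_obs | theta = k)`,
#' the probability of observing at least as many haplotypes as seen, and
#' returns the logit `FS = ln(S' / (1 - S'))`. Large negative values
#' indicate an excess of haplotypes relative to the neutral expectation, as
#' after a sweep or expansion.
#'
#' @param k mean pairwise differences per sequence (theta estimate).
#' @param k_obs observed number of haplotypes.
#' @param n2 number of sequences.
#' @return FS, or `NA` when k = 0.
#' @export
fus_fs <- function(k, k_obs, n2) {
  if (k <= 0) return(NA_real_)
  p <- ewens_allele_distribution(n2, k)
  sprime <- sum(p[seq.int(k_obs, n2)])
  sprime <- min(max(sprime, .Machine$double.xmin), 1 - 1e-15)
  log(sprime / (1 - sprime))
}

#' All three neutrality tests for an alignment
#'
#' Computes Tajima's D, Fu and Li's D* and Fu's FS from an alignment, with
#' the sufficient statistics taken under complete deletion. Optionally
#' attaches empirical significance from a seeded coalescent null.
#'
#' @param aln a `locus_alignment`.
#' @param significance if `TRUE`, simulate the null and report p-values.
#' @param n_sims,seed passed to [neutrality_significance()].
#' @return one-row data.frame: D, Dstar, FS (and p_D, p_Dstar, p_FS,
#'   significance stars when requested).
#' @export
neutrality_tests <- function(aln, significance = FALSE, n_sims = 1000,
                             seed = 1L) {
  sites <- classify_sites(aln)
  n <- nrow(aln$seq)
  k <- mean_pairwise_differences(aln)
  hap <- haplotype_summary(aln)
  out <- data.frame(D = tajimas_d(k, sites$S, n),
                    Dstar = fu_li_dstar(sites$eta, sites$eta_s, n),
                    FS = fus_fs(k, hap$h, n))
  if (significance) {
    pD <- neutrality_significance(out$D, "D", n2 = n, S = sites$S,
                                  n_sims = n_sims, seed = seed)
    pDs <- neutrality_significance(out$Dstar, "Dstar", n2 = n, S = sites$S,
                                   n_sims = n_sims, seed = seed + 1L)
    pFS <- neutrality_significance(out$FS, "FS", n2 = n, theta = k,
                                   n_sims = n_sims, seed = seed + 2L)
    out$p_D <- pD; out$p_Dstar <- pDs; out$p_FS <- pFS
    out$sig_D <- p_stars(pD); out$sig_Dstar <- p_stars(pDs)
    out$sig_FS <- p_stars(pFS, fs = TRUE)
  }
  out
}

p_stars <- function(p, fs = FALSE) {
  if (is.na(p)) return("")
  # Fu's convention for FS: the 5% level corresponds to empirical P < 0.02
  if (fs) { if (p < 0.002) "**" else if (p < 0.02) "*" else "" }
  else { if (p <= 0.01) "**" else if (p <= 0.05) "*" else "" }
}

#' Empirical significance of a neutrality statistic
#'
#' Simulates the statistic's null distribution with seeded neutral
#' coalescent replicates: conditioned on the observed number of segregating
#' sites for D and D* (mutations placed on the genealogy in proportion to
#' branch length), and parameterised by the theta estimate for FS. The
#' p-value uses the (count + 1)/(n_sims + 1) estimator; two-tailed for D
#' and D*, lower-tailed for FS (Fu's convention).
#'
#' @param observed the observed statistic (`NA` gives `NA`).
#' @param stat one of "D", "Dstar", "FS".
#' @param n2 sample size.
#' @param S observed segregating sites (for D, D*).
#' @param theta theta estimate (for FS).
#' @param n_sims number of replicates (>= 1000 recommended).
#' @param seed integer seed.
#' @return empirical p-value.
#' @export
neutrality_significance <- function(observed, stat = c("D", "Dstar", "FS"),
                                    n2, S = NULL, theta = NULL,
                                    n_sims = 1000, seed = 1L) {
  stat <- match.arg(stat)
  if (is.na(observed)) return(NA_real_)
  set.seed(as.integer(seed))
  sims <- numeric(n_sims)
  for (r in seq_len(n_sims)) {
    gen <- sim_genealogy(n2)
    if (stat == "FS") {
      stopifnot(!is.null(theta))
      mut <- drop_mutations(gen, theta = theta)
      sims[r] <- fus_fs(mut$k, mut$h, n2)
    } else {
      stopifnot(!is.null(S))
      mut <- drop_mutations(gen, n_mut = S)
      sims[r] <- if (stat == "D") tajimas_d(mut$k, mut$S, n2)
                 else fu_li_dstar(mut$eta, mut$eta_s, n2)
    }
  }
  sims <- sims[!is.na(sims)]
  m <- length(sims)
  if (stat == "FS") return((sum(sims <= observed) + 1) / (m + 1))
  lo <- sum(sims <= observed)
  hi <- sum(sims >= observed)
  min(1, 2 * (min(lo, hi) + 1) / (m + 1))
}
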