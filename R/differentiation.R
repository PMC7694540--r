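# Pool two alignments over their shared valid columns. Returns the pooled
# matrix integer-coded (A,C,G,T -> 1:4) and restricted to segregating
# valid sites (monomorphic columns contribute no differences), the group
# index, and the total number of valid sites for per-site scaling.
pool_alignments <- function(alnA, alnB) {
  if (ncol(alnA$seq) != ncol(alnB$seq))
    stop("alignment error: loci of unequal length")
  pooled <- locus_alignment(rbind(alnA$seq, alnB$seq),
    sample_id = make.unique(c(alnA$samples$sample_id,
                              alnB$samples$sample_id)),
    population = c(alnA$samples$population, alnB$samples$population),
    region = c(alnA$samples$region, alnB$samples$region))
  sites <- classify_sites(pooled)
  seg <- sites$valid & sites$status == "segregating_SNP"
  m <- pooled$seq[, seg, drop = FALSE]
  imat <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))
  list(mat = imat,
       grp = rep(c(1L, 2L), c(nrow(alnA$seq), nrow(alnB$seq))),
       n_valid = sum(sites$valid))
}

# Mean pairwise difference count between rows of the coded matrix indexed
# by ia and ib (within-group when ia and ib are identical).
mean_diffs_between <- function(m, ia, ib) {
  within <- identical(ia, ib)
  na <- length(ia); nb <- length(ib)
  tot <- 0
  for (j in seq_len(ncol(m))) {
    ca <- tabulate(m[ia, j], 4L)
    if (within) tot <- tot + (na * (na - 1) - sum(ca * (ca - 1))) / 2
    else tot <- tot + na * nb - sum(ca * tabulate(m[ib, j], 4L))
  }
  if (within) tot / (na * (na - 1) / 2) else tot / (na * nb)
}

fst_core <- function(mat, grp) {
  ia <- which(grp == 1L); ib <- which(grp == 2L)
  Hw <- (mean_diffs_between(mat, ia, ia) + mean_diffs_between(mat, ib, ib)) / 2
  Hb <- mean_diffs_between(mat, ia, ib)
  list(FST = if (Hb > 0) 1 - Hw / Hb else NA_real_, Hw = Hw, Hb = Hb)
}

#' Hudson's FST from two population alignments
#'
#' The nucleotide-sequence fixation index `FST = 1 - Hw/Hb`, where `Hw` is
#' the unweighted mean of the two within-population mean pairwise
#' difference counts and `Hb` the mean pairwise difference count between
#' populations, all over shared valid sites (complete deletion on the
#' pooled alignment).
#'
#' @param alnA,alnB `locus_alignment`s of the two populations (>= 2
#'   sequences each).
#' @return list with `FST` (NA, flagged, when `Hb = 0`), `Hw`, `Hb`
#'   (per valid site).
#' @export
hudson_fst <- function(alnA, alnB) {
  p <- pool_alignments(alnA, alnB)
  r <- fst_core(p$mat, p$grp)
  r$Hw <- r$Hw / p$n_valid
  r$Hb <- r$Hb / p$n_valid
  r
}

#' Effective number of migrants from FST
#'
#' Island-model relation `Nm = (1 - FST) / (4 FST)`.
#'
#' @param FST fixation index in (0, 1].
#' @return Nm; `Inf` when `FST <= 0` (gene flow indistinguishable from
#'   panmixia).
#' @export
nm_from_fst <- function(FST) {
  if (is.na(FST)) return(NA_real_)
  if (FST <= 0) return(Inf)
  (1 - FST) / (4 * FST)
}

# Haplotype frequency table per group over the (already valid) site matrix.
hap_freqs <- function(mat, grp) {
  key <- apply(mat, 1L, paste, collapse = "")
  haps <- unique(key)
  H <- length(haps)
  gs <- sort(unique(grp))
  cnt <- matrix(0L, nrow = length(gs), ncol = H)
  for (g in seq_along(gs))
    cnt[g, ] <- tabulate(match(key[grp == gs[g]], haps), nbins = H)
  rep_rows <- mat[match(haps, key), , drop = FALSE]
  hd <- matrix(0, H, H)
  if (H > 1L) for (a in 2:H) for (b in seq_len(a - 1L)) {
    d <- sum(rep_rows[a, ] != rep_rows[b, ])
    hd[a, b] <- hd[b, a] <- d
  }
  list(counts = cnt, dist = hd)         # counts: groups x haplotypes
}

suite_core <- function(mat, grp, unbiased = FALSE) {
  hf <- hap_freqs(mat, grp)
  cnt <- hf$counts
  nj <- rowSums(cnt)
  n <- sum(nj)
  pj <- cnt / nj                        # per-deme haplotype frequencies
  pbar <- colSums(cnt) / n
  # GST: Nei's haplotype-heterozygosity form, unweighted deme means
  Hj <- 1 - rowSums(pj^2)
  if (unbiased) Hj <- nj / (nj - 1) * Hj
  HS_g <- mean(Hj)
  HT_g <- 1 - sum(colMeans(pj)^2)
  if (unbiased) HT_g <- n / (n - 1) * HT_g
  GST <- if (HT_g > 0) 1 - HS_g / HT_g else NA_real_
  # HST: sample-size-weighted unbiased heterozygosities
  Hju <- nj / (nj - 1) * (1 - rowSums(pj^2))
  HS_h <- sum(nj / n * Hju)
  HT_h <- n / (n - 1) * (1 - sum(pbar^2))
  HST <- if (HT_h > 0) 1 - HS_h / HT_h else NA_real_
  # KST: within vs pooled mean pairwise sequence differences
  Kj <- vapply(seq_along(nj), function(g) {
    ig <- which(grp == sort(unique(grp))[g])
    if (length(ig) < 2L) 0 else mean_diffs_between(mat, ig, ig)
  }, numeric(1))
  KS <- sum(nj / n * Kj)
  KT <- mean_diffs_between(mat, seq_len(nrow(mat)), seq_len(nrow(mat)))
  KST <- if (KT > 0) 1 - KS / KT else NA_real_
  # NST: GST generalised by nucleotide distance between haplotypes
  vj <- vapply(seq_along(nj), function(g)
    drop(pj[g, ] %*% hf$dist %*% pj[g, ]), numeric(1))
  vS <- mean(vj)
  vT <- drop(colMeans(pj) %*% hf$dist %*% colMeans(pj))
  NST <- if (vT > 0) 1 - vS / vT else NA_real_
  list(GST = GST, HST = HST, KST = KST, NST = NST)
}

#' GST, HST, KST and NST between two populations
#'
#' Haplotype-level differentiation statistics: `GST` from haplotype
#' heterozygosities (unweighted deme means, Nei's form; an unbiased variant
#' is switchable), `HST` from sample-size-weighted unbiased haplotype
#' heterozygosities, `KST = 1 - KS/KT` from within- versus pooled mean
#' pairwise sequence differences, and `NST`, the GST analogue weighting
#' haplotype pairs by their nucleotide distance (so it reduces to GST when
#' all distinct haplotypes are equidistant).
#'
#' @inheritParams hudson_fst
#' @param unbiased apply small-sample corrections to GST's
#'   heterozygosities.
#' @return list with elements `GST`, `HST`, `KST`, `NST` (NA, flagged,
#'   when the pooled sample is monomorphic).
#' @export
differentiation_suite <- function(alnA, alnB, unbiased = FALSE) {
  p <- pool_alignments(alnA, alnB)
  suite_core(p$mat, p$grp, unbiased = unbiased)
}

#' Permutation test for a differentiation statistic
#'
#' Shuffles population labels (preserving sample sizes), recomputes the
#' statistic for each permutation and returns the one-sided p-value
#' `(#\{perm >= observed\} + 1) / (n_perms + 1)`; ties count as
#' exceedances.
#'
#' @param stat_fn one of `"KST"`, `"HST"`, `"GST"`, `"NST"`, `"FST"`, or a
#'   function of `(mat, grp)` returning a scalar.
#' @inheritParams hudson_fst
#' @param n_perms number of permutations (default 1000; the classical
#'   protocol uses 10000).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `n_perms`, `seed`.
#' @export
permute_labels_test <- function(stat_fn, alnA, alnB, n_perms = 1000,
                                seed = 1L) {
  if (n_perms < 100) stop("n_perms must be >= 100")
  p <- pool_alignments(alnA, alnB)
  f <- if (is.function(stat_fn)) stat_fn else switch(
    stat_fn,
    FST = function(m, g) fst_core(m, g)$FST,
    GST = function(m, g) suite_core(m, g)$GST,
    HST = function(m, g) suite_core(m, g)$HST,
    KST = function(m, g) suite_core(m, g)$KST,
    NST = function(m, g) suite_core(m, g)$NST,
    stop("unknown statistic: ", stat_fn))
  obs <- f(p$mat, p$grp)
  if (is.na(obs)) return(list(observed = NA_real_, p = NA_real_,
                              n_perms = n_perms, seed = seed))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (r in seq_len(n_perms)) {
    s <- f(p$mat, sample(p$grp))
    if (!is.na(s) && s >= obs) exceed <- exceed + 1L
  }
  list(observed = obs, p = (exceed + 1) / (n_perms + 1),
       n_perms = n_perms, seed = seed)
}

#' Phylogeographic-structure flag from NST versus GST
#'
#' An NST significantly greater than GST indicates that similar haplotypes
#' co-occur geographically, i.e. phylogeographic structure.
#'
#' @param NST,GST observed statistics.
#' @param p_from_permutation permutation p-value for the NST - GST
#'   difference (see [nst_gst_test()]).
#' @param alpha significance level (default 0.05).
#' @return `TRUE` iff `NST > GST` and the difference is significant.
#' @export
phylogeography_flag <- function(NST, GST, p_from_permutation, alpha = 0.05) {
  if (anyNA(c(NST, GST, p_from_permutation))) return(FALSE)
  NST > GST && p_from_permutation <= alpha
}

#' Permutation test for the NST - GST difference
#'
#' @inheritParams permute_labels_test
#' @return list with `NST`, `GST`, `p` (for the difference) and the
#'   phylogeography flag.
#' @export
nst_gst_test <- function(alnA, alnB, n_perms = 1000, seed = 1L) {
  res <- permute_labels_test(function(m, g) {
    s <- suite_core(m, g); s$NST - s$GST
  }, alnA, alnB, n_perms = n_perms, seed = seed)
  s <- differentiation_suite(alnA, alnB)
  list(NST = s$NST, GST = s$GST, p = res$p,
       flag = phylogeography_flag(s$NST, s$GST, res$p))
}

#' Full pairwise differentiation result for two populations
#'
#' @inheritParams permute_labels_test
#' @param n_perms permutations for the HST and KST significance tests.
#' @return one-row data.frame with FST, GST, HST, KST, NST, Nm, Hw, Hb,
#'   p_HST, p_KST.
#' @export
differentiation_result <- function(alnA, alnB, n_perms = 1000, seed = 1L) {
  fst <- hudson_fst(alnA, alnB)
  sut <- differentiation_suite(alnA, alnB)
  pH <- permute_labels_test("HST", alnA, alnB, n_perms = n_perms, seed = seed)
  pK <- permute_labels_test("KST", alnA, alnB, n_perms = n_perms,
                            seed = seed + 1L)
  data.frame(pop_a = alnA$samples$population[1L],
             pop_b = alnB$samples$population[1L],
             FST = fst$FST, GST = sut$GST, HST = sut$HST, KST = sut$KST,
             NST = sut$NST, Nm = nm_from_fst(fst$FST),
             Hw = fst$Hw, Hb = fst$Hb, p_HST = pH$p, p_KST = pK$p,
             n_perms = n_perms, seed = seed, stringsAsFactors = FALSE)
}

#' All pairwise differentiation results for a multi-population alignment
#'
#' @param aln a `locus_alignment` with >= 2 populations, or a list of
#'   per-population alignments.
#' @param by group sequences by `"population"` or `"region"` (pooling
#'   populations per regional group before comparison).
#' @inheritParams differentiation_result
#' @return data.frame, one row per unordered pair.
#' @export
pairwise_differentiation <- function(aln, by = "population", n_perms = 1000,
                                     seed = 1L) {
  parts <- if (inherits(aln, "locus_alignment"))
    split_by_population(aln, by = by) else aln
  nm <- names(parts)
  rows <- list()
  for (i in seq_along(parts)) for (j in seq_len(i - 1L)) {
    r <- differentiation_result(parts[[j]], parts[[i]], n_perms = n_perms,
                                seed = seed + i * 131L + j)
    r$pop_a <- nm[j]; r$pop_b <- nm[i]
    rows[[length(rows) + 1L]] <- r
  }
  do.call(rbind, rows)
}
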