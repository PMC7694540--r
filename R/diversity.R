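# Per-column pairwise-difference count over valid (complete-deletion) sites.
# Returns total differing pairs per segregating column; k and pi derive from it.
site_pair_diffs <- function(aln, sites = NULL) {
  if (is.null(sites)) sites <- classify_sites(aln)
  x <- aln$seq[, sites$valid, drop = FALSE]
  n <- nrow(x)
  npairs <- n * (n - 1) / 2
  seg <- which(sites$status[sites$valid] == "segregating_SNP")
  diffs <- vapply(seg, function(j) {
    tab <- table(x[, j])
    npairs - sum(tab * (tab - 1) / 2)
  }, numeric(1))
  list(total = sum(diffs), npairs = npairs, L_valid = ncol(x))
}

#' Mean number of pairwise differences (k)
#'
#' Average number of nucleotide differences between two sequences, taken
#' over all sequence pairs and counted over valid sites only
#' (complete deletion; see [classify_sites()]).
#'
#' @param aln a `locus_alignment` with at least 2 sequences.
#' @return k, a single number.
#' @export
mean_pairwise_differences <- function(aln) {
  if (nrow(aln$seq) < 2L) stop("need at least 2 sequences")
  d <- site_pair_diffs(aln)
  d$total / d$npairs
}

#' Nucleotide diversity (pi)
#'
#' Per-site nucleotide diversity: the mean pairwise difference count k
#' divided by the number of analysed sites.
#'
#' @inheritParams mean_pairwise_differences
#' @return pi, a single number.
#' @export
nucleotide_diversity <- function(aln) {
  d <- site_pair_diffs(aln)
  if (d$L_valid == 0L) stop("no valid sites after complete deletion")
  (d$total / d$npairs) / d$L_valid
}

#' Haplotype count and haplotype diversity
#'
#' Haplotypes are distinct full-length sequences over valid sites. Hd uses
#' the unbiased estimator `n/(n-1) * (1 - sum(p_i^2))`.
#'
#' @inheritParams mean_pairwise_differences
#' @return list with `h` (count), `Hd` (diversity) and `counts` (named
#'   haplotype frequencies, decreasing).
#' @export
haplotype_summary <- function(aln) {
  n <- nrow(aln$seq)
  if (n < 2L) stop("need at least 2 sequences")
  sites <- classify_sites(aln)
  key <- apply(aln$seq[, sites$valid, drop = FALSE], 1L, paste, collapse = "")
  counts <- sort(table(key), decreasing = TRUE)
  p <- as.numeric(counts) / n
  list(h = length(counts), Hd = n / (n - 1) * (1 - sum(p^2)),
       counts = counts)
}

#' Watterson's estimator of theta
#'
#' `theta_W = S / a1` per sequence, with `a1` the harmonic number of
#' `n - 1`.
#'
#' @param S number of segregating sites.
#' @param n2 number of sequences.
#' @return theta_W (per sequence, not per site).
#' @export
watterson_theta <- function(S, n2) {
  if (n2 < 2L) stop("need at least 2 sequences")
  if (S == 0) return(0)
  S / sum(1 / seq_len(n2 - 1))
}

#' Per-population diversity summary (one table row per population)
#'
#' Computes, for an alignment, the standard diversity row: number of
#' sequences (2n), segregating sites S, haplotype count h, haplotype
#' diversity Hd, mean pairwise differences k, nucleotide diversity pi,
#' Watterson's theta, and the number of analysed sites.
#'
#' @param aln a `locus_alignment`.
#' @return a one-row data.frame of class `diversity_summary`.
#' @export
diversity_summary <- function(aln) {
  sites <- classify_sites(aln)
  d <- site_pair_diffs(aln, sites)
  hap <- haplotype_summary(aln)
  n <- nrow(aln$seq)
  k <- d$total / d$npairs
  out <- data.frame(
    population = paste(sort(unique(aln$samples$population)), collapse = "+"),
    n2 = n, S = sites$S, h = hap$h, Hd = hap$Hd, k = k,
    pi = if (d$L_valid > 0) k / d$L_valid else NA_real_,
    theta_w = watterson_theta(sites$S, n), L_valid = d$L_valid,
    stringsAsFactors = FALSE)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Diversity table across populations
#'
#' Applies [diversity_summary()] and the neutrality tests to each
#' population of an alignment, in the column order of the classical
#' diversity table: 2n, S, h, Hd, pi, D, D*, FS.
#'
#' @param aln a `locus_alignment` with population labels.
#' @param by `"population"` or `"region"`.
#' @param overall also append a pooled "Overall" row.
#' @return data.frame, one row per population.
#' @export
diversity_table <- function(aln, by = "population", overall = TRUE) {
  parts <- split_by_population(aln, by = by)
  if (overall && length(parts) > 1L) parts <- c(parts, list(Overall = aln))
  rows <- lapply(names(parts), function(p) {
    ds <- diversity_summary(parts[[p]])
    nt <- neutrality_tests(parts[[p]])
    data.frame(population = p, n2 = ds$n2, S = ds$S, h = ds$h,
               Hd = round(ds$Hd, 2), pi = round(ds$pi, 5),
               D = round(nt$D, 2), Dstar = round(nt$Dstar, 2),
               FS = round(nt$FS, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sliding-window nucleotide diversity
#'
#' Computes pi in windows of `window_bp` columns advanced by `step_bp`,
#' in original alignment coordinates; excluded columns inside a window
#' reduce that window's denominator.
#'
#' @param aln a `locus_alignment`.
#' @param window_bp window width in alignment columns (default 400).
#' @param step_bp step between window starts (default 100).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `pi`, `n_valid_sites`.
#' @export
sliding_window_pi <- function(aln, window_bp = 400, step_bp = 100) {
  L <- ncol(aln$seq)
  if (window_bp > L) stop("window_bp (", window_bp, ") exceeds alignment length (", L, ")")
  sites <- classify_sites(aln)
  n <- nrow(aln$seq)
  npairs <- n * (n - 1) / 2
  # per-column differing-pair counts on valid columns, 0 elsewhere
  percol <- numeric(L)
  for (j in which(sites$valid & sites$status == "segregating_SNP")) {
    tab <- table(aln$seq[, j])
    percol[j] <- npairs - sum(tab * (tab - 1) / 2)
  }
  starts <- seq(1L, L - window_bp + 1L, by = step_bp)
  out <- lapply(starts, function(s) {
    idx <- s:(s + window_bp - 1L)
    nv <- sum(sites$valid[idx])
    data.frame(start = s, end = s + window_bp - 1L,
               pi = if (nv > 0) sum(percol[idx]) / npairs / nv else NA_real_,
               n_valid_sites = nv)
  })
  do.call(rbind, out)
}
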