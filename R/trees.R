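TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura 2-parameter distance between two sequences
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` and `Q` the
#' transition and transversion mismatch proportions over sites where both
#' sequences carry an unambiguous base.
#'
#' @param seqA,seqB character vectors (or single strings) of equal length.
#' @return the distance, with attributes `P` and `Q`.
#' @export
kimura2p_distance <- function(seqA, seqB) {
  if (length(seqA) == 1L) seqA <- strsplit(seqA, "")[[1]]
  if (length(seqB) == 1L) seqB <- strsplit(seqB, "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences of unequal length")
  a <- toupper(seqA); b <- toupper(seqB)
  ok <- a %in% names(TRANSITIONS) & b %in% names(TRANSITIONS)
  if (!any(ok)) stop("no valid sites")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  P <- sum(a != b & TRANSITIONS[a] == b) / n
  Q <- sum(a != b & TRANSITIONS[a] != b) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("saturation error: K2 distance undefined (P=", P, ", Q=", Q, ")")
  d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  attr(d, "P") <- P; attr(d, "Q") <- Q
  d
}

#' Pairwise K2 distance matrix for an alignment
#'
#' @param aln a `locus_alignment` (or character matrix with rownames).
#' @param fallback_p on saturation, fall back to the raw mismatch
#'   proportion for that pair instead of erroring.
#' @return a `dist` object labelled by sample id.
#' @export
k2_distance_matrix <- function(aln, fallback_p = FALSE) {
  mat <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- tryCatch(as.numeric(kimura2p_distance(mat[i, ], mat[j, ])),
                    error = function(e) {
                      if (!fallback_p) stop(e)
                      ok <- mat[i, ] %in% names(TRANSITIONS) &
                        mat[j, ] %in% names(TRANSITIONS)
                      mean(mat[i, ok] != mat[j, ok])
                    })
    d[i, j] <- d[j, i] <- dij
  }
  stats::as.dist(d)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch, the
#' usual display convention.
#'
#' @param D a `dist` or symmetric matrix with labels.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  m <- as.matrix(D)
  if (nrow(m) < 3L) stop("need at least 3 labels")
  if (max(abs(m - t(m))) > 1e-8) stop("non-symmetric distance matrix")
  tr <- ape::nj(stats::as.dist(m))
  clamp_negative_branches(tr)
}

# One sweep: move each negative branch length onto its sister branch and
# clamp at zero; any residual negatives (both sisters negative) clamp to 0.
clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters) && tr$edge.length[e] < 0) {
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] +
        tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the K2/NJ tree for an alignment and attaches, as internal node
#' labels, the percentage of `n_reps` column-resampled replicates whose NJ
#' tree contains each internal bipartition.
#'
#' @param aln a `locus_alignment` with >= 4 sequences.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param fallback_p see [k2_distance_matrix()] (default TRUE: bootstrap
#'   resampling can saturate individual pairs).
#' @return a `phylo` tree; `node.label` holds supports in 0..100.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1L,
                              fallback_p = TRUE) {
  mat <- if (inherits(aln, "locus_alignment")) aln$seq else aln
  if (nrow(mat) < 4L) stop("need at least 4 sequences")
  build <- function(m) neighbor_joining(k2_distance_matrix(m, fallback_p))
  tr <- build(mat)
  set.seed(as.integer(seed))
  counts <- ape::boot.phylo(tr, mat, build, B = n_reps, rooted = FALSE,
                            quiet = TRUE)
  # the root of an unrooted tree carries no bipartition: label stays NA
  tr$node.label <- round(100 * counts / n_reps)
  tr
}

#' Neighbour-joining tree of populations on Hudson FST distances
#'
#' Builds the pairwise FST matrix (negative estimates floored at zero) and
#' returns its NJ tree.
#'
#' @param pops named list of per-population `locus_alignment`s (>= 3).
#' @return a `phylo` tree with one tip per population.
#' @export
fst_nj_tree <- function(pops) {
  if (length(pops) < 3L) stop("need at least 3 populations")
  nm <- names(pops)
  if (is.null(nm)) nm <- vapply(pops, function(a)
    a$samples$population[1L], character(1))
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    f <- hudson_fst(pops[[i]], pops[[j]])$FST
    if (is.na(f))
      stop("undefined FST between ", nm[i], " and ", nm[j],
           " (no between-population diversity)")
    m[i, j] <- m[j, i] <- max(f, 0)
  }
  neighbor_joining(m)
}
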