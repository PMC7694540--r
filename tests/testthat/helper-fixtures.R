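# Fixtures are built in code: population configurations whose sufficient
# statistics (n, S, singleton layout) are fully determined, plus random
# alignments for oracle comparisons.

# n sequences of length L, identical except `singletons`: a list of
# (sequence index, number of private variant sites).
singleton_alignment <- function(n, L = 1139, singletons = list(c(1, 1)),
                                population = "pop1") {
  m <- matrix("A", n, L)
  site <- 1L
  for (sg in singletons) {
    for (s in seq_len(sg[2])) {
      m[sg[1], site] <- "G"
      site <- site + 1L
    }
  }
  locus_alignment(m, population = population)
}

# 20 sequences, one singleton: the unique configuration behind the
# Palmeira row (2n=20, S=1, h=2, Hd=0.10, pi=0.00009).
palmeira_alignment <- function() singleton_alignment(20)

# 18 sequences, one singleton (Ikwambi row).
ikwambi_alignment <- function() singleton_alignment(18)

# 32 sequences, three singleton sites: two carried by one sequence, one by
# another (Magania row: S=3, h=3, Hd=0.12, k=93/496).
magania_alignment <- function()
  singleton_alignment(32, singletons = list(c(1, 2), c(2, 1)))

# Random alignment with adjustable polymorphism for brute-force oracles.
random_alignment <- function(n, L, seed, p_var = 0.2, population = NULL) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), n, L)
  nvar <- max(1L, round(p_var * L))
  for (j in sample.int(L, nvar)) {
    carriers <- sample.int(n, sample.int(n - 1L, 1L))
    m[carriers, j] <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1L)
  }
  if (is.null(population)) population <- "pop1"
  locus_alignment(m, population = population)
}

# ---- independent oracles -------------------------------------------------

# Brute-force S: per-column count of >= 2 distinct ACGT states (complete
# deletion: columns containing - or non-ACGT are skipped).
oracle_S <- function(mat) {
  sum(apply(mat, 2L, function(col) {
    if (any(!col %in% c("A", "C", "G", "T"))) return(FALSE)
    length(unique(col)) >= 2L
  }))
}

# Brute-force k and pi by explicit pairwise enumeration.
oracle_k_pi <- function(mat) {
  valid <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- mat[, valid, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  k <- tot / (n * (n - 1) / 2)
  list(k = k, pi = k / ncol(m))
}

# Brute-force Hudson FST = 1 - Hw/Hb with explicit pair loops.
oracle_fst <- function(matA, matB) {
  mat <- rbind(matA, matB)
  valid <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  A <- matA[, valid, drop = FALSE]; B <- matB[, valid, drop = FALSE]
  pairdiff <- function(x, y) sum(x != y)
  within <- function(m) {
    n <- nrow(m); tot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + pairdiff(m[i, ], m[j, ])
    tot / (n * (n - 1) / 2)
  }
  between <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    between <- between + pairdiff(A[i, ], B[j, ])
  between <- between / (nrow(A) * nrow(B))
  Hw <- (within(A) + within(B)) / 2
  1 - Hw / between
}

# Brute-force KST = 1 - KS/KT with size-weighted within means.
oracle_kst <- function(matA, matB) {
  mat <- rbind(matA, matB)
  valid <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  A <- matA[, valid, drop = FALSE]; B <- matB[, valid, drop = FALSE]
  within <- function(m) {
    n <- nrow(m); tot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + sum(m[i, ] != m[j, ])
    tot / (n * (n - 1) / 2)
  }
  nA <- nrow(A); nB <- nrow(B); n <- nA + nB
  KS <- nA / n * within(A) + nB / n * within(B)
  KT <- within(rbind(A, B))
  1 - KS / KT
}

# All set partitions of 1..n (for the Ewens enumeration oracle).
all_set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# P(K = k) under the Ewens sampling formula by exhaustive enumeration of
# labelled partitions: P(partition) = theta^k prod (|b|-1)! / theta^{(n)}.
oracle_ewens <- function(n, theta) {
  parts <- all_set_partitions(n)
  rising <- prod(theta + 0:(n - 1))
  pk <- numeric(n)
  for (p in parts) {
    k <- length(p)
    w <- theta^k * prod(vapply(p, function(b) factorial(length(b) - 1),
                               numeric(1))) / rising
    pk[k] <- pk[k] + w
  }
  pk
}
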