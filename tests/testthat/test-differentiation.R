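two_pop_fixture <- function(seed = 1, n = 6, L = 40, divergence = 5) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mk <- function(base, label) {
    m <- matrix(rep(base, each = n), n, L)
    for (j in sample.int(L, 4)) {
      ii <- sample.int(n, sample.int(n - 1, 1))
      m[ii, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
    }
    locus_alignment(m, population = label)
  }
  der <- anc
  flip <- sample.int(L, divergence)
  for (j in flip) der[j] <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
  list(A = mk(anc, "A"), B = mk(der, "B"))
}

test_that("Hudson FST matches the brute-force Hw/Hb oracle", {
  for (seed in 1:4) {
    fx <- two_pop_fixture(seed)
    got <- hudson_fst(fx$A, fx$B)
    expect_equal(got$FST, oracle_fst(fx$A$seq, fx$B$seq), tolerance = 1e-12)
  }
  # two copies of one population: FST ~ 0
  aln <- random_alignment(8, 50, seed = 5)
  half1 <- locus_alignment(aln$seq[1:4, ], population = "A")
  half2 <- locus_alignment(aln$seq[5:8, ], population = "B")
  f <- hudson_fst(half1, half2)
  expect_lt(abs(f$FST), 0.35)
  # fixed different haplotypes: FST = 1
  a <- locus_alignment(matrix("A", 4, 30), population = "A")
  b <- locus_alignment(matrix(rep(c(rep("A", 25), rep("T", 5)), each = 4),
                              4, 30), population = "B")
  expect_equal(hudson_fst(a, b)$FST, 1)
  # identical monomorphic populations: undefined, flagged
  expect_true(is.na(hudson_fst(a, a)$FST))
})

test_that("Nm follows the island-model relation", {
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(round(nm_from_fst(0.0225), 2), 10.86)
  expect_equal(nm_from_fst(1), 0)
  expect_identical(nm_from_fst(0), Inf)
})

test_that("KST matches brute-force KS/KT and the suite is symmetric", {
  fx <- two_pop_fixture(7, n = 4)
  s <- differentiation_suite(fx$A, fx$B)
  expect_equal(s$KST, oracle_kst(fx$A$seq, fx$B$seq), tolerance = 1e-12)
  # symmetry under population label swap
  s2 <- differentiation_suite(fx$B, fx$A)
  for (nm in names(s)) expect_equal(s[[nm]], s2[[nm]])
  # invariance to sequence order
  perm <- locus_alignment(fx$A$seq[sample(nrow(fx$A$seq)), ],
                          population = "A")
  s3 <- differentiation_suite(perm, fx$B)
  for (nm in names(s)) expect_equal(s[[nm]], s3[[nm]])
})

test_that("NST exceeds GST when within-population haplotypes are similar", {
  # each population carries two 1-step haplotypes; populations are 6 steps
  # apart, so distance-awareness (NST) sees more structure than identity
  # (GST)
  base <- rep("A", 30)
  h2 <- base; h2[1] <- "G"
  far <- base; far[10:15] <- "T"
  far2 <- far; far2[2] <- "C"
  a <- locus_alignment(do.call(rbind, list(base, base, h2, h2)),
                       population = "A")
  b <- locus_alignment(do.call(rbind, list(far, far, far2, far2)),
                       population = "B")
  s <- differentiation_suite(a, b)
  expect_gt(s$NST, s$GST)
  expect_true(all(unlist(s) <= 1))
  # monomorphic pooled sample: all undefined
  mono <- locus_alignment(matrix("A", 4, 20), population = "A")
  mono2 <- locus_alignment(matrix("A", 4, 20), population = "B")
  expect_true(all(is.na(unlist(differentiation_suite(mono, mono2)))))
})

test_that("permutation p-values match exhaustive 3+3 enumeration", {
  fx <- two_pop_fixture(11, n = 3, L = 30, divergence = 4)
  res <- permute_labels_test("KST", fx$A, fx$B, n_perms = 2000, seed = 2)
  # exhaustive: all 20 assignments of 3+3 labels
  pooled <- rbind(fx$A$seq, fx$B$seq)
  rownames(pooled) <- NULL
  combs <- utils::combn(6, 3)
  stats <- apply(combs, 2L, function(ia) {
    a <- locus_alignment(pooled[ia, , drop = FALSE], population = "A")
    b <- locus_alignment(pooled[-ia, , drop = FALSE], population = "B")
    differentiation_suite(a, b)$KST
  })
  p_exact <- mean(stats >= res$observed)
  expect_lt(abs(res$p - p_exact), 0.06)
  # determinism
  res2 <- permute_labels_test("KST", fx$A, fx$B, n_perms = 2000, seed = 2)
  expect_identical(res$p, res2$p)
})

test_that("identical populations give a null permutation test", {
  aln <- random_alignment(10, 40, seed = 13)
  a <- locus_alignment(aln$seq[1:5, ], population = "A")
  b <- locus_alignment(aln$seq[6:10, ], population = "B")
  res <- permute_labels_test("KST", a, b, n_perms = 300, seed = 1)
  expect_gt(res$p, 0.05)
})

test_that("phylogeography flag requires NST > GST and significance", {
  expect_false(phylogeography_flag(0.5, 0.5, 0.01))
  expect_true(phylogeography_flag(0.6, 0.4, 0.01))
  expect_false(phylogeography_flag(0.6, 0.4, 0.2))
})

test_that("differentiation_result assembles the full pairwise row", {
  fx <- two_pop_fixture(17)
  row <- differentiation_result(fx$A, fx$B, n_perms = 200, seed = 4)
  expect_equal(row$FST, hudson_fst(fx$A, fx$B)$FST)
  expect_equal(row$KST, differentiation_suite(fx$A, fx$B)$KST)
  expect_true(row$p_KST > 0 && row$p_KST <= 1)
  expect_equal(row$Nm, nm_from_fst(row$FST))
})
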