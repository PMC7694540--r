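test_that("haplotype collapse tallies frequencies and treats gaps as a state", {
  hs <- collapse_haplotypes(palmeira_alignment())
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$frequency, c(19L, 1L))
  expect_equal(sum(hs$frequency), 20L)
  # gap is a fifth state: AA- and AAA are distinct haplotypes
  aln <- locus_alignment(c("AA-", "AAA", "AAA"))
  expect_equal(nrow(collapse_haplotypes(aln)), 2L)
  # all-distinct input
  m <- matrix("A", 4, 10); for (i in 1:4) m[i, i] <- "T"
  expect_equal(collapse_haplotypes(locus_alignment(m))$frequency,
               rep(1L, 4))
})

test_that("parsimony probability is monotone and permissive at one step", {
  for (L in c(100, 500, 633, 1139, 2000))
    expect_gte(haplosweep:::parsimony_probability(1, L), 0.95)
  for (L in c(200, 633)) {
    p <- vapply(1:20, haplosweep:::parsimony_probability, numeric(1), m = L)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("connection limit matches an independent direct evaluation", {
  # independent evaluation: log-space grid over j of the same per-site
  # Poisson multiple-hit probability, written from the definition
  direct_limit <- function(m, alpha = 0.95) {
    best <- 0L
    for (j in seq_len(m)) {
      q <- j / m
      if (q >= 0.75) break
      mu <- -0.75 * log(1 - 4 * q / 3)
      lp <- j * (log(mu) - mu - log(q)) + (m - j) * (-mu - log(1 - q))
      if (exp(lp) >= alpha) best <- j else break
    }
    best
  }
  for (L in c(200, 633, 754, 1139))
    expect_equal(parsimony_connection_limit(L), direct_limit(L))
  expect_gte(parsimony_connection_limit(633), 1L)
})

test_that("network construction links haplotypes through intermediates", {
  aln <- locus_alignment(c("AAA", "AAT", "ATT", "AAA", "AAT"))
  net <- build_statistical_parsimony_network(collapse_haplotypes(aln),
                                             j95 = 3)
  # chain AAA - AAT - ATT with single-step edges, no intermediates needed
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$nodes$observed))
  expect_equal(length(unique(net$components)), 1L)
  # frequencies sum to the sequence count
  expect_equal(sum(net$nodes$frequency), 5L)
})

test_that("distant haplotypes beyond the limit stay in separate components", {
  near <- c("AAAAAAAAAA", "AAAAAAAAAT")
  far <- paste(rep("G", 10), collapse = "")
  aln <- locus_alignment(c(near, far))
  net <- build_statistical_parsimony_network(collapse_haplotypes(aln),
                                             j95 = 3)
  expect_equal(length(unique(net$components)), 2L)
})

test_that("star data yields a star topology and multi-step links insert nodes", {
  centre <- rep("A", 20)
  leaves <- lapply(1:4, function(i) { x <- centre; x[i] <- "T"; x })
  seqs <- c(rep(paste(centre, collapse = ""), 5),
            vapply(leaves, paste, character(1), collapse = ""))
  net <- build_statistical_parsimony_network(
    collapse_haplotypes(locus_alignment(seqs)))
  expect_equal(nrow(net$edges), 4L)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(max(deg), 4L)            # the centre haplotype
  # two haplotypes three steps apart: two inferred intermediates
  x <- rep("A", 30); y <- x; y[1:3] <- "T"
  net2 <- build_statistical_parsimony_network(
    collapse_haplotypes(
      locus_alignment(c(paste(x, collapse = ""), paste(y, collapse = "")))),
    j95 = 5)
  expect_equal(sum(!net2$nodes$observed), 2L)
  expect_equal(nrow(net2$edges), 3L)
})

test_that("perfect-phylogeny data gives a tree and order invariance holds", {
  # unique-site haplotypes: infinite-sites tree structure
  base <- rep("A", 40)
  hs <- list(base)
  for (i in 1:5) { x <- hs[[length(hs)]]; x[i] <- "T"; hs[[i + 1]] <- x }
  seqs <- vapply(hs, paste, character(1), collapse = "")
  seqs <- rep(seqs, times = c(6, 1, 3, 1, 2, 1))
  net <- build_statistical_parsimony_network(
    collapse_haplotypes(locus_alignment(seqs)))
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
  # input order invariance under the documented tie-break
  set.seed(2)
  net2 <- build_statistical_parsimony_network(
    collapse_haplotypes(locus_alignment(sample(seqs))))
  expect_equal(sort(paste(net$edges$from, net$edges$to)),
               sort(paste(net2$edges$from, net2$edges$to)))
})

test_that("network export writes node, edge and DOT files", {
  aln <- locus_alignment(c("AAA", "AAT", "ATT", "AAA"))
  net <- build_statistical_parsimony_network(collapse_haplotypes(aln),
                                             j95 = 3)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  expect_true(file.exists(paste0(prefix, "_nodes.tsv")))
  expect_true(file.exists(paste0(prefix, "_edges.tsv")))
  dot <- readLines(paste0(prefix, ".dot"))
  expect_true(any(grepl("--", dot, fixed = TRUE)))
})
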