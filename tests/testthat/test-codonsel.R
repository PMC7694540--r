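sense_codons <- function() {
  code <- haplosweep:::GENETIC_CODE_STD
  names(code)[code != "*"]
}

test_that("codon site fractions follow the Nei-Gojobori enumeration", {
  # TTT: one synonymous neighbour (TTC), no stop neighbours
  f <- haplosweep:::codon_site_fractions("TTT")
  expect_equal(unname(f["syn"]), 1 / 3)
  expect_equal(unname(f["nonsyn"]), 8 / 3)
  # TGG: no synonymous neighbour; two stop neighbours are excluded
  g <- haplosweep:::codon_site_fractions("TGG")
  expect_equal(unname(g["syn"]), 0)
  expect_equal(unname(g["nonsyn"]), 7 / 3)
  # switchable convention: stops counted as non-synonymous
  g2 <- haplosweep:::codon_site_fractions("TGG", "nonsynonymous")
  expect_equal(unname(g2["nonsyn"]), 3)
  # independent enumeration oracle over all sense codons
  code <- haplosweep:::GENETIC_CODE_STD
  for (cod in sample(sense_codons(), 12)) {
    nb <- haplosweep:::codon_neighbours(cod)
    keep <- code[nb] != "*"
    syn <- sum(code[nb][keep] == code[cod]) / 3
    f <- haplosweep:::codon_site_fractions(cod)
    expect_equal(unname(f["syn"]), syn)
    expect_equal(sum(f), sum(keep) / 3)
  }
})

test_that("site fractions average over sequences and respect the 3L bound", {
  seqs <- c("TTTATGGCA", "TTTATGGCA", "TTTATGGCA")
  aln <- locus_alignment(seqs, population = "p")
  one <- haplosweep:::codon_site_fractions("TTT") +
    haplosweep:::codon_site_fractions("ATG") +
    haplosweep:::codon_site_fractions("GCA")
  sf <- ng_site_fractions(aln)
  expect_equal(sf$syn_sites, unname(one["syn"]))
  expect_equal(sf$syn_sites + sf$nonsyn_sites <= 9, TRUE)
  # no stop-adjacent codons: fractions sum to exactly 3 x codons
  aln2 <- locus_alignment(c("TTTCTT", "TTTCTT"), population = "p")
  sf2 <- ng_site_fractions(aln2)
  expect_equal(sf2$syn_sites + sf2$nonsyn_sites, 6)
})

test_that("observed substitutions are classified by amino-acid effect", {
  # third-position synonymous change TTT <-> TTC
  a <- locus_alignment(c("TTTATG", "TTCATG"), population = "p")
  cs <- classify_substitutions(a)
  expect_equal(cs$syn_subs, 1)
  expect_equal(cs$nonsyn_subs, 0)
  # first-position Phe -> Ile
  b <- locus_alignment(c("TTTATG", "ATTATG"), population = "p")
  cs <- classify_substitutions(b)
  expect_equal(cs$syn_subs, 0)
  expect_equal(cs$nonsyn_subs, 1)
})

test_that("multi-hit codons average over minimal mutational pathways", {
  # independent orderings oracle for two-position codon pairs
  code <- haplosweep:::GENETIC_CODE_STD
  oracle_pair <- function(c1, c2) {
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    pos <- which(a != b)
    perms <- if (length(pos) == 2) list(pos, rev(pos)) else list(pos)
    res <- lapply(perms, function(ord) {
      cur <- a; syn <- 0; nonsyn <- 0; stop <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        s1 <- code[paste(cur, collapse = "")]
        s2 <- code[paste(nxt, collapse = "")]
        if (s1 == "*" || s2 == "*") stop <- TRUE
        if (s1 == s2) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      list(syn = syn, nonsyn = nonsyn, stop = stop)
    })
    ok <- !vapply(res, `[[`, logical(1), "stop")
    if (any(ok)) res <- res[ok]
    c(mean(vapply(res, `[[`, numeric(1), "syn")),
      mean(vapply(res, `[[`, numeric(1), "nonsyn")))
  }
  pairs <- list(c("TTA", "CTG"), c("TTT", "GAT"), c("AAA", "AGG"),
                c("TCA", "ACT"))
  for (pr in pairs) {
    aln <- locus_alignment(c(pr[1], pr[2]), population = "p")
    cs <- classify_substitutions(aln)
    exp <- oracle_pair(pr[1], pr[2])
    expect_equal(c(cs$syn_subs, cs$nonsyn_subs), exp)
  }
})

test_that("pN/pS reproduces the printed-table arithmetic and edge rules", {
  drc <- codon_count_table(syn_sites = 157.09, nonsyn_sites = 484.91,
                           syn_subs = 1, nonsyn_subs = 5)
  expect_equal(round(pnps(drc), 2), 1.62)
  moz <- codon_count_table(syn_sites = 153.47, nonsyn_sites = 488.53,
                           syn_subs = 1, nonsyn_subs = 3)
  expect_equal(round(pnps(moz), 2), 0.94)
  # no synonymous substitutions: ratio undefined
  mal <- codon_count_table(syn_sites = 153.43, nonsyn_sites = 488.57,
                           syn_subs = 0, nonsyn_subs = 2)
  expect_true(is.na(pnps(mal)))
  # scale invariance: doubling both counts leaves the ratio unchanged
  dbl <- codon_count_table(syn_sites = 157.09, nonsyn_sites = 484.91,
                           syn_subs = 2, nonsyn_subs = 10)
  expect_equal(pnps(dbl), pnps(drc))
})
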