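scan_fixture <- function(seed = 11, n_per_pop = 10) {
  rp1_region_dataset(simulation_config(seed = seed, n_per_pop = n_per_pop))
}

test_that("per-locus profile equals independent single-locus calls", {
  ds <- scan_fixture()
  tab <- per_locus_profile(ds)
  for (r in sample(nrow(tab), 8)) {
    sub <- subset_alignment(ds[[tab$locus[r]]],
                            population = tab$population[r])
    expect_equal(tab$pi[r], nucleotide_diversity(sub))
    expect_equal(tab$Hd[r], haplotype_summary(sub)$Hd)
    expect_equal(tab$D[r], neutrality_tests(sub)$D)
  }
})

test_that("a singleton population reproduces its diversity-table row", {
  pal <- palmeira_alignment()
  pal$samples$population <- "Palmeira"
  pal$samples$region <- "southern"
  other <- coalescent_locus(10, 3, 1139, seed = 4,
                            population = "Elsewhere",
                            region = "eastern_central")
  combined <- locus_alignment(rbind(pal$seq, other$seq),
                              sample_id = c(pal$samples$sample_id,
                                            paste0("e", 1:10)),
                              population = c(pal$samples$population,
                                             other$samples$population),
                              region = c(pal$samples$region,
                                         other$samples$region),
                              locus_name = "CYP6P9a", offset_kb = 0)
  tab <- per_locus_profile(list(CYP6P9a = combined))
  row <- tab[tab$population == "Palmeira", ]
  expect_equal(round(row$Hd, 2), 0.10)
  expect_equal(round(row$pi, 5), 0.00009)
  expect_equal(round(row$D, 2), -1.16)
})

test_that("monomorphic populations yield n.a-style cells", {
  mono <- locus_alignment(matrix("A", 8, 200), population = "Uganda",
                          region = "eastern_central", locus_name = "25BAC")
  poly <- coalescent_locus(8, 3, 200, seed = 9, population = "Kinshasa",
                           region = "eastern_central", locus_name = "25BAC")
  combined <- locus_alignment(rbind(mono$seq, poly$seq),
                              sample_id = sprintf("s%02d", 1:16),
                              population = rep(c("Uganda", "Kinshasa"),
                                               each = 8),
                              region = "eastern_central",
                              locus_name = "25BAC", offset_kb = -9)
  tab <- per_locus_profile(list(`25BAC` = combined),
                           comparison = "eastern_central",
                           reference = "eastern_central")
  row <- tab[tab$population == "Uganda", ]
  expect_equal(row$pi, 0)
  expect_true(is.na(row$D))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_table(tab, path)
  expect_true(any(grepl("n.a", readLines(path), fixed = TRUE)))
})

test_that("group pi ratio follows the unweighted-mean definition", {
  tab <- data.frame(
    locus = "0BAC", offset_kb = -34,
    population = sprintf("p%d", 1:7),
    group = c(rep("eastern_central", 3), rep("southern", 4)),
    pi = c(1.76e-3, 0.74e-3, 6.49e-3, 0.06e-3, 0.72e-3, 0.36e-3, 1.08e-3))
  r <- group_pi_ratio(tab)
  expect_equal(round(r$pi_ratio, 2), 5.40)
  # equal means give 1
  tab$pi <- 1e-3
  expect_equal(group_pi_ratio(tab)$pi_ratio, 1)
  # all-zero reference is undefined
  tab$pi[tab$group == "southern"] <- 0
  expect_true(is.na(group_pi_ratio(tab)$pi_ratio))
})

test_that("sweep_report flags the sweep and spares neutral groups", {
  ds <- scan_fixture(seed = 31, n_per_pop = 12)
  tab <- per_locus_profile(ds)
  rep <- sweep_report(tab, groups = "southern")
  expect_true(rep$swept[rep$locus == "CYP6P9a"])
  ext <- attr(rep, "extent")
  expect_gte(ext$n_swept[ext$group == "southern"], 1)
  # an all-monomorphic group is always flagged
  mono_tab <- data.frame(
    locus = "X", offset_kb = 0, population = sprintf("p%d", 1:4),
    group = rep(c("southern", "eastern_central"), each = 2),
    n2 = 10, S = 0, h = 1,
    Hd = c(0, 0, 0.5, 0.6), pi = c(0, 0, 1e-3, 2e-3),
    D = c(NA, NA, -0.2, 0.1), note = "")
  r <- sweep_report(mono_tab, groups = "southern")
  expect_true(r$swept)
})

test_that("region configs round-trip through YAML and drive the scan", {
  ds <- scan_fixture(seed = 41, n_per_pop = 8)
  dir <- withr::local_tempdir()
  cfgfile <- write_region_dataset(ds, dir)
  cfg <- read_region_config(cfgfile)
  expect_s3_class(cfg, "region_config")
  expect_equal(sort(cfg$loci$offset_kb), c(-34, -9, 0, 29, 61, 86))
  expect_equal(cfg$focal, "CYP6P9a")
  tab_file <- per_locus_profile(cfg)
  tab_mem <- per_locus_profile(ds)
  expect_equal(tab_file$pi, tab_mem$pi)
  expect_equal(tab_file$D, tab_mem$D)
})
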