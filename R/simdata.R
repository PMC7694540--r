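# Kingman coalescent genealogy for n tips.
# Returns branches as parallel lists: tip set and length of every non-root
# branch. Uses the current RNG state (callers seed).
sim_genealogy <- function(n) {
  run_structured_coalescent(init_lineages(seq_len(n), rep(1L, n)), M = 0)
}

# A lineage set: list of tip-index vectors, deme of each, birth time of each.
init_lineages <- function(tips, deme, t0 = 0) {
  list(tips = lapply(tips, identity), deme = as.integer(deme),
       birth = rep(t0, length(tips)), t = t0,
       br_tips = list(), br_len = numeric())
}

# Structured (island-model) coalescent on an existing lineage set.
# Within-deme pairs coalesce at rate 1; each lineage migrates at rate M/2
# to a uniformly chosen other deme of `demes` (which may include currently
# empty demes). Runs until a single lineage remains or time t_max.
run_structured_coalescent <- function(lin, M, t_max = Inf,
                                      demes = sort(unique(lin$deme))) {
  repeat {
    k <- length(lin$tips)
    if (k <= 1L) break
    kd <- vapply(demes, function(d) sum(lin$deme == d), integer(1))
    coal_rates <- kd * (kd - 1) / 2
    mig_rate <- if (length(demes) > 1L) M / 2 * k else 0
    tot <- sum(coal_rates) + mig_rate
    if (tot <= 0) break                  # isolated singletons, no migration
    wait <- stats::rexp(1L, tot)
    if (lin$t + wait > t_max) { lin$t <- t_max; break }
    lin$t <- lin$t + wait
    if (stats::runif(1L) < sum(coal_rates) / tot) {
      d <- if (length(demes) == 1L) demes else
        demes[sample.int(length(demes), 1L, prob = coal_rates)]
      pair <- which(lin$deme == d)
      pair <- pair[sample.int(length(pair), 2L)]
      lin <- merge_lineages(lin, pair[1L], pair[2L])
    } else {
      i <- sample.int(k, 1L)
      others <- setdiff(demes, lin$deme[i])
      lin$deme[i] <- others[sample.int(length(others), 1L)]
    }
  }
  lin
}

# Record the two child branches and replace them with their ancestor.
merge_lineages <- function(lin, i, j) {
  lin$br_tips <- c(lin$br_tips, lin$tips[c(i, j)])
  lin$br_len <- c(lin$br_len, lin$t - lin$birth[c(i, j)])
  merged <- sort(c(lin$tips[[i]], lin$tips[[j]]))
  keep <- setdiff(seq_along(lin$tips), c(i, j))
  lin$tips <- c(lin$tips[keep], list(merged))
  lin$deme <- c(lin$deme[keep], lin$deme[i])
  lin$birth <- c(lin$birth[keep], lin$t)
  lin
}

# Force all open lineages into one panmictic deme (end of an isolation epoch).
pool_lineages <- function(lin) { lin$deme[] <- 1L; lin }

# Drop infinite-sites mutations on a completed genealogy, proportionally to
# branch length: either a Poisson(theta/2 * total length) number or exactly
# n_mut (fixed-S conditioning). Returns summary statistics and the
# descendant-set of each mutation.
drop_mutations <- function(lin, theta = NULL, n_mut = NULL) {
  n <- length(unique(unlist(lin$tips)))
  tot_len <- sum(lin$br_len)
  if (is.null(n_mut))
    n_mut <- stats::rpois(1L, theta / 2 * tot_len)
  if (n_mut > 0L && tot_len > 0) {
    br <- sample.int(length(lin$br_len), n_mut, replace = TRUE,
                     prob = lin$br_len)
    carriers <- lin$br_tips[br]
  } else carriers <- list()
  cc <- lengths(carriers)
  npairs <- n * (n - 1) / 2
  k <- if (length(cc)) sum(cc * (n - cc)) / npairs else 0
  eta_s <- sum(cc == 1L | cc == n - 1L)
  # haplotype partition: tips sharing the same mutation signature
  if (length(carriers)) {
    sig <- vapply(seq_len(n), function(tip)
      paste(which(vapply(carriers, function(s) tip %in% s, logical(1))),
            collapse = ","), character(1))
    h_counts <- as.integer(table(sig))
  } else h_counts <- n
  list(k = k, S = length(cc), eta = length(cc), eta_s = eta_s,
       h = length(h_counts), h_counts = h_counts, carriers = carriers, n = n)
}

# Convert a genealogy + mutations into a sequence matrix of length L.
# Infinite-sites positions are drawn uniformly without replacement; when
# mutations exceed L the fallback samples positions with replacement
# (finite sites) with a warning.
mutations_to_matrix <- function(mut, L) {
  n <- mut$n
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  nm <- length(mut$carriers)
  if (nm > 0L) {
    if (nm <= L) pos <- sample.int(L, nm) else {
      warning("finite-sites fallback: ", nm, " mutations on ", L, " sites")
      pos <- sample.int(L, nm, replace = TRUE)
    }
    for (i in seq_len(nm)) {
      p <- pos[i]
      derived <- sample(setdiff(bases, m[mut$carriers[[i]][1L], p]), 1L)
      m[mut$carriers[[i]], p] <- derived
    }
  }
  m
}

#' Simulate one neutral coalescent locus
#'
#' Kingman coalescent genealogy with Poisson(theta/2 x branch length)
#' infinite-sites mutations mapped to distinct uniform positions along an
#' alignment of length `L`.
#'
#' @param n number of haploid sequences (>= 2).
#' @param theta per-locus scaled mutation rate.
#' @param L alignment length in bp.
#' @param seed integer seed; the same seed yields an identical alignment.
#' @param population,region,locus_name,offset_kb metadata for the result.
#' @return a [locus_alignment()].
#' @export
coalescent_locus <- function(n, theta, L, seed, population = "pop1",
                             region = "region1", locus_name = "simlocus",
                             offset_kb = 0) {
  if (n < 2L) stop("need n >= 2")
  set.seed(as.integer(seed))
  gen <- sim_genealogy(n)
  mut <- drop_mutations(gen, theta = theta)
  locus_alignment(mutations_to_matrix(mut, L), population = population,
                  region = region, locus_name = locus_name,
                  offset_kb = offset_kb)
}

#' Simulate a locus under a star-genealogy (partial) selective sweep
#'
#' A fraction `f` of the sampled lineages coalesces instantly into a single
#' recent ancestor (the star component, the limiting genealogy of a hard
#' sweep); the remaining lineages plus that ancestor then coalesce
#' neutrally, and mutations are dropped on the resulting genealogy. `f = 0`
#' is the neutral model; `f = 1` yields identical sequences. Intermediate
#' `f` reproduces the sweep signature: depressed pi and Hd, negative
#' Tajima's D, one dominant haplotype.
#'
#' @param n sample size.
#' @param theta per-locus scaled mutation rate.
#' @param L alignment length (bp).
#' @param f sweep strength in `[0, 1]`.
#' @param seed integer seed.
#' @inheritParams coalescent_locus
#' @return a [locus_alignment()].
#' @export
apply_star_sweep <- function(n, theta, L, f, seed, population = "pop1",
                             region = "region1", locus_name = "simlocus",
                             offset_kb = 0) {
  stopifnot(f >= 0, f <= 1)
  set.seed(as.integer(seed))
  lin <- star_then_neutral(seq_len(n), f)
  mut <- drop_mutations(lin, theta = theta)
  locus_alignment(mutations_to_matrix(mut, L), population = population,
                  region = region, locus_name = locus_name,
                  offset_kb = offset_kb)
}

# Star component at time 0, then neutral coalescence (uses current RNG).
star_then_neutral <- function(tips, f) {
  n <- length(tips)
  m <- round(f * n)
  lin <- init_lineages(tips, rep(1L, n))
  if (m >= 2L) {
    star <- sample.int(n, m)
    for (idx in seq_len(m - 1L)) {
      # merge the first two star lineages repeatedly at t = 0
      pos <- which(vapply(lin$tips, function(s) any(s %in% tips[star]),
                          logical(1)))[1:2]
      lin <- merge_lineages(lin, pos[1L], pos[2L])
    }
  }
  run_structured_coalescent(lin, M = 0)
}

#' Simulate an island-model structured dataset at one locus
#'
#' Structured coalescent with `npops` demes exchanging migrants
#' symmetrically at scaled rate `M` (each lineage migrates at rate `M/2`);
#' within-deme pairs coalesce at rate 1.
#'
#' @param npops number of demes.
#' @param n_per_pop sequences sampled per deme.
#' @param theta per-locus scaled mutation rate.
#' @param M scaled migration rate (larger = closer to panmixia).
#' @param seed integer seed.
#' @param L alignment length (bp).
#' @param pop_names,region optional labels.
#' @param locus_name,offset_kb locus metadata.
#' @return named list of per-population [locus_alignment()]s.
#' @export
island_model_dataset <- function(npops, n_per_pop, theta, M, seed, L = 1000,
                                 pop_names = NULL, region = "region1",
                                 locus_name = "simlocus", offset_kb = 0) {
  if (npops < 2L) stop("need npops >= 2")
  if (M <= 0) stop("island model needs M > 0 to reach a common ancestor")
  set.seed(as.integer(seed))
  if (is.null(pop_names)) pop_names <- sprintf("pop%d", seq_len(npops))
  n <- npops * n_per_pop
  deme <- rep(seq_len(npops), each = n_per_pop)
  lin <- run_structured_coalescent(init_lineages(seq_len(n), deme), M = M,
                                   demes = seq_len(npops))
  mut <- drop_mutations(lin, theta = theta)
  aln <- locus_alignment(mutations_to_matrix(mut, L),
                         population = pop_names[deme], region = region,
                         locus_name = locus_name, offset_kb = offset_kb)
  split_by_population(aln)
}

#' Default simulation configuration for a six-locus region dataset
#'
#' The defaults emulate the sampling design of a resistance-locus amplicon
#' survey: six loci spanning about 120 kb at offsets -34, -9, 0, +29, +61
#' and +86 kb from the focal gene; seven populations in two regional
#' groups; within-group near-panmixia and a deep between-group split; and a
#' selective sweep confined to one group whose strength decays
#' exponentially with distance from the focal locus.
#'
#' @param n_per_pop sequences per population (default 20).
#' @param theta_per_site per-site scaled mutation rate (default 0.004,
#'   inside the unswept per-site diversity range of the motivating survey,
#'   roughly 2 to 6.5 per mille in the central-African populations).
#' @param M_within within-group scaled migration rate (default 25, which
#'   under the finite-island approximation `FST ~ 1/(1 + M (d/(d-1))^2)`
#'   targets within-group FST of about 0.02).
#' @param t_split between-group isolation time in coalescent units
#'   (default 4; pairwise between-group FST approx `t/(1+t)` = 0.8).
#' @param f0 sweep strength at the focal locus (default 0.95).
#' @param decay_kb exponential decay scale of sweep strength with distance
#'   (default 25 kb: a sharp footprint typical of a strong recent hard
#'   sweep, steep enough that the focal locus stands out from the -9 kb
#'   neighbour in the diversity-ratio profile).
#' @param swept_group group receiving the sweep (default "southern").
#' @param seed integer seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_pop = 20, theta_per_site = 0.004,
                              M_within = 25, t_split = 4, f0 = 0.95,
                              decay_kb = 25, swept_group = "southern",
                              seed = 1L) {
  loci <- data.frame(
    name = c("0BAC", "25BAC", "CYP6P9a", "63BAC", "95BAC", "120BAC"),
    offset_kb = c(-34, -9, 0, 29, 61, 86),
    L = c(626, 754, 1139, 614, 671, 633),
    stringsAsFactors = FALSE)
  pops <- data.frame(
    population = c("Mozambique", "Malawi", "Zambia", "Tanzania",
                   "Uganda", "DRCongo", "Cameroon"),
    group = c(rep("southern", 4), rep("eastern_central", 3)),
    stringsAsFactors = FALSE)
  structure(list(loci = loci, pops = pops, n_per_pop = n_per_pop,
                 theta_per_site = theta_per_site, M_within = M_within,
                 t_split = t_split, f0 = f0, decay_kb = decay_kb,
                 swept_group = swept_group, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sweep strength as a function of distance from the focal locus
#'
#' Exponential decay `f(offset) = f0 * exp(-|offset| / decay_kb)`,
#' maximal at the focal locus.
#'
#' @param offset_kb offset in kb.
#' @param f0 strength at offset 0.
#' @param decay_kb decay scale in kb.
#' @return sweep strength in `[0, 1]`.
#' @export
sweep_decay <- function(offset_kb, f0 = 0.95, decay_kb = 25) {
  f0 * exp(-abs(offset_kb) / decay_kb)
}

#' Simulate a full multi-locus regional dataset
#'
#' For every locus of the configuration, simulates a two-group structured
#' coalescent: within each group an island model with high migration
#' (near-panmixia), no migration between groups until `t_split`, after
#' which all remaining lineages coalesce panmictically. In the swept group
#' a star component of strength `f = f0 exp(-|offset|/decay_kb)` is applied
#' at time zero, so the sweep signal is strongest at the focal locus and
#' decays along the region.
#'
#' @param config a [simulation_config()].
#' @return named list of `locus_alignment`s (one per locus, all
#'   populations pooled with labels), ordered by genomic offset.
#' @export
rp1_region_dataset <- function(config = simulation_config()) {
  cfg <- config
  out <- vector("list", nrow(cfg$loci))
  names(out) <- cfg$loci$name
  for (li in seq_len(nrow(cfg$loci))) {
    set.seed(cfg$seed + 1000L * li)
    L <- cfg$loci$L[li]
    theta <- cfg$theta_per_site * L
    f <- sweep_decay(cfg$loci$offset_kb[li], cfg$f0, cfg$decay_kb)
    npop <- nrow(cfg$pops)
    n <- npop * cfg$n_per_pop
    deme <- rep(seq_len(npop), each = cfg$n_per_pop)
    tips <- seq_len(n)
    groups <- unique(cfg$pops$group)
    # epoch 1: within-group island models, no gene flow between groups
    merged <- NULL
    for (g in groups) {
      gdemes <- which(cfg$pops$group == g)
      gtips <- tips[deme %in% gdemes]
      if (g == cfg$swept_group && f > 0) {
        lin <- init_lineages(gtips, deme[gtips])
        m <- round(f * length(gtips))
        if (m >= 2L) {
          star <- sample(gtips, m)
          for (s in seq_len(m - 1L)) {
            pos <- which(vapply(lin$tips, function(x) any(x %in% star),
                                logical(1)))[1:2]
            lin <- merge_lineages(lin, pos[1L], pos[2L])
          }
        }
      } else {
        lin <- init_lineages(gtips, deme[gtips])
      }
      lin <- run_structured_coalescent(lin, M = cfg$M_within,
                                       t_max = cfg$t_split, demes = gdemes)
      merged <- if (is.null(merged)) lin else join_lineage_sets(merged, lin)
    }
    # epoch 2: one ancestral panmictic population
    merged$t <- cfg$t_split
    merged <- pool_lineages(merged)
    merged <- run_structured_coalescent(merged, M = 0)
    mut <- drop_mutations(merged, theta = theta)
    out[[li]] <- locus_alignment(
      mutations_to_matrix(mut, L),
      sample_id = sprintf("%s_h%03d", cfg$pops$population[deme], ave(
        deme, deme, FUN = seq_along)),
      population = cfg$pops$population[deme],
      region = cfg$pops$group[deme],
      locus_name = cfg$loci$name[li], offset_kb = cfg$loci$offset_kb[li])
  }
  out[order(cfg$loci$offset_kb)]
}

join_lineage_sets <- function(a, b) {
  list(tips = c(a$tips, b$tips), deme = c(a$deme, b$deme),
       birth = c(a$birth, b$birth), t = max(a$t, b$t),
       br_tips = c(a$br_tips, b$br_tips), br_len = c(a$br_len, b$br_len))
}

#' Write a simulated regional dataset to disk
#'
#' Emits one FASTA per locus, a shared sample-to-population map TSV and a
#' region configuration YAML, i.e. exactly the inputs the analysis side of
#' the package consumes.
#'
#' @param dataset result of [rp1_region_dataset()].
#' @param dir output directory (created if needed).
#' @param focal name of the focal locus (default "CYP6P9a").
#' @return path of the region config file, invisibly.
#' @export
write_region_dataset <- function(dataset, dir, focal = "CYP6P9a") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- unique(do.call(rbind, lapply(dataset, function(a) a$samples)))
  utils::write.table(pm, file.path(dir, "pop_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  loci <- lapply(dataset, function(a) {
    fa <- file.path(dir, paste0(a$locus_name, ".fasta"))
    write_fasta_alignment(a, fa)
    list(name = a$locus_name, offset_kb = a$offset_kb,
         fasta = basename(fa))
  })
  groups <- stats::setNames(as.list(pm$region[!duplicated(pm$population)]),
                            pm$population[!duplicated(pm$population)])
  cfgfile <- file.path(dir, "region.yaml")
  yaml::write_yaml(list(focal = focal, pop_map = "pop_map.tsv",
                        loci = unname(loci), groups = groups), cfgfile)
  invisible(cfgfile)
}
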