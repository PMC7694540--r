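#' Read a region configuration (YAML or JSON)
#'
#' The file lists the loci of the scanned region (name, offset in kb from
#' the focal gene, FASTA path), a sample-to-population map, a mapping from
#' population to regional group, and the focal locus name. Relative paths
#' are resolved against the config file's directory.
#'
#' @param path YAML or JSON file.
#' @return a `region_config` list with elements `loci` (data.frame),
#'   `groups` (named character), `focal`, `pop_map` (data.frame).
#' @export
read_region_config <- function(path) {
  if (!file.exists(path)) stop("file error: no such file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(path)
  loci <- do.call(rbind, lapply(cfg$loci, function(l)
    data.frame(name = l$name, offset_kb = as.numeric(l$offset_kb),
               fasta = file.path(base, l$fasta), stringsAsFactors = FALSE)))
  if (anyDuplicated(loci$offset_kb)) stop("duplicate locus offsets")
  groups <- unlist(cfg$groups)
  pm <- read_pop_map(file.path(base, cfg$pop_map))
  structure(list(loci = loci, groups = groups, focal = cfg$focal,
                 pop_map = pm), class = "region_config")
}

# Accept either a region_config (reading FASTAs) or a named list of
# locus_alignments (e.g. straight from rp1_region_dataset()).
load_region <- function(config) {
  if (inherits(config, "region_config")) {
    alns <- lapply(seq_len(nrow(config$loci)), function(i)
      read_fasta_alignment(config$loci$fasta[i], config$pop_map,
                           locus_name = config$loci$name[i],
                           offset_kb = config$loci$offset_kb[i]))
    names(alns) <- config$loci$name
    groups <- config$groups
  } else {
    alns <- config
    groups <- do.call(c, unname(lapply(alns, function(a)
      stats::setNames(a$samples$region, a$samples$population))))
    groups <- groups[!duplicated(names(groups))]
  }
  list(alns = alns[order(vapply(alns, `[[`, numeric(1), "offset_kb"))],
       groups = groups)
}

#' Per-locus, per-population diversity profile across a region
#'
#' Fills the haplotype diversity, nucleotide diversity and Tajima's D of
#' every (locus, population) cell, the per-locus group means and the
#' between-group pi ratio. Undefined statistics (monomorphic populations)
#' are `NA`, rendered "n.a" by the writer. A population missing at a locus
#' is flagged in the `note` column rather than failing the scan.
#'
#' @param config a `region_config` or a named list of `locus_alignment`s
#'   with population and region labels.
#' @param comparison,reference regional groups compared in the pi ratio
#'   (defaults: the non-swept convention `"eastern_central"` over
#'   `"southern"`).
#' @param ratio_method `"mean"` (default: ratio of unweighted group means
#'   of per-population pi) or `"pooled"` (pi of group-pooled alignments).
#' @return a `locus_scan_table`: data.frame of per-cell rows, with the
#'   per-locus summary in attribute `"locus_summary"`.
#' @export
per_locus_profile <- function(config, comparison = "eastern_central",
                              reference = "southern",
                              ratio_method = c("mean", "pooled")) {
  ratio_method <- match.arg(ratio_method)
  reg <- load_region(config)
  rows <- list()
  for (ln in names(reg$alns)) {
    aln <- reg$alns[[ln]]
    for (p in unique(aln$samples$population)) {
      sub <- tryCatch(subset_alignment(aln, population = p),
                      error = function(e) NULL)
      if (is.null(sub)) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = ln, offset_kb = aln$offset_kb, population = p,
          group = unname(reg$groups[p]), n2 = NA, S = NA, h = NA,
          Hd = NA, pi = NA, D = NA, note = "insufficient sequences",
          stringsAsFactors = FALSE)
        next
      }
      ds <- diversity_summary(sub)
      nt <- neutrality_tests(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = ln, offset_kb = aln$offset_kb, population = p,
        group = unname(reg$groups[p]), n2 = ds$n2, S = ds$S, h = ds$h,
        Hd = ds$Hd, pi = ds$pi, D = nt$D, note = "",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- lapply(split(tab, tab$locus), function(lt) {
    mk <- function(g) mean(lt$pi[lt$group == g], na.rm = TRUE)
    ratio <- if (ratio_method == "mean") {
      rf <- mk(reference)
      if (is.finite(rf) && rf > 0) mk(comparison) / rf else NA_real_
    } else {
      aln <- reg$alns[[lt$locus[1L]]]
      pc <- nucleotide_diversity(subset_alignment(aln, region = comparison))
      pr <- nucleotide_diversity(subset_alignment(aln, region = reference))
      if (pr > 0) pc / pr else NA_real_
    }
    data.frame(locus = lt$locus[1L], offset_kb = lt$offset_kb[1L],
               pi_comparison = mk(comparison), pi_reference = mk(reference),
               pi_ratio = ratio, stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  summ <- summ[order(summ$offset_kb), ]
  rownames(summ) <- NULL
  attr(tab, "locus_summary") <- summ
  attr(tab, "comparison") <- comparison
  attr(tab, "reference") <- reference
  class(tab) <- c("locus_scan_table", "data.frame")
  tab
}

#' Per-locus diversity ratio between two regional groups
#'
#' @param table a `locus_scan_table` from [per_locus_profile()].
#' @param comparison,reference group labels.
#' @return data.frame with one ratio per locus, ordered by offset;
#'   undefined (NA) when the reference group mean is zero.
#' @export
group_pi_ratio <- function(table, comparison = "eastern_central",
                           reference = "southern") {
  out <- lapply(split(as.data.frame(table), table$locus), function(lt) {
    mc <- mean(lt$pi[lt$group == comparison], na.rm = TRUE)
    mr <- mean(lt$pi[lt$group == reference], na.rm = TRUE)
    data.frame(locus = lt$locus[1L], offset_kb = lt$offset_kb[1L],
               pi_ratio = if (is.finite(mr) && mr > 0) mc / mr else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$offset_kb), ]
  rownames(out) <- NULL
  out
}

#' Call selective sweeps per locus and group
#'
#' Flags a (locus, group) pair as swept when the group's mean nucleotide
#' and haplotype diversity at that locus fall below configured quantiles
#' of the per-population values of the reference (non-swept) group at the
#' same locus, and Tajima's D is consistent with a sweep (group mean below
#' `d_max`); a monomorphic group (pi = 0, D undefined) is always flagged.
#' Thresholds are configuration, not fixed constants.
#'
#' @param table a `locus_scan_table`.
#' @param thresholds list: `pi_quantile` and `hd_quantile` (default 0.25),
#'   `d_max` (default -1.5).
#' @param groups groups to evaluate (default: all non-reference groups
#'   plus the reference's complement; every group present is assessed
#'   against the other groups pooled).
#' @return data.frame of per (locus, group) calls plus a region summary in
#'   attribute `"extent"` (offset range of swept loci per group).
#' @export
sweep_report <- function(table,
                         thresholds = list(pi_quantile = 0.25,
                                           hd_quantile = 0.25,
                                           d_max = -1.5),
                         groups = NULL) {
  tab <- as.data.frame(table)
  if (is.null(groups)) groups <- unique(tab$group)
  rows <- list()
  for (ln in unique(tab$locus)) {
    lt <- tab[tab$locus == ln, ]
    for (g in groups) {
      gt <- lt[lt$group == g, ]
      ot <- lt[lt$group != g, ]
      if (!nrow(gt) || all(is.na(gt$pi))) next
      pi_g <- mean(gt$pi, na.rm = TRUE)
      hd_g <- mean(gt$Hd, na.rm = TRUE)
      d_g <- mean(gt$D, na.rm = TRUE)
      pi_thr <- stats::quantile(ot$pi, thresholds$pi_quantile, na.rm = TRUE)
      hd_thr <- stats::quantile(ot$Hd, thresholds$hd_quantile, na.rm = TRUE)
      swept <- if (pi_g == 0) TRUE else {
        pi_g <= pi_thr && hd_g <= hd_thr &&
          (!is.na(d_g) && d_g <= thresholds$d_max)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = ln, offset_kb = lt$offset_kb[1L], group = g,
        pi = pi_g, Hd = hd_g, D = d_g, pi_threshold = unname(pi_thr),
        hd_threshold = unname(hd_thr), swept = swept,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no (locus, group) pair could be evaluated")
  out <- do.call(rbind, rows)
  out <- out[order(out$offset_kb, out$group), ]
  rownames(out) <- NULL
  extent <- do.call(rbind, lapply(split(out, out$group), function(gt) {
    sw <- gt[gt$swept, ]
    data.frame(group = gt$group[1L], n_swept = nrow(sw),
               from_kb = if (nrow(sw)) min(sw$offset_kb) else NA_real_,
               to_kb = if (nrow(sw)) max(sw$offset_kb) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(extent) <- NULL
  attr(out, "extent") <- extent
  out
}

#' Write a locus scan table as TSV
#'
#' @param table a `locus_scan_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(table, path) {
  tab <- as.data.frame(table)
  tab$Hd <- ifelse(is.na(tab$Hd), "n.a", sprintf("%.2f", tab$Hd))
  tab$pi <- ifelse(is.na(tab$pi), "n.a", sprintf("%.5f", tab$pi))
  tab$D <- ifelse(is.na(tab$D), "n.a", sprintf("%.2f", tab$D))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
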