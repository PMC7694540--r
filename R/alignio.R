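#' @keywords internal
"_PACKAGE"

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a locus alignment
#'
#' A `locus_alignment` holds phased haplotype sequences for one locus
#' together with the population and regional-group label of each sequence.
#' Sequences are stored as an upper-case character matrix (one row per
#' haplotype) over the alphabet `A,C,G,T,N,-` plus IUPAC ambiguity codes.
#'
#' @param seqs character matrix (rows = haplotypes, columns = sites) or a
#'   character vector of equal-length sequence strings.
#' @param sample_id character vector of unique sequence identifiers.
#' @param population character vector of population labels.
#' @param region character vector of regional-group labels (e.g. "southern").
#' @param locus_name name of the locus.
#' @param offset_kb position of the locus in kb relative to the focal gene.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, sample_id = NULL, population = "pop1",
                            region = "region1", locus_name = "locus",
                            offset_kb = 0) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- toupper(as.matrix(seqs))
  n <- nrow(seqs)
  if (n < 2L) stop("alignment error: need at least 2 sequences")
  if (ncol(seqs) < 1L) stop("alignment error: zero-length alignment")
  bad <- setdiff(unique(as.vector(seqs)), c(names(IUPAC_CODES), "-"))
  if (length(bad))
    stop("input error: non-IUPAC character(s): ", paste(bad, collapse = ", "))
  if (is.null(sample_id)) sample_id <- if (!is.null(rownames(seqs)))
    rownames(seqs) else sprintf("seq%03d", seq_len(n))
  if (anyDuplicated(sample_id))
    stop("metadata error: duplicated sample_id in alignment")
  population <- rep_len(as.character(population), n)
  region <- rep_len(as.character(region), n)
  rownames(seqs) <- sample_id
  structure(
    list(locus_name = locus_name, offset_kb = offset_kb, seq = seqs,
         samples = data.frame(sample_id = sample_id, population = population,
                              region = region, stringsAsFactors = FALSE)),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus_name, "' (", x$offset_kb, " kb): ",
      nrow(x$seq), " sequences x ", ncol(x$seq), " bp, ",
      length(unique(x$samples$population)), " population(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.locus_alignment <- function(x) dim(x$seq)

#' Subset an alignment by sample, population or region
#'
#' @param aln a `locus_alignment`.
#' @param samples,population,region keep sequences matching any of these.
#' @return a `locus_alignment` with the selected rows, input order preserved.
#' @export
subset_alignment <- function(aln, samples = NULL, population = NULL,
                             region = NULL) {
  keep <- rep(TRUE, nrow(aln$seq))
  if (!is.null(samples)) keep <- keep & aln$samples$sample_id %in% samples
  if (!is.null(population)) keep <- keep & aln$samples$population %in% population
  if (!is.null(region)) keep <- keep & aln$samples$region %in% region
  if (sum(keep) < 2L)
    stop("alignment error: fewer than 2 sequences after subsetting")
  locus_alignment(aln$seq[keep, , drop = FALSE],
                  sample_id = aln$samples$sample_id[keep],
                  population = aln$samples$population[keep],
                  region = aln$samples$region[keep],
                  locus_name = aln$locus_name, offset_kb = aln$offset_kb)
}

#' Split an alignment into per-population alignments
#'
#' @param aln a `locus_alignment`.
#' @param by group by `"population"` (default) or `"region"`.
#' @return named list of `locus_alignment` objects.
#' @export
split_by_population <- function(aln, by = c("population", "region")) {
  by <- match.arg(by)
  labs <- aln$samples[[by]]
  out <- lapply(unique(labs), function(p)
    subset_alignment(aln, population = if (by == "population") p else NULL,
                     region = if (by == "region") p else NULL))
  names(out) <- unique(labs)
  out
}

#' Read a FASTA alignment with population metadata
#'
#' Reads a multiple sequence alignment in FASTA format and attaches
#' population and region labels from a sample map. Record order is
#' preserved. All sequences must have identical length and every record id
#' must be present in the map.
#'
#' @param path FASTA file of aligned, phased haplotypes.
#' @param pop_map a data.frame with columns `sample_id`, `population` and
#'   optionally `region`, or the path to a tab-separated file with a header
#'   naming those columns.
#' @param locus_name,offset_kb locus metadata (defaults: file stem, 0).
#' @return a [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, pop_map, locus_name = NULL,
                                 offset_kb = 0) {
  if (!file.exists(path)) stop("file error: no such file: ", path)
  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  if (is.null(locus_name))
    locus_name <- tools::file_path_sans_ext(basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) < 2L) stop("alignment error: fewer than 2 records")
  chars <- lapply(as.character(dna), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L)
    stop("alignment error: ragged sequence lengths (",
         paste(sort(unique(lens)), collapse = ", "), ") in ", path)
  ids <- names(dna)
  missing_ids <- setdiff(ids, pop_map$sample_id)
  if (length(missing_ids))
    stop("metadata error: sample id(s) not in population map: ",
         paste(missing_ids, collapse = ", "))
  idx <- match(ids, pop_map$sample_id)
  region <- if ("region" %in% names(pop_map)) pop_map$region[idx] else "region1"
  locus_alignment(do.call(rbind, chars), sample_id = ids,
                  population = pop_map$population[idx], region = region,
                  locus_name = locus_name, offset_kb = offset_kb)
}

#' Read a sample-to-population map
#'
#' @param path tab-separated file with header `sample_id`, `population` and
#'   optionally `region`.
#' @return data.frame.
#' @export
read_pop_map <- function(path) {
  if (!file.exists(path)) stop("file error: no such file: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(m)))
    stop("metadata error: population map needs columns ",
         paste(need, collapse = ", "))
  m
}

#' Write an alignment to FASTA (with its population map alongside)
#'
#' @param aln a `locus_alignment`.
#' @param path output FASTA path.
#' @param pop_map_path optional path for the matching sample map TSV.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, pop_map_path = NULL) {
  lines <- character(2L * nrow(aln$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$samples$sample_id)
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  if (!is.null(pop_map_path))
    utils::write.table(aln$samples, pop_map_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify alignment columns
#'
#' Labels every column of an alignment as monomorphic, a segregating SNP, an
#' indel column, or excluded for missing data, and tallies segregating sites
#' (S), total mutations (eta), singleton mutations (eta_s) and indel columns.
#' Filtering is "complete deletion": any column containing a gap is an indel
#' column and any column containing `N` or an ambiguity code is excluded;
#' neither contributes to S or to downstream diversity statistics. At a
#' segregating site a site with `a` nucleotide states carries `a - 1`
#' mutations, of which those observed in exactly one sequence are singletons.
#'
#' @param aln a `locus_alignment`.
#' @return a `site_classification` list: `status` (factor, one level per
#'   column), `S`, `eta`, `eta_s`, `n_indels`, `valid` (logical index of
#'   analysed columns: monomorphic or SNP).
#' @export
classify_sites <- function(aln) {
  x <- aln$seq
  n <- nrow(x)
  L <- ncol(x)
  status <- character(L)
  eta <- 0L; eta_s <- 0L
  nuc <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    col <- x[, j]
    if (any(col == "-")) { status[j] <- "indel_column"; next }
    if (any(!col %in% nuc)) { status[j] <- "excluded_missing"; next }
    tab <- tabulate(match(col, nuc), nbins = 4L)
    a <- sum(tab > 0L)
    if (a < 2L) { status[j] <- "monomorphic"; next }
    status[j] <- "segregating_SNP"
    eta <- eta + (a - 1L)
    eta_s <- eta_s + min(sum(tab == 1L), a - 1L)
  }
  status <- factor(status, levels = c("monomorphic", "segregating_SNP",
                                      "indel_column", "excluded_missing"))
  structure(list(status = status, S = sum(status == "segregating_SNP"),
                 eta = eta, eta_s = eta_s,
                 n_indels = sum(status == "indel_column"),
                 valid = status %in% c("monomorphic", "segregating_SNP")),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("site_classification: L =", length(x$status), " S =", x$S,
      " eta =", x$eta, " eta_s =", x$eta_s, " indels =", x$n_indels, "\n")
  invisible(x)
}

#' Resolve heterozygous (ambiguity-coded) diploid consensus sequences
#'
#' Direct Sanger sequencing of diploid individuals yields one consensus per
#' individual with IUPAC ambiguity codes at heterozygous sites. Statistical
#' phasing is out of scope here; this fallback either splits each individual
#' into two pseudo-haplotypes with each ambiguous site resolved to one of
#' its constituent bases uniformly at random (`split_random`, seeded; the
#' two haplotypes receive complementary bases at biallelic codes), or masks
#' ambiguous sites to `N` (`exclude_ambiguous`), so they are dropped by
#' complete deletion.
#'
#' @param diploid a `locus_alignment` of diploid consensus sequences.
#' @param mode `"split_random"` or `"exclude_ambiguous"`.
#' @param seed integer seed (required for `split_random`).
#' @return a `locus_alignment`; under `split_random` it has `2n` rows with
#'   sample ids suffixed `_1`/`_2`.
#' @export
resolve_heterozygotes <- function(diploid,
                                  mode = c("split_random", "exclude_ambiguous"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  x <- diploid$seq
  amb_codes <- setdiff(names(IUPAC_CODES), c("A", "C", "G", "T", "N"))
  if (mode == "exclude_ambiguous") {
    x[x %in% amb_codes] <- "N"
    return(locus_alignment(x, sample_id = diploid$samples$sample_id,
                           population = diploid$samples$population,
                           region = diploid$samples$region,
                           locus_name = diploid$locus_name,
                           offset_kb = diploid$offset_kb))
  }
  if (is.null(seed)) stop("split_random requires a seed")
  set.seed(as.integer(seed))
  n <- nrow(x)
  out <- matrix("", nrow = 2L * n, ncol = ncol(x))
  for (i in seq_len(n)) {
    h1 <- x[i, ]; h2 <- x[i, ]
    amb <- which(h1 %in% amb_codes)
    for (j in amb) {
      bases <- IUPAC_CODES[[h1[j]]]
      pick <- sample(bases, 2L, replace = length(bases) < 2L)
      h1[j] <- pick[1L]; h2[j] <- pick[2L]
    }
    out[2L * i - 1L, ] <- h1
    out[2L * i, ] <- h2
  }
  ids <- as.vector(rbind(paste0(diploid$samples$sample_id, "_1"),
                         paste0(diploid$samples$sample_id, "_2")))
  locus_alignment(out, sample_id = ids,
                  population = rep(diploid$samples$population, each = 2L),
                  region = rep(diploid$samples$region, each = 2L),
                  locus_name = diploid$locus_name,
                  offset_kb = diploid$offset_kb)
}
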