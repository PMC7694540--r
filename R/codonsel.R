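GENETIC_CODE_STD <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

translate_codon <- function(codon) unname(GENETIC_CODE_STD[codon])

# The nine single-base neighbours of a codon.
codon_neighbours <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (alt in setdiff(c("A","C","G","T"), b[p])) {
    nb <- b; nb[p] <- alt
    out <- c(out, paste(nb, collapse = ""))
  }
  out
}

# Synonymous/total mutational site fractions of one codon. Changes creating
# stop codons are excluded from both numerator and denominator when
# stop_mutations = "excluded" (the default) and counted as non-synonymous
# when "nonsynonymous".
codon_site_fractions <- function(codon,
                                 stop_mutations = c("excluded",
                                                    "nonsynonymous")) {
  stop_mutations <- match.arg(stop_mutations)
  aa <- translate_codon(codon)
  nb <- codon_neighbours(codon)
  aan <- translate_codon(nb)
  keep <- if (stop_mutations == "excluded") aan != "*" else rep(TRUE, 9L)
  syn <- sum(aan[keep] == aa) / 3
  tot <- sum(keep) / 3
  c(syn = syn, nonsyn = tot - syn)
}

# Trim a sequence matrix to the reading frame and return codon index sets.
frame_trim <- function(mat, frame) {
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  mat <- mat[, frame:ncol(mat), drop = FALSE]
  if (ncol(mat) %% 3 != 0)
    stop("coding length (", ncol(mat), ") not divisible by 3 after frame trim")
  mat
}

#' Nei-Gojobori synonymous and non-synonymous site counts
#'
#' For every codon of every sequence, each of the nine single-base changes
#' contributes 1/3 of a site, synonymous or non-synonymous by its
#' amino-acid effect under the standard genetic code; fractions are
#' averaged over all sequences in the alignment (which is why site totals
#' are population-specific and fractional). By default, changes creating a
#' stop codon are excluded from both the numerator and the site
#' denominator. Codons containing gaps, N or ambiguity codes, and internal
#' stop codons (with a warning), are skipped.
#'
#' @param coding_aln a `locus_alignment` restricted to the coding region.
#' @param frame reading frame: the column where codon position 1 starts
#'   (1, 2 or 3).
#' @param stop_mutations `"excluded"` (default) or `"nonsynonymous"`.
#' @return list with `syn_sites` and `nonsyn_sites` (fractional,
#'   per-sequence averages).
#' @export
ng_site_fractions <- function(coding_aln, frame = 1,
                              stop_mutations = "excluded") {
  mat <- frame_trim(coding_aln$seq, frame)
  ncod <- ncol(mat) / 3
  syn <- nonsyn <- numeric(nrow(mat))
  warned <- FALSE
  for (i in seq_len(nrow(mat))) {
    for (cd in seq_len(ncod)) {
      codon <- paste(mat[i, (3 * cd - 2):(3 * cd)], collapse = "")
      if (!codon %in% names(GENETIC_CODE_STD)) next
      if (translate_codon(codon) == "*") {
        if (!warned) { warning("internal stop codon(s) skipped"); warned <- TRUE }
        next
      }
      f <- codon_site_fractions(codon, stop_mutations)
      syn[i] <- syn[i] + f["syn"]
      nonsyn[i] <- nonsyn[i] + f["nonsyn"]
    }
  }
  list(syn_sites = mean(syn), nonsyn_sites = mean(nonsyn))
}

# Average synonymous/non-synonymous composition over all minimal
# single-step mutational pathways between two codons, skipping pathways
# through stop codons where any stop-free pathway exists.
pathway_classify <- function(cod_a, cod_b) {
  a <- strsplit(cod_a, "")[[1]]; b <- strsplit(cod_b, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- all_permutations(pos)
  paths <- list()
  for (ord in perms) {
    cur <- a; steps <- character(0); through_stop <- FALSE
    syn <- 0; nonsyn <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (aa2 == "*" || aa1 == "*") through_stop <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(syn = syn, nonsyn = nonsyn,
                                        stop = through_stop)
  }
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (any(ok)) paths <- paths[ok]
  c(syn = mean(vapply(paths, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(paths, `[[`, numeric(1), "nonsyn")))
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Classify observed coding substitutions as synonymous or non-synonymous
#'
#' Each polymorphic codon is classified by the amino-acid effect of its
#' variant codons in context. Codons with one varying position give an
#' integer (1, 0) or (0, 1) contribution; codons with several varying
#' positions are averaged over all minimal mutational pathways between the
#' two most frequent variants (pathways through stop codons are avoided
#' when possible), and codons with three or more distinct variants are
#' pathway-averaged pairwise against the major variant with a warning.
#'
#' @inheritParams ng_site_fractions
#' @return list with `syn_subs` and `nonsyn_subs` (possibly fractional
#'   after pathway averaging).
#' @export
classify_substitutions <- function(coding_aln, frame = 1) {
  mat <- frame_trim(coding_aln$seq, frame)
  ncod <- ncol(mat) / 3
  syn <- nonsyn <- 0
  for (cd in seq_len(ncod)) {
    sub <- mat[, (3 * cd - 2):(3 * cd), drop = FALSE]
    codons <- apply(sub, 1L, paste, collapse = "")
    codons <- codons[codons %in% names(GENETIC_CODE_STD)]
    codons <- codons[translate_codon(codons) != "*"]
    tab <- sort(table(codons), decreasing = TRUE)
    if (length(tab) < 2L) next
    if (length(tab) > 2L)
      warning("codon ", cd, ": >2 variants, pathway-averaged against the ",
              "major variant")
    major <- names(tab)[1L]
    for (v in names(tab)[-1L]) {
      cl <- pathway_classify(major, v)
      syn <- syn + cl["syn"]
      nonsyn <- nonsyn + cl["nonsyn"]
    }
  }
  list(syn_subs = unname(syn), nonsyn_subs = unname(nonsyn))
}

#' Build the codon-count table for a coding alignment
#'
#' @inheritParams ng_site_fractions
#' @return a `codon_count_table` list: syn/nonsyn sites and substitutions,
#'   pS, pN.
#' @export
codon_count_table <- function(coding_aln = NULL, frame = 1,
                              stop_mutations = "excluded",
                              syn_sites = NULL, nonsyn_sites = NULL,
                              syn_subs = NULL, nonsyn_subs = NULL) {
  if (!is.null(coding_aln)) {
    sf <- ng_site_fractions(coding_aln, frame, stop_mutations)
    cs <- classify_substitutions(coding_aln, frame)
    syn_sites <- sf$syn_sites; nonsyn_sites <- sf$nonsyn_sites
    syn_subs <- cs$syn_subs; nonsyn_subs <- cs$nonsyn_subs
  }
  structure(list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                 syn_subs = syn_subs, nonsyn_subs = nonsyn_subs,
                 pS = syn_subs / syn_sites, pN = nonsyn_subs / nonsyn_sites),
            class = "codon_count_table")
}

#' pN/pS ratio
#'
#' `pN/pS = (nonsyn_subs/nonsyn_sites) / (syn_subs/syn_sites)`. Values
#' above 1 indicate positive selection, below 1 purifying selection.
#' Undefined (NA, reported "-") when there are no synonymous
#' substitutions.
#'
#' @param counts a [codon_count_table()].
#' @return the ratio, or `NA` when undefined.
#' @export
pnps <- function(counts) {
  if (counts$syn_subs == 0) return(NA_real_)
  counts$pN / counts$pS
}

#' Per-population pN/pS table for a coding alignment
#'
#' @param aln a `locus_alignment` covering the coding region, with
#'   population labels.
#' @inheritParams ng_site_fractions
#' @return data.frame shaped like the classical pN/pS table: sites,
#'   substitutions, pS, pN and the ratio per population.
#' @export
pnps_table <- function(aln, frame = 1, stop_mutations = "excluded") {
  parts <- split_by_population(aln)
  rows <- lapply(names(parts), function(p) {
    ct <- codon_count_table(parts[[p]], frame, stop_mutations)
    data.frame(population = p, syn_sites = round(ct$syn_sites, 2),
               syn_subs = ct$syn_subs, pS = round(ct$pS, 3),
               nonsyn_sites = round(ct$nonsyn_sites, 2),
               nonsyn_subs = ct$nonsyn_subs, pN = round(ct$pN, 3),
               pnps = round(pnps(ct), 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
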