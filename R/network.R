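#' Collapse an alignment into haplotypes (gaps as a fifth state)
#'
#' Identical sequences are merged into haplotypes with frequencies and
#' per-population counts. Comparison treats the gap character as a fifth
#' state, so a sequence differing only by an indel column is a distinct
#' haplotype; columns excluded for missing data ([classify_sites()]) are
#' dropped before comparison.
#'
#' @param aln a `locus_alignment`.
#' @return data.frame of class `haplotype_set`: `id` (H1, H2, ... by
#'   decreasing frequency, ties by sequence lexicographic order),
#'   `sequence`,
#'   `frequency`, and one count column per population; the full sequence
#'   matrix of haplotype representatives is kept in attribute `"seq"`.
#' @export
collapse_haplotypes <- function(aln) {
  sites <- classify_sites(aln)
  keep <- sites$status != "excluded_missing"
  mat <- aln$seq[, keep, drop = FALSE]
  key <- apply(mat, 1L, paste, collapse = "")
  haps <- unique(key)
  freq <- as.integer(table(key)[haps])
  # order-independent ids: frequency rank, ties by sequence lexicographic
  ord <- order(-freq, haps)
  haps <- haps[ord]; freq <- freq[ord]
  pops <- sort(unique(aln$samples$population))
  comp <- t(vapply(haps, function(h)
    vapply(pops, function(p)
      sum(key == h & aln$samples$population == p), integer(1)),
    integer(length(pops))))
  if (length(pops) == 1L) comp <- matrix(comp, ncol = 1L)
  out <- data.frame(id = sprintf("H%d", seq_along(haps)), sequence = haps,
                    frequency = freq, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(comp, row.names = NULL))
  names(out)[-(1:3)] <- pops
  attr(out, "seq") <- mat[match(haps, key), , drop = FALSE]
  class(out) <- c("haplotype_set", "data.frame")
  out
}

# Probability that a connection of j observed differences over m sites is
# free of superimposed or parallel changes. Mutations hit sites
# independently; the per-site expected number of hits mu is solved from
# the 4-state correction so that the expected fraction of differing sites
# equals j/m. The connection is parsimonious when each differing site was
# hit exactly once and no other site was hit invisibly.
parsimony_probability <- function(j, m) {
  q <- j / m
  if (q >= 3 / 4) return(0)
  if (j == 0) return(1)
  mu <- -0.75 * log1p(-4 * q / 3)
  p_single_given_diff <- mu * exp(-mu) / q
  p_clean_given_same <- exp(-mu) / (1 - q)
  p_single_given_diff^j * p_clean_given_same^(m - j)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` such that the probability
#' that a j-step connection between two haplotypes is non-homoplasious
#' ([parsimony_probability()]) is at least `alpha`. Haplotype pairs more
#' than `j` steps apart are not connected in the network.
#'
#' @param L_valid number of compared sites.
#' @param alpha connection confidence (default 0.95).
#' @return the limit j, an integer >= 0.
#' @export
parsimony_connection_limit <- function(L_valid, alpha = 0.95) {
  if (L_valid < 1) stop("L_valid must be >= 1")
  j <- 0L
  while (j < L_valid && parsimony_probability(j + 1L, L_valid) >= alpha)
    j <- j + 1L
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes in order of increasing fifth-state Hamming distance
#' up to the connection limit, inserting unobserved intermediate nodes on
#' multi-step links so that every edge spans exactly one mutational step.
#' Ties are broken by higher endpoint frequency first, then by
#' lexicographic id pair; by default links that would close a cycle are
#' skipped (single spanning forest), and `retain_ties = TRUE` keeps
#' equal-distance alternative links for display.
#'
#' @param haplotypes a `haplotype_set` from [collapse_haplotypes()].
#' @param j95 connection limit in steps (default: computed from the
#'   sequence length with [parsimony_connection_limit()]).
#' @param alpha confidence used when computing the default limit.
#' @param retain_ties keep equal-distance links that close cycles.
#' @return a `parsimony_network` list: `nodes` (id, frequency, observed,
#'   population counts), `edges` (from, to, one step each), `j95`,
#'   `components` (component id per observed haplotype).
#' @export
build_statistical_parsimony_network <- function(haplotypes, j95 = NULL,
                                                alpha = 0.95,
                                                retain_ties = FALSE) {
  hs <- haplotypes
  mat <- attr(hs, "seq")
  H <- nrow(hs)
  if (is.null(j95)) j95 <- parsimony_connection_limit(ncol(mat), alpha)
  # pairwise fifth-state Hamming distances
  dm <- matrix(0L, H, H)
  if (H > 1L) for (a in 2:H) for (b in seq_len(a - 1L))
    dm[a, b] <- dm[b, a] <- sum(mat[a, ] != mat[b, ])
  cand <- which(upper.tri(dm) & dm <= j95 & dm > 0L, arr.ind = TRUE)
  if (nrow(cand)) {
    o <- order(dm[cand],
               -pmax(hs$frequency[cand[, 1]], hs$frequency[cand[, 2]]),
               -pmin(hs$frequency[cand[, 1]], hs$frequency[cand[, 2]]),
               hs$id[cand[, 1]], hs$id[cand[, 2]])
    cand <- cand[o, , drop = FALSE]
  }
  comp <- seq_len(H)                     # union-find over observed haplotypes
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  extra_nodes <- character(0)
  n_inferred <- 0L
  add_link <- function(a, b, d) {
    # insert d-1 intermediates so each edge is one step
    chain <- hs$id[a]
    if (d > 1L) for (s in seq_len(d - 1L)) {
      n_inferred <<- n_inferred + 1L
      mv <- sprintf("mv%d", n_inferred)
      extra_nodes <<- c(extra_nodes, mv)
      edges <<- rbind(edges, data.frame(from = chain, to = mv))
      chain <- mv
    }
    edges <<- rbind(edges, data.frame(from = chain, to = hs$id[b]))
  }
  for (r in seq_len(nrow(cand))) {
    a <- cand[r, 1]; b <- cand[r, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      comp[ra] <- rb
      add_link(a, b, dm[a, b])
    } else if (retain_ties) {
      add_link(a, b, dm[a, b])
    }
  }
  comp_id <- vapply(seq_len(H), find, integer(1))
  pops <- setdiff(names(hs), c("id", "sequence", "frequency"))
  nodes <- data.frame(id = c(hs$id, extra_nodes),
                      frequency = c(hs$frequency, rep(0L,
                                                      length(extra_nodes))),
                      observed = c(rep(TRUE, H), rep(FALSE,
                                                     length(extra_nodes))),
                      stringsAsFactors = FALSE)
  for (p in pops)
    nodes[[p]] <- c(hs[[p]], rep(0L, length(extra_nodes)))
  structure(list(nodes = nodes, edges = edges, j95 = j95,
                 components = match(comp_id, unique(comp_id))),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("parsimony_network:", sum(x$nodes$observed), "haplotypes,",
      sum(!x$nodes$observed), "inferred intermediates,",
      nrow(x$edges), "edges, limit", x$j95, "steps,",
      length(unique(x$components)), "component(s)\n")
  invisible(x)
}

#' Write a parsimony network as node/edge TSV tables and DOT text
#'
#' @param net a `parsimony_network`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.dot`.
#' @return the DOT path, invisibly.
#' @export
write_network <- function(net, prefix) {
  utils::write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dot <- c("graph haplotype_network {",
           sprintf("  %s [label=\"%s (%d)\"%s];", net$nodes$id,
                   net$nodes$id, net$nodes$frequency,
                   ifelse(net$nodes$observed, "", " shape=point")),
           sprintf("  %s -- %s;", net$edges$from, net$edges$to),
           "}")
  writeLines(dot, paste0(prefix, ".dot"))
  invisible(paste0(prefix, ".dot"))
}
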