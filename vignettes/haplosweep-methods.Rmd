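---
title: "Methods: sweep detection and gene-flow analysis in haplosweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep detection and gene-flow analysis in haplosweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplosweep)
```

# Scope and model

haplosweep analyses per-locus multiple sequence alignments of phased
haplotypes, the typical product of amplicon resequencing of a candidate
region — here modelled on surveys of the *CYP6P9a* pyrethroid-resistance
locus and the surrounding *rp1* QTL region in *Anopheles funestus*. The
questions it addresses are: is diversity at a locus depressed in the way a
recent selective sweep predicts; how strongly are populations
differentiated and how much gene flow connects them; and how does the
sweep signal extend across a multi-locus region.

All statistics operate under **complete deletion**: any alignment column
containing a gap or an undetermined base (`N`, ambiguity codes) is excluded
from the diversity and neutrality statistics. Indel columns are tallied
separately and are never counted as SNPs; they re-enter only in the
haplotype network, where the gap is a fifth character state. Columns are
0-based half-open internally and 1-based inclusive in every report.

## Diversity statistics

For an alignment of $n$ sequences and $L_v$ valid sites:

* $k$ — mean number of pairwise differences, $\sum_{i<j} d_{ij} / \binom{n}{2}$;
* $\pi = k / L_v$ — nucleotide diversity per site;
* $S$ — segregating sites; a site with $a$ states carries $a-1$ mutations
  ($\eta$ in total), and mutations observed in exactly one sequence are
  singletons ($\eta_s$);
* $\theta_W = S / a_1$, $a_1 = \sum_{i=1}^{n-1} 1/i$ (per sequence);
* $h$, $H_d$ — haplotype count and diversity, with the unbiased estimator
  $H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$.

The $n/(n-1)$ correction and the plain $\binom{n}{2}$ denominator of $k$
were chosen because they reproduce published reference values exactly: a
19:1 haplotype split at $n = 20$ gives $H_d = 0.10$ and
$\pi = (19/190)/1139 = 0.00009$ at 1139 bp. Reports round $H_d$ to 2 and
$\pi$ to 5 decimals, matching the conventional table layout.

Sliding-window diversity uses windows of 400 bp advanced by 100 bp by
default (the convention for this locus size); window coordinates refer to
original alignment columns, and excluded columns inside a window shrink
that window's denominator rather than shifting the window.

## Neutrality tests

Tajima's D contrasts $k$ with $S/a_1$, normalised by the classical
variance chain ($b_1, b_2, c_1, c_2, e_1, e_2$). Fu and Li's D* is the
outgroup-free form with the *corrected* coefficient chain ($c_n$, $d_n$,
$u_{D^*}$, $v_{D^*}$); the uncorrected 1993 printing of $d_n$ does not
reproduce the reference values (−1.54 at $n=20$, −1.50 at $n=18$ for a
single singleton), the corrected one does, which fixed the choice.

Fu's FS uses the Ewens sampling formula. With $\hat\theta = k$ (per
sequence, not per site — the per-site variant does not reproduce the
reference values −0.88/−0.79), the probability of at least the observed
number of haplotypes is
$S' = \sum_{j \ge h_{obs}} \frac{|s(n,j)|\,\hat\theta^j}{\hat\theta^{(n)}}$,
with unsigned Stirling numbers of the first kind computed in log space
(stable to $n$ in the hundreds), and $F_S = \ln(S'/(1-S'))$.

Multi-allelic sites count $a - 1$ mutations each (an infinite-sites
reading of amplicon SNPs, so $\eta = S$ for biallelic data). D and D* are
undefined at $S = 0$ and FS at $k = 0$; reports print "-" there.

**Significance** is empirical: a seeded neutral coalescent null,
conditioned on the observed $S$ for D and D* (mutations placed on the
genealogy proportionally to branch length) and parameterised by
$\hat\theta$ for FS, with the $(\text{count}+1)/(n_{sims}+1)$ estimator;
two-tailed for D and D*, lower-tailed for FS with Fu's convention that the
5% level corresponds to empirical $P < 0.02$. DnaSP-style beta
approximations are not used, so stars can disagree with published tables
near thresholds.

## Codon-level selection (pN/pS)

Nei–Gojobori counting: every codon contributes fractional synonymous and
non-synonymous *site* counts (each of the nine single-base neighbours
weighs 1/3), averaged over all sequences of the sample — which is why
site totals are population-specific and fractional. Observed substitutions
are classified by amino-acid effect in codon context; codons with several
varying positions are averaged over all minimal mutational pathways
(avoiding stop-codon intermediates when possible). By default, mutations
creating stop codons are excluded from both numerator and site
denominator; `stop_mutations = "nonsynonymous"` switches to the
convention in which they count as non-synonymous sites (the printed
reference site totals, which sum to exactly $3 \times$ codons, are
consistent with the latter — the default follows the stricter exclusion
rule and the choice is documented per result). The ratio
$p_N/p_S = (n_{ns}/L_{ns})/(n_s/L_s)$ is undefined when there are no
synonymous substitutions.

## Population differentiation

$F_{ST}$ is the nucleotide-sequence form $1 - H_w/H_b$ (Hudson–Slatkin–
Maddison): $H_w$ the unweighted mean of the two within-population mean
pairwise difference counts, $H_b$ the between-population mean, over shared
valid sites. This family was fixed by the published pairing of
$F_{ST} = 0.02$ with $N_m = 10.87$, which is consistent with
$N_m = (1-F_{ST})/(4F_{ST})$.

The haplotype-level suite: $G_{ST}$ from haplotype heterozygosities
(unweighted deme means; Nei's unbiased correction switchable), $H_{ST}$
from sample-size-weighted unbiased heterozygosities, $K_{ST} = 1 - K_S/K_T$
on mean pairwise sequence differences (within, size-weighted, versus
pooled), and $N_{ST}$ — the $G_{ST}$ analogue with haplotype pairs
weighted by their nucleotide distance, so $N_{ST}$ significantly above
$G_{ST}$ indicates phylogeographic structure (similar haplotypes co-occur
geographically). The exact estimator variants used by legacy software are
not recoverable from published output; the implemented forms are
documented here and verified against brute-force enumeration, and
permutation significance shuffles population labels preserving sizes
(10,000 permutations by convention; ties count as exceedances,
$(m+1)/(n+1)$ estimator). Raw p-values are reported without
multiple-testing correction, matching the original analysis protocol.

## Haplotype networks

Haplotypes are collapsed on full sequences with the gap as a fifth state
(a 3-bp deletion is three one-step characters — the simplest reading of
"gaps as a fifth state"; missing-data columns are dropped). The
**connection limit** is the statistical-parsimony criterion: the largest
step count $j$ whose connection is non-homoplasious with probability at
least 0.95. The probability model is a per-site Poisson multiple-hit
argument with a 4-state correction: solving
$\mu = -\tfrac34\ln(1 - \tfrac43 q)$ for the per-site hit rate from the
observed difference fraction $q = j/m$, a $j$-step connection is
parsimonious when each differing site was hit exactly once
($[\mu e^{-\mu}/q]^j$) and no other site was hit invisibly
($[e^{-\mu}/(1-q)]^{m-j}$). For a 633-bp locus this gives a limit of 8
steps, in the range classical TCS software reports for amplicons of this
size. The network connects haplotype pairs in increasing distance order up
to the limit, inserting unobserved intermediate nodes so that every edge
is one mutational step; ties break by higher endpoint frequency then
lexicographic id, cycles are skipped by default (single spanning forest)
with `retain_ties = TRUE` keeping equal-distance alternatives for display.
Output is node/edge TSV plus DOT text; no graphics are rendered.

## Distance trees

Kimura 2-parameter distances
($d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$) feed neighbour-joining;
negative NJ branch lengths are clamped to zero with the deficit moved to
the sister branch. Bootstrap support resamples alignment columns (not
codons) and reports the percentage of replicates containing each internal
bipartition. Population trees use the pairwise Hudson $F_{ST}$ matrix with
negative estimates floored at zero. Maximum-likelihood inference and
substitution-model selection are deliberately out of scope; the NJ/K2
pathway is the implemented surface (HKY+G is not implemented).

# The synthetic-data generator

The generator exists so the full pipeline can run, and be tested, with no
external data. It emulates the *design* of the motivating survey:

* six loci at −34, −9, 0, +29, +61 and +86 kb from the focal gene, with
  the published fragment lengths (626–1139 bp);
* seven populations in two regional groups (four "southern", three
  "eastern/central"), 20 phased haplotypes per population;
* per-site $\theta$ = 0.004, inside the unswept per-site diversity range
  observed in the motivating survey (roughly 2 to 6.5 per mille in the
  central-African populations across the six loci); a higher $\theta$ also
  keeps mutational (Poisson) noise small relative to genealogical noise,
  which sharpens the regional diversity-ratio profile;
* within-group island-model migration $M = 25$, set from the finite-island
  approximation $F_{ST} \approx 1/(1 + M (d/(d-1))^2)$ to target
  within-group $F_{ST} \approx 0.02$;
* a two-epoch split between groups with no inter-group migration until
  `t_split` (in units of $2N$) — between-group $F_{ST} \approx t/(1+t)$,
  so the default 4 targets $\approx 0.8$, inside the strongly
  differentiated 0.5–0.97 regime. A deep split was chosen over calibrated
  low migration because it hits that regime robustly;
* a **star-genealogy partial sweep** in the swept group: a fraction $f$ of
  its sampled lineages coalesces instantly into one recent ancestor before
  neutral coalescence of the remainder. This is the limiting genealogy of
  a hard sweep and reproduces the targeted signature — depressed $\pi$ and
  $H_d$, negative Tajima's D, one dominant haplotype — without forward
  simulation;
* sweep strength decays with distance from the focal locus,
  $f(x) = f_0\, e^{-|x|/25\,\text{kb}}$ with $f_0 = 0.95$. The 25 kb scale
  is the sharp footprint of a strong recent sweep; it was chosen so that
  the focal locus is statistically distinguishable from its −9 kb
  neighbour in the diversity-ratio profile, which flatter footprints
  (e.g. a 75 kb scale) blur.

Mutations are infinite-sites, mapped to distinct uniform positions (a
finite-sites fallback with replacement engages, with a warning, only if
mutations exceed the locus length). Everything is seed-deterministic.

What the generator does **not** emulate: within-locus recombination,
direct sequencing artefacts or phasing error, varying sample sizes,
mutation-rate heterogeneity along the sequence, and indels (simulated
data are gap-free; the fifth-state network logic is exercised by
constructed fixtures instead). Passing tests therefore show that the
statistics and the scan behave correctly under a clean coalescent sweep
signal, not that the pipeline is robust to every artefact of real Sanger
data.

# The regional sweep scan

`per_locus_profile()` fills haplotype diversity, $\pi$ and Tajima's D for
every (locus, population) cell and computes, per locus, the ratio of
unweighted group means of per-population $\pi$ (comparison group over
reference group). The unweighted mean is the simplest reading of
"relative levels of diversity between regions"; a pooled-alignment
variant is available (`ratio_method = "pooled"`) since neither variant is
canonical. `sweep_report()` flags a (locus, group) pair as swept when the
group's mean $\pi$ and $H_d$ fall below configured quantiles (default
0.25) of the other groups' per-population values at that locus and the
group's mean D is below a configured ceiling (default −1.5); a
monomorphic group is always flagged. These thresholds are configuration,
not science — the motivating analyses make sweep calls qualitatively.

# Numerical choices and degenerate inputs

* Statistics undefined at zero polymorphism are `NA` internally, "-" or
  "n.a" in writers, never zero.
* $S' $ in FS is clamped away from 0 and 1 before the logit.
* Stirling numbers, Ewens probabilities and the parsimony probability are
  evaluated in log space.
* K2 saturation ($1-2P-Q \le 0$) is an error for a single pair; the
  bootstrap uses a per-pair p-distance fallback so a single saturated
  resample does not abort a replicate set.
* Permutation and coalescent p-values use the $(m+1)/(n+1)$ estimator, so
  they are never exactly zero.
* All stochastic entry points require an explicit seed; there is no
  silent clock seeding.

# Problem sizes used in the test suite

The suite calibrates the coalescent null with 2000 replicates at $n=20$,
$\theta=5$; checks sweep monotonicity with 500 replicates per sweep
strength; island-model $F_{ST}$ monotonicity with 500 replicates per
migration rate at 5+5 lineages; and the regional profile's focal-locus
peak and the neutral scan's false-positive rate with 20 full six-locus
datasets each at the generator defaults. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while keeping
the default test run desk-scale.

# Known limitations

* Statistical phasing is not implemented; `resolve_heterozygotes()` is a
  documented fallback (random split or masking), not a substitute for
  phase inference, and pipelines are expected to receive phased input.
* The coalescent null for significance ignores recombination and
  demography, like the classical table lookups it replaces.
* The Nei–Gojobori variant counts polymorphism, not divergence; no
  multiple-hit correction is applied to $p_N/p_S$.
* $N_{ST}/G_{ST}$ estimator variants differ across legacy software;
  absolute values may shift slightly between implementations even though
  orderings and significance behave the same.
* The sweep scan's $\pi$-ratio is a per-locus summary of single
  realisations; at these locus sizes its replicate-to-replicate
  variability is dominated by coalescent noise, which bounds how sharply
  any single dataset localises a sweep.
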