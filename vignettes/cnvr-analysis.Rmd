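---
title: "Methods: constructing and analysing copy number variable regions"
author: "cnvrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and analysing copy number variable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrtools)
```

# Scope and model

`cnvrtools` takes the *output* of a multi-sample read-depth CNV caller — one
row per sample-level call with an integer copy number — and carries out the
downstream population analysis: merging calls into copy number variable
regions (CNVRs), classifying and summarising them, annotating genes, and
asking three evolutionary questions about the genes they hit (selective
constraint, expression breadth, network centrality). Read mapping, the CNV
calling model itself, and quantification of expression data are explicitly
out of scope; their outputs are this package's inputs.

All intervals are held internally in 0-based half-open coordinates, so an
interval's length is always `end - start`. GFF3/GTF input (1-based
inclusive) is shifted on read; report TSVs display 1-based inclusive
coordinates to match Ensembl-style tables, and each writer states its
convention in a header comment. Strand is carried through gene tables but
ignored by every overlap computation: CNVRs are unstranded. Chromosome
names are matched as exact text; no `chr`-prefix normalisation is applied,
because silent renaming hides data errors.

# CNVR construction

Two intervals A and B sharing `o` bases have *reciprocal overlap*
`min(o/|A|, o/|B|)`; a pair qualifies for merging when this reaches the
threshold (default 0.5) — both intervals must be covered at least 50% by
the other. Merging is agglomerative and runs to a fixed point: while any
two current regions on one chromosome qualify, the qualifying pair with the
highest reciprocal overlap is merged into a region spanning from the
minimum start to the maximum end of its members. So for two calls with
`a < c < b < d` at sufficient overlap the resulting region runs from `a`
to `d`.

Two numerical choices matter here:

* **Which pair merges first.** Pairwise merging is not order-independent:
  with `[0,100)`, `[50,150)`, `[100,200)` at threshold 0.5, merging the left
  pair first strands the right interval and vice versa. The package always
  merges the *best* pair (highest reciprocal overlap, ties broken by
  leftmost and then shortest merged extent). This is deterministic,
  invariant to input order (calls are pre-sorted by chromosome, start, end,
  sample), idempotent on its own output, and reproduces the two-call
  example above exactly. The test suite checks equivalence against an
  independent brute-force implementation of the same rule on thousands of
  random instances.
* **Threshold comparison.** Overlap-versus-threshold tests use exact
  integer arithmetic (`o * q >= len * p` for a threshold `p/q`), so a pair
  at exactly 50% overlap merges regardless of floating-point
  representation.

Regions carried by fewer than `min_samples` distinct samples (default 3,
chosen as a small-population frequency filter against rare calls and
false positives) are set aside. Each surviving region is classified from
its member copy numbers against the chromosome's baseline: `loss` if all
members fall below, `gain` if all above, `mixed` if both directions occur.
Autosomes default to baseline 2 and the X chromosome to 1 — appropriate
for male mammalian samples, where a single-X call of copy number 1 is no
variant at all; a member call *equal* to baseline is treated as an input
error. Summaries report size statistics, the union ("unique") base count
via interval reduction, and the fraction of the genome covered.
Cross-study comparisons deliberately use a weaker rule — a region counts
as overlapped if it shares a single base with the reference set.

# Gene annotation and classes

A gene is a *CNV gene* iff it shares at least one base with a CNVR;
overlap is `complete` when the gene is contained in the union of the
CNVRs touching it, `partial` otherwise. Genes touched only by gain CNVRs
are *duplication* genes, only by loss CNVRs *deletion* genes, anything
else — a mixed CNVR, or both a pure gain and a pure loss — *mixed*. A gene
overlapped by one gain and one loss CNVR is deliberately classed mixed:
that is what "a mix of loss and gain" means at the gene level, even though
the convention is not forced by the region-level definition. All remaining
genes form the *neutral* complement used by every downstream contrast.

# Term over-representation

For a universe of `N` annotated genes, `K` of which carry a term, and a
query of `n` genes with `k` carriers, the expected count is `nK/N` and the
tail probability is binomial: `P(X >= k)` when `k` exceeds expectation
(over-representation, direction `+`), `P(X <= k)` otherwise (direction
`-`), with `X ~ Binomial(n, K/N)`. The universe is restricted to genes
with at least one annotation, and `n` counts only query genes inside that
universe — the headline numbers 19,879 and 89 in the classical cattle
analysis are of exactly this kind. Bonferroni multiplies by the number of
terms with `K >= 1` in the annotation set actually used (full GO and GO
slim analyses are run separately); the multiplier is recorded in the
output so results are auditable. Tails are computed by `pbinom`, which is
accurate far below the double-precision underflow of naive summation.

# Selective constraint (dN/dS)

For each ortholog pair the protocol is: translate both coding sequences
(standard code; terminal stop trimmed, internal stop an error, ambiguous
codons to `X`), align the proteins globally under BLOSUM50 with affine gap
penalties, copy each amino-acid gap back onto the nucleotides as a
three-base gap, and estimate rates from the codon alignment with the
Nei–Gojobori proportion method:

* the synonymous fraction of each codon position is the share of its three
  possible changes that preserve the amino acid, with stop-creating
  changes contributing to the nonsynonymous side; sites are averaged
  between the two sequences, so `S + N = 3 × codons` always holds;
* codons differing at 2–3 positions are scored by averaging synonymous and
  nonsynonymous steps over all minimal mutational pathways, discarding
  pathways that pass through a stop codon (in the vanishingly rare case
  that every pathway does, all are kept rather than losing the column);
* columns with gaps, ambiguity or stop codons are skipped;
* proportions are corrected for multiple hits with Jukes–Cantor,
  `d = -(3/4) ln(1 - (4/3) p)`. When `p >= 3/4` the logarithm is
  undefined — the pair is flagged *saturated* and removed before any
  contrast, since no sensible rate exists.

Gap penalties (open 10, extend 1) are fixed defaults, configurable;
ortholog alignments are insensitive to small changes here, but a fixed
value is required for determinism. The alignment's tie-breaking follows
the underlying dynamic program, which is deterministic for any input.
`omega = dN/dS` is undefined when both rates are 0, infinite when only
`dS` is, and both cases are excluded from rank tests. The class-versus-
neutral contrast is one-tailed (class shifted *higher*: relaxed
constraint).

The simulation used to validate the estimator evolves both lineages of
each pair from a common ancestor by proposal/acceptance: uniform
single-nucleotide proposals, stop-creating changes rejected, synonymous
changes always accepted, nonsynonymous accepted with probability `omega`.
The proposal count is calibrated so realised synonymous divergence matches
the target (default dS = 0.2, safely below saturation). Because proposals
that would create stops are rejected rather than redirected, the realised
nonsynonymous rate sits a few percent below `omega` times the synonymous
rate; median recovery within 15% of truth is the validated property, and
the acceptance checks measure exactly that at 200 pairs of 200 codons.

# Expression breadth and tissue specificity

Binary expression calls are platform-specific and strict: a gene is
expressed in a tissue if UPC > 0.5 (microarray) or FPKM/RPKM > 1.0
(RNA-seq) in *at least one* sample of that tissue — a value exactly at the
threshold does not qualify. Tissues assayed by two experiments are
combined by union after harmonising tissue labels through a synonym table
(unmappable labels are an error listing the offenders); breadth is the
number of tissues called expressed and can only grow as experiments are
added. A gene is *tissue-specific* iff its breadth is exactly 1 over the
analysed panel — the literature rarely pins this down, so the package
defines it explicitly and reports per-tissue counts of specific genes.
The breadth contrast includes only genes expressed somewhere and is
one-tailed (CNV genes expressed in *fewer* tissues). Breadth is computed
over the full panel for every gene, not per-gene subsets of usable
tissues.

The synthetic expression generator plants a breadth per gene (lower mean
for CNV genes, default 2 versus 10, matching the observed medians in the
motivating cattle data) and produces one five-tissue microarray experiment
and one RNA-seq experiment covering the rest of the 22-tissue panel plus
two shared tissues, so the union rule is genuinely exercised. It emulates
threshold-separable signal: expressed gene–tissue pairs always have a
clearly super-threshold sample and silent pairs never do. Real data are
noisier — borderline values, batch effects, missing tissues — so passing
tests demonstrate correct *bookkeeping*, not robustness of the thresholds
themselves.

# Network centrality

Edges are undirected; self-loops are removed and duplicate or reversed
pairs collapsed, so degree is the number of distinct interaction partners.
Confidence scores, if present, are ignored — no score threshold is
applied. Contrasts restrict both groups to genes with at least one
interaction and are one-tailed (class *less* central). The generator is a
configuration model with class-specific Poisson stub counts; discarded
self-loops and duplicates shave realised degrees slightly below target,
which is irrelevant to rank-based contrasts.

# The rank-sum test

All three contrasts share one implementation of the one-tailed Wilcoxon
rank-sum (Mann–Whitney) test. Within a pooled-size cutoff (default 12) the
p-value is exact: tie-free samples use the exact Mann–Whitney null
distribution, and tied samples a full enumeration of group assignments
over midranks (the exact permutation test — at these sizes the
normal approximation is badly calibrated for tied data). Above the cutoff,
the normal approximation with midranks, tie-corrected variance and a 0.5
continuity correction is used. Every result records the U statistic,
group sizes, method and group medians. Null calibration (rejection rate
0.05 ± 0.01 at `alpha = 0.05` over 10,000 replicates) is verified in the
acceptance suite.

# Synthetic study conditions

The generators default to the conditions used throughout the validation
suite: 50 samples, 100 planted CNVRs with a 30:16:11 loss/gain/mixed mix,
sizes log-uniform on 1.8 kb–1.56 Mb (the size range observed in the
motivating exome study), carrier counts skewed low with 15% of regions
planted below the 3-sample filter, 2,000 genes, a 22-tissue panel, and
endpoint jitter with sd 5% of region length clamped at ±25% — the clamp
guarantees every jittered call keeps ≥ 50% reciprocal overlap with its
planted region, which keeps the planted truth unambiguous. Planted regions
are spaced by at least the longest region length on each chromosome, so
truth regions cannot merge with each other; overlapping-truth scenarios
are a documented extension, not a default. These sizes keep the full
validation run within a few minutes on one CPU while leaving each
statistical check comfortably powered.

# Known limitations

* Merge semantics implement transitive agglomeration with a best-pair
  rule; a clique interpretation of "pairwise reciprocal overlap" (every
  member pair qualifying) would be stricter, and on a two-call instance
  the two coincide. The choice is recorded here because published
  descriptions of the rule rarely disambiguate it.
* Whether "present in at least 3 samples" counts samples or calls is
  ambiguous in most study descriptions; distinct samples are counted.
* Annotation-term enrichment takes the term-to-gene table as given
  (pre-propagated); no GO-graph propagation is performed.
* The dN/dS estimator is counting-based; maximum-likelihood codon models
  are out of scope.
* Gene classes are assigned from CNVR state, not from individual member
  calls.
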