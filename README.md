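# cnvrtools

Downstream population analysis of copy number variation from read-depth
CNV calls.

Copy number variations (CNVs) — gains and losses of large genomic
segments between individuals — are a major source of structural genetic
diversity, and in livestock genomics they are routinely called from exome
or genome read depth across many animals at once. `cnvrtools` picks up
where the caller stops: it takes a table of per-sample calls with integer
copy numbers and answers the population-level questions. Which regions of
the genome are recurrently variable? Which genes do they hit, and are
those genes functionally unusual, evolving faster, more narrowly
expressed, or less central in interaction networks than copy-number-
neutral genes? It is aimed at researchers running comparative or
population CNV studies who need the published analysis conventions as
tested, reusable code.

## What it computes

* **CNVR construction.** Calls are merged across samples into copy number
  variable regions (CNVRs) wherever two regions show at least 50% pairwise
  *reciprocal* overlap — for intervals A, B sharing o bases, the value
  min(o/|A|, o/|B|) — agglomerating best-pair-first to a deterministic
  fixed point. Regions carried by fewer than 3 distinct samples are
  filtered out; survivors are classified **loss** / **gain** / **mixed**
  against per-chromosome baseline copy numbers (2 for autosomes, 1 for a
  male X) and summarised (size range, mean/median, unique base coverage,
  genome fraction).
* **Gene annotation.** Genes sharing ≥ 1 base with a CNVR (completely or
  partially contained) are partitioned into duplication / deletion /
  mixed classes; everything else is the neutral comparison set.
* **Term enrichment.** Binomial over/under-representation of annotation
  terms: expected count nK/N, tail P(X ≥ k) or P(X ≤ k) with
  X ~ Binomial(n, K/N), Bonferroni-corrected over terms with K ≥ 1.
* **Selective constraint.** Per ortholog pair: translate, align proteins
  (BLOSUM50, affine gaps), project gaps to codons, then Nei–Gojobori
  counting with Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)·p);
  saturated pairs (p ≥ 3/4) are removed, and dN, dS and ω = dN/dS are
  contrasted class-versus-neutral with one-tailed Wilcoxon rank-sum
  tests.
* **Expression breadth.** Strict per-tissue calls (UPC > 0.5, FPKM/RPKM
  > 1.0 in ≥ 1 sample), union across experiments, breadth = number of
  expressed tissues, tissue-specific genes (breadth 1), one-tailed
  breadth contrast.
* **Network centrality.** Degree (distinct partners) from a cleaned
  undirected edge list; one-tailed degree contrasts restricted to genes
  with ≥ 1 interaction.
* **Synthetic data.** Generators for every input with machine-readable
  ground truth: jittered calls around planted CNVRs, codon pairs evolved
  at known ω, expression matrices with planted breadth, configuration-
  model networks.

## Worked example

A complete synthetic study: plant 100 CNVRs across 50 samples, merge and
filter, annotate 2,000 genes, and test whether CNV genes are expressed in
fewer tissues.

```r
library(cnvrtools)

genome <- simulate_genome()
sim <- simulate_cnv_calls(genome, n_samples = 50, n_cnvrs = 100, seed = 1)
cnvrs <- classify_states(merge_cnvs(sim$calls, threshold = 0.5), genome)
kept <- filter_by_frequency(cnvrs, min_samples = 3)$kept
kept
#> cnvr_set: 85 CNVR(s) from 469 call(s) in 50 sample(s)
#> state
#>  gain  loss mixed
#>    15    50    20
summarize_cnvrs(kept, genome)
#> 85 CNVR(s); sizes 2200-1.691e+06 bp (mean 2.509e+05, median 5.756e+04)
#> unique coverage 2.132e+07 bp (0.683% of genome)
```

85 of the 100 planted regions pass the 3-sample filter (15 were planted
rare on purpose); sizes and the loss-heavy state mix reflect the planted
configuration. Annotation and the breadth contrast:

```r
genes <- simulate_gene_models(genome, n_genes = 2000,
                              cnvr_truth = sim$truth, seed = 2)$genes
records <- partition_gene_classes(overlap_genes(kept, genes), kept)
table(records$gene_class)
#>    deletion duplication       mixed
#>          53          14          17
sets <- gene_class_sets(records, genes)

expr <- simulate_expression(genes$gene_id, cnv_genes = sets$cnv, seed = 3)
breadth <- combine_experiments(lapply(expr$experiments, call_expressed))
compare_breadth(breadth, sets$cnv)
#> Wilcoxon rank-sum (normal_approximation, one-tailed 'less'): U = 277.5, n = 84/1916, p = 7.542e-55
#> medians: 2 vs 10
```

The 84 expressed CNV genes have median breadth 2 against 10 for the 1,916
expressed neutral genes — the planted narrow-expression effect, recovered
with the one-tailed rank-sum test the pipeline uses for every contrast.
`run_pipeline(pipeline_config(...))` chains all of these stages from input
files and writes a TSV/JSON report bundle; see `?run_pipeline` and the
methods vignette (`vignettes/cnvr-analysis.Rmd`) for the full model
description and design rationale.

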