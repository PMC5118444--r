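# Builds a complete on-disk input bundle for run_pipeline() from the
# synthetic generators, planting expression and network effects on the CNV
# gene set the CNVR/gene stages will actually discover.
build_pipeline_fixture <- function(dir, seed = 1, n_samples = 20,
                                   n_cnvrs = 20, n_genes = 300,
                                   jitter_sd = 0.05, rare_fraction = 0.15,
                                   mean_breadth_cnv = 2,
                                   mean_breadth_neutral = 10,
                                   n_pairs_class = 12, n_pairs_neutral = 18,
                                   omega_cnv = 0.5, omega_neutral = 0.2,
                                   min_samples = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  g <- simulate_genome()
  write_genome_description(g, path("genome.tsv"))
  sim <- simulate_cnv_calls(g, n_samples = n_samples, n_cnvrs = n_cnvrs,
                            jitter_sd = jitter_sd,
                            rare_fraction = rare_fraction, seed = seed)
  write_cnv_calls(sim$calls, path("calls.tsv"))
  kept_truth <- sim$truth[sim$truth$n_carriers >= min_samples, , drop = FALSE]
  gm <- simulate_gene_models(g, n_genes = n_genes, cnvr_truth = kept_truth,
                             overlap_fraction = 0.15, seed = seed + 1)
  write_gene_models(gm$genes, path("genes.gff3"))

  # realized CNV gene set, as the pipeline will compute it
  cs <- filter_by_frequency(classify_states(merge_cnvs(sim$calls), g),
                            min_samples)$kept
  rec <- partition_gene_classes(overlap_genes(cs, gm$genes), cs)
  cnv_genes <- rec$gene_id
  neutral_genes <- setdiff(gm$genes$gene_id, cnv_genes)

  # annotation: random background terms over all genes
  set.seed(seed + 2)
  terms <- sprintf("GO:%04d", 1:15)
  t2g <- do.call(rbind, lapply(terms, function(t) {
    data.frame(term_id = t,
               gene_id = sample(gm$genes$gene_id,
                                sample(10:80, 1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(t2g, path("annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ex <- simulate_expression(gm$genes$gene_id, cnv_genes = cnv_genes,
                            mean_breadth_cnv = mean_breadth_cnv,
                            mean_breadth_neutral = mean_breadth_neutral,
                            seed = seed + 3)
  write_expression_experiment(ex$experiments[[1]], path("expr_micro.tsv"),
                              path("expr_micro_manifest.tsv"))
  write_expression_experiment(ex$experiments[[2]], path("expr_rna.tsv"),
                              path("expr_rna_manifest.tsv"))

  net <- simulate_ppi(gm$genes$gene_id, low_degree_genes = cnv_genes,
                      seed = seed + 4)
  utils::write.table(net$edges, path("edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pc <- simulate_ortholog_pairs(n_pairs = n_pairs_class, n_codons = 120,
                                omega = omega_cnv, seed = seed + 5)
  pn <- simulate_ortholog_pairs(n_pairs = n_pairs_neutral, n_codons = 120,
                                omega = omega_neutral, seed = seed + 6)
  n_c <- min(n_pairs_class, length(cnv_genes))
  n_n <- min(n_pairs_neutral, length(neutral_genes))
  pairs <- rbind(pc$pairs[seq_len(n_c), , drop = FALSE],
                 pn$pairs[seq_len(n_n), , drop = FALSE])
  pairs$gene_id <- c(cnv_genes[seq_len(n_c)], neutral_genes[seq_len(n_n)])
  write_ortholog_pairs(pairs, path("orth_query.fa"), path("orth_subject.fa"))

  config <- pipeline_config(
    out_dir = file.path(dir, "out"),
    genome = path("genome.tsv"),
    cnv_calls = path("calls.tsv"),
    gene_models = path("genes.gff3"),
    annotation = path("annotation.tsv"),
    ortholog_query = path("orth_query.fa"),
    ortholog_subject = path("orth_subject.fa"),
    expression = list(
      list(matrix = path("expr_micro.tsv"),
           manifest = path("expr_micro_manifest.tsv"),
           experiment_id = "EXP_MICRO", platform = "microarray_upc"),
      list(matrix = path("expr_rna.tsv"),
           manifest = path("expr_rna_manifest.tsv"),
           experiment_id = "EXP_RNA", platform = "rnaseq_fpkm")),
    edges = path("edges.tsv"),
    min_samples = min_samples,
    seed = seed)
  list(config = config, genome = g, cnvr_truth = sim$truth,
       gene_truth = gm$truth, expression_truth = ex$truth,
       ppi_truth = net$truth, cnv_genes = cnv_genes)
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  setNames(tools::md5sum(files), basename(files))
}
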