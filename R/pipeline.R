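# End-to-end orchestration: read inputs, construct CNVRs, annotate genes,
# run the enrichment / constraint / breadth / centrality analyses, and write
# a reproducible report bundle. Every stage is a pure function of its inputs
# and the resolved configuration, which is written alongside the outputs.

#' Assemble a pipeline configuration
#'
#' Defaults mirror the standard analysis settings: 50% reciprocal overlap,
#' a 3-sample frequency filter, UPC > 0.5 and FPKM/RPKM > 1.0 expression
#' calls, and BLOSUM50 alignment with gap open 10 / extend 1.
#'
#' @param out_dir output directory (created if needed).
#' @param genome path to a genome description TSV
#'   ([read_genome_description()]).
#' @param cnv_calls path to a CNV call table ([read_cnv_calls()]).
#' @param cnv_calls_dialect `"tsv_with_header"` or `"bed_like"`.
#' @param gene_models path to GFF3/GTF/BED gene models.
#' @param annotation,annotation_meta term-to-gene TSV and optional term
#'   metadata TSV ([read_annotation_table()]).
#' @param ortholog_query,ortholog_subject paired FASTA files
#'   ([read_ortholog_pairs()]).
#' @param expression list of experiment descriptors, each a list with
#'   `matrix`, `manifest`, `experiment_id`, `platform`.
#' @param tissue_synonyms optional TSV with columns `raw`, `canonical`.
#' @param edges path to an interaction edge-list TSV ([read_edge_list()]).
#' @param stages character vector of enabled stages among `"cnvr"`,
#'   `"genes"`, `"enrichment"`, `"dnds"`, `"breadth"`, `"network"`.
#' @param overlap_threshold reciprocal-overlap threshold; default 0.5.
#' @param min_samples CNVR frequency filter; default 3.
#' @param upc_threshold,fpkm_threshold expression calling thresholds.
#' @param gap_open,gap_extend protein-alignment gap penalties.
#' @param seed seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            genome,
                            cnv_calls = NULL,
                            cnv_calls_dialect = "tsv_with_header",
                            gene_models = NULL,
                            annotation = NULL,
                            annotation_meta = NULL,
                            ortholog_query = NULL,
                            ortholog_subject = NULL,
                            expression = NULL,
                            tissue_synonyms = NULL,
                            edges = NULL,
                            stages = c("cnvr", "genes", "enrichment",
                                       "dnds", "breadth", "network"),
                            overlap_threshold = 0.5,
                            min_samples = 3L,
                            upc_threshold = 0.5,
                            fpkm_threshold = 1.0,
                            gap_open = 10,
                            gap_extend = 1,
                            seed = 1L) {
  structure(list(out_dir = out_dir, genome = genome, cnv_calls = cnv_calls,
                 cnv_calls_dialect = cnv_calls_dialect,
                 gene_models = gene_models, annotation = annotation,
                 annotation_meta = annotation_meta,
                 ortholog_query = ortholog_query,
                 ortholog_subject = ortholog_subject,
                 expression = expression,
                 tissue_synonyms = tissue_synonyms, edges = edges,
                 stages = stages, overlap_threshold = overlap_threshold,
                 min_samples = min_samples, upc_threshold = upc_threshold,
                 fpkm_threshold = fpkm_threshold, gap_open = gap_open,
                 gap_extend = gap_extend, seed = seed),
            class = "pipeline_config")
}

validate_pipeline_inputs <- function(config) {
  need <- function(stage, paths, what) {
    if (!stage %in% config$stages) return(invisible())
    for (p in paths) {
      if (is.null(p)) {
        stop("stage '", stage, "' enabled but ", what, " not configured")
      }
      if (!file.exists(p)) {
        stop("stage '", stage, "' input missing: ", p)
      }
    }
  }
  if (!file.exists(config$genome)) stop("genome description missing: ",
                                        config$genome)
  need("cnvr", list(config$cnv_calls), "cnv_calls")
  need("genes", list(config$gene_models), "gene_models")
  need("enrichment", list(config$annotation), "annotation")
  need("dnds", list(config$ortholog_query, config$ortholog_subject),
       "ortholog FASTA pair")
  if ("breadth" %in% config$stages) {
    if (is.null(config$expression) || !length(config$expression)) {
      stop("stage 'breadth' enabled but no expression experiments configured")
    }
    for (e in config$expression) {
      need("breadth", list(e$matrix, e$manifest), "expression experiment")
    }
  }
  need("network", list(config$edges), "edges")
  deps <- c(genes = "cnvr", enrichment = "genes", dnds = "genes",
            breadth = "genes", network = "genes")
  for (s in intersect(names(deps), config$stages)) {
    if (!deps[[s]] %in% config$stages) {
      stop("stage '", s, "' requires stage '", deps[[s]], "'")
    }
  }
  invisible()
}

contrast_row <- function(label, statistic, rs) {
  data.frame(contrast = label, statistic = statistic,
             median_group = rs$median_x, median_neutral = rs$median_y,
             U = rs$U, n_group = rs$n1, n_neutral = rs$n2,
             method = rs$method, p_one_tailed = rs$p_one_tailed,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the CNVR analysis pipeline
#'
#' Executes the enabled stages in order — CNVR construction, gene
#' annotation, term enrichment, selective constraint, expression breadth,
#' network centrality — writing a TSV report per stage plus the resolved
#' configuration (`run_config.json`) and a run log into
#' `config$out_dir`. Inputs are validated before any computation. Outputs
#' are deterministic: re-running an identical configuration reproduces the
#' report byte for byte.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(paste("cnvrtools", as.character(utils::packageVersion("cnvrtools"))),
                 paste("seed:", config$seed),
                 paste("stages:", paste(config$stages, collapse = ", ")),
                 paste("overlap_threshold:", config$overlap_threshold),
                 paste("min_samples:", config$min_samples))
  out <- function(name) file.path(config$out_dir, name)
  report <- list()

  genome <- read_genome_description(config$genome)
  report$genome <- genome

  if ("cnvr" %in% config$stages) {
    calls <- read_cnv_calls(config$cnv_calls, config$cnv_calls_dialect)
    merged <- merge_cnvs(calls, config$overlap_threshold)
    merged <- classify_states(merged, genome)
    flt <- filter_by_frequency(merged, config$min_samples)
    cnvr_set <- flt$kept
    log_lines <- c(log_lines,
                   sprintf("cnvr: %d calls -> %d regions; %d removed by the %d-sample filter, %d kept",
                           nrow(calls), nrow(merged$cnvrs),
                           nrow(flt$removed$cnvrs), config$min_samples,
                           nrow(cnvr_set$cnvrs)))
    write_cnvr_report(cnvr_set, out("cnvrs.tsv"), out("cnvrs.bed"))
    summ <- summarize_cnvrs(cnvr_set, genome)
    write_tsv(data.frame(
      count = summ$count, min_size = summ$min_size,
      max_size = summ$max_size, mean_size = summ$mean_size,
      median_size = summ$median_size, total_unique = summ$total_unique,
      genome_fraction = summ$genome_fraction,
      n_loss = summ$state_counts[["loss"]],
      n_gain = summ$state_counts[["gain"]],
      n_mixed = summ$state_counts[["mixed"]]),
      out("cnvr_summary.tsv"), "sizes in bases")
    report$cnvrs <- cnvr_set
    report$removed_cnvrs <- flt$removed
    report$summary <- summ
  }

  sets <- NULL
  if ("genes" %in% config$stages) {
    genes <- read_gene_models(config$gene_models)
    records <- overlap_genes(report$cnvrs, genes)
    records <- partition_gene_classes(records, report$cnvrs)
    sets <- gene_class_sets(records, genes)
    log_lines <- c(log_lines,
                   sprintf("genes: %d CNV gene(s) of %d (%d duplication, %d deletion, %d mixed)",
                           nrow(records), nrow(genes),
                           length(sets$duplication), length(sets$deletion),
                           length(sets$mixed)))
    write_tsv(records, out("cnv_genes.tsv"))
    report$genes <- genes
    report$cnv_gene_records <- records
    report$gene_sets <- sets
  }

  if ("enrichment" %in% config$stages) {
    ann <- read_annotation_table(config$annotation, config$annotation_meta)
    coding <- report$genes$gene_id[report$genes$biotype %in%
                                     c("protein_coding", "unknown")]
    enr_sets <- list(cnv = sets$cnv, duplication = sets$duplication,
                     deletion = sets$deletion, mixed = sets$mixed)
    report$enrichment <- list()
    for (nm in names(enr_sets)) {
      q <- intersect(enr_sets[[nm]], coding)
      if (!length(intersect(q, unique(ann$term2gene$gene_id)))) {
        log_lines <- c(log_lines, sprintf(
          "enrichment: class '%s' has no annotated genes; skipped", nm))
        next
      }
      res <- binomial_enrichment(q, ann)
      write_tsv(res, out(sprintf("enrichment_%s.tsv", nm)))
      report$enrichment[[nm]] <- res
    }
  }

  if ("dnds" %in% config$stages) {
    pairs <- read_ortholog_pairs(config$ortholog_query,
                                 config$ortholog_subject)
    res <- dnds_pairs(pairs, config$gap_open, config$gap_extend)
    usable <- filter_saturated(res)
    log_lines <- c(log_lines,
                   sprintf("dnds: %d pair(s), %d saturated/undefined removed",
                           nrow(res), nrow(res) - nrow(usable)))
    write_tsv(res, out("dnds_results.tsv"))
    neutral <- usable[usable$gene_id %in% sets$neutral, , drop = FALSE]
    rows <- list()
    for (nm in c("cnv", "duplication", "deletion", "mixed")) {
      grp <- usable[usable$gene_id %in% sets[[nm]], , drop = FALSE]
      for (stat in c("dN", "dS", "omega")) {
        if (!nrow(grp) || !nrow(neutral)) next
        rs <- try(compare_constraint(grp, neutral, stat), silent = TRUE)
        if (inherits(rs, "try-error")) next
        rows[[length(rows) + 1]] <- contrast_row(nm, stat, rs)
      }
    }
    contrasts <- do.call(rbind, rows)
    if (!is.null(contrasts)) {
      write_tsv(contrasts, out("dnds_contrasts.tsv"),
                "one-tailed rank-sum, alternative: class > neutral")
    }
    report$dnds <- res
    report$dnds_contrasts <- contrasts
  }

  if ("breadth" %in% config$stages) {
    experiments <- lapply(config$expression, function(e) {
      read_expression_experiment(e$matrix, e$manifest, e$experiment_id,
                                 e$platform)
    })
    callsets <- lapply(experiments, call_expressed,
                       upc_threshold = config$upc_threshold,
                       fpkm_threshold = config$fpkm_threshold)
    synonyms <- if (!is.null(config$tissue_synonyms)) {
      utils::read.table(config$tissue_synonyms, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else NULL
    callset <- combine_experiments(callsets, synonyms)
    write_tsv(data.frame(gene_id = names(callset$breadth),
                         breadth = callset$breadth),
              out("expression_breadth.tsv"))
    counts <- tissue_specific_counts(callset, sets$cnv)
    write_tsv(counts, out("tissue_specific_counts.tsv"))
    rs <- compare_breadth(callset, sets$cnv)
    write_tsv(contrast_row("cnv", "breadth", rs), out("breadth_contrast.tsv"),
              "one-tailed rank-sum, alternative: CNV < neutral")
    log_lines <- c(log_lines,
                   sprintf("breadth: medians %g (CNV) vs %g (neutral), p = %.3g",
                           rs$median_x, rs$median_y, rs$p_one_tailed))
    report$breadth <- callset
    report$tissue_specific <- counts
    report$breadth_contrast <- rs
  }

  if ("network" %in% config$stages) {
    edges <- read_edge_list(config$edges)
    degrees <- compute_degrees(edges)
    write_tsv(data.frame(gene_id = names(degrees), degree = degrees),
              out("degrees.tsv"))
    rows <- list()
    for (nm in c("cnv", "duplication", "deletion", "mixed")) {
      rs <- try(compare_centrality(sets[[nm]], sets$neutral, degrees),
                silent = TRUE)
      if (inherits(rs, "try-error")) next
      rows[[length(rows) + 1]] <- contrast_row(nm, "degree", rs)
    }
    contrasts <- do.call(rbind, rows)
    if (!is.null(contrasts)) {
      write_tsv(contrasts, out("centrality_contrasts.tsv"),
                "restricted to degree >= 1; alternative: class < neutral")
    }
    report$degrees <- degrees
    report$centrality_contrasts <- contrasts
  }

  jsonlite::write_json(unclass(config), out("run_config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  writeLines(log_lines, out("run_log.txt"))
  report$log <- log_lines
  invisible(report)
}
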