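# Synthetic inputs with known ground truth for every stage of the pipeline:
# jittered multi-sample CNV calls around planted CNVRs, gene models, codon
# pairs evolved at a known dN/dS, expression matrices with planted broad and
# tissue-specific genes, and interaction networks with class-specific degree
# distributions. Each generator seeds R's RNG from its `seed` argument, so a
# fixed seed reproduces outputs exactly.

#' Default synthetic genome
#'
#' 29 autosomes with lengths decreasing from 160 Mb to 45 Mb plus a 149 Mb X
#' chromosome, loosely shaped like a bovine karyotype. Baselines are 2 for
#' autosomes and 1 for X (male samples).
#'
#' @param n_autosomes number of autosomes; default 29.
#' @param include_x add an X chromosome; default TRUE.
#' @return A genome description `data.frame`.
#' @export
simulate_genome <- function(n_autosomes = 29, include_x = TRUE) {
  lens <- round(seq(1.6e8, 4.5e7, length.out = n_autosomes))
  chrom <- paste0("chr", seq_len(n_autosomes))
  if (include_x) {
    chrom <- c(chrom, "chrX")
    lens <- c(lens, 1.49e8)
  }
  genome_description(chrom, lens)
}

#' Simulate per-sample CNV calls around planted CNVRs
#'
#' Regions are placed on chromosomes (probability proportional to length)
#' with large buffers between neighbours so that the planted truth is
#' unambiguous. Each region gets a state (loss/gain/mixed) and a number of
#' carrier samples; every carrier contributes one call whose endpoints are
#' jittered by a truncated normal (sd = `jitter_sd` x region length, clamped
#' to a quarter of the length per endpoint, which keeps the reciprocal
#' overlap between any call and its region at >= 0.5 by construction).
#' A `rare_fraction` of regions receives fewer than `min_carriers` carriers
#' to exercise the downstream frequency filter.
#'
#' @param genome genome description.
#' @param n_samples number of samples; default 50.
#' @param n_cnvrs number of planted regions; default 100.
#' @param size_range region length range in bases, drawn log-uniformly;
#'   default 1.8 kb to 1.56 Mb.
#' @param jitter_sd endpoint jitter as a fraction of region length;
#'   default 0.05.
#' @param state_props named proportions for loss/gain/mixed; default
#'   30:16:11.
#' @param min_carriers minimum carriers for a common region; default 3.
#' @param carrier_geom_prob geometric parameter for extra carriers beyond
#'   `min_carriers` (smaller = more carriers); default 0.3.
#' @param rare_fraction fraction of regions planted below `min_carriers`;
#'   default 0.15.
#' @param seed RNG seed (required).
#' @return List with `calls` (CNV call data.frame) and `truth` (data.frame
#'   `cnvr_id`, `chrom`, `start`, `end`, `state`, `n_carriers`).
#' @export
simulate_cnv_calls <- function(genome, n_samples = 50, n_cnvrs = 100,
                               size_range = c(1800, 1.56e6),
                               jitter_sd = 0.05,
                               state_props = c(loss = 30, gain = 16,
                                               mixed = 11),
                               min_carriers = 3, carrier_geom_prob = 0.3,
                               rare_fraction = 0.15, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  stopifnot(jitter_sd >= 0, n_cnvrs >= 1, n_samples >= 1)
  state_props <- state_props / sum(state_props)
  sizes <- round(exp(stats::runif(n_cnvrs, log(size_range[1]),
                                  log(size_range[2]))))
  chrom <- sample(genome$chrom, n_cnvrs, replace = TRUE,
                  prob = genome$length)
  truth <- NULL
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    L <- genome$length[genome$chrom == chr]
    lens <- sizes[idx]
    buffer <- max(lens)
    need <- sum(lens) + (length(lens) + 1) * buffer
    if (need > L) {
      stop("infeasible spacing: ", length(lens), " region(s) of total ",
           sum(lens), " bases do not fit on ", chr, " with buffers")
    }
    extra <- sort(stats::runif(length(lens), 0, L - need))
    starts <- numeric(length(lens))
    pos <- buffer
    for (i in seq_along(lens)) {
      starts[i] <- round(pos + extra[i])
      pos <- pos + lens[i] + buffer
    }
    truth <- rbind(truth, data.frame(chrom = chr, start = starts,
                                     end = starts + lens,
                                     stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  truth$cnvr_id <- paste0("TRUE_", seq_len(nrow(truth)))
  truth$state <- sample(names(state_props), nrow(truth), replace = TRUE,
                        prob = state_props)
  n_rare <- round(rare_fraction * nrow(truth))
  rare <- sample(nrow(truth), n_rare)
  carriers <- pmin(min_carriers +
                     stats::rgeom(nrow(truth), carrier_geom_prob),
                   n_samples)
  carriers[rare] <- sample(seq_len(max(1, min_carriers - 1)), n_rare,
                           replace = TRUE)
  # a mixed region needs carriers in both directions
  truth$state[truth$state == "mixed" & carriers < 2] <- "loss"
  truth$n_carriers <- carriers
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  calls <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    baseline <- genome$expected_copy_number[genome$chrom == truth$chrom[i]]
    len <- truth$end[i] - truth$start[i]
    who <- sample(sample_ids, truth$n_carriers[i])
    bound <- floor(len / 4)
    d1 <- pmax(-bound, pmin(bound, round(stats::rnorm(length(who), 0,
                                                      jitter_sd * len))))
    d2 <- pmax(-bound, pmin(bound, round(stats::rnorm(length(who), 0,
                                                      jitter_sd * len))))
    dir <- switch(truth$state[i],
                  loss = rep("loss", length(who)),
                  gain = rep("gain", length(who)),
                  mixed = {
                    d <- sample(c("loss", "gain"), length(who),
                                replace = TRUE)
                    d[1] <- "loss"; d[2] <- "gain"
                    d
                  })
    # copy numbers are relative to the chromosome baseline (1 on a male X)
    lo_vals <- seq(0, baseline - 1)
    cn <- ifelse(dir == "loss",
                 lo_vals[sample.int(length(lo_vals), length(who),
                                    replace = TRUE)],
                 baseline + sample.int(3, length(who), replace = TRUE))
    calls[[i]] <- data.frame(
      sample = who, chrom = truth$chrom[i],
      start = pmax(0, truth$start[i] + d1),
      end = truth$end[i] + d2,
      copy_number = as.integer(cn),
      true_cnvr = truth$cnvr_id[i], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  list(calls = sort_cnv_calls(calls),
       truth = truth[, c("cnvr_id", "chrom", "start", "end", "state",
                         "n_carriers")])
}

#' Simulate gene models, some overlapping planted CNVRs
#'
#' @param genome genome description.
#' @param n_genes number of genes; default 2000.
#' @param cnvr_truth optional planted-region truth from
#'   [simulate_cnv_calls()]; when given, `overlap_fraction` of the genes are
#'   placed inside (or straddling) planted regions and the rest are kept
#'   clear of them.
#' @param overlap_fraction fraction of genes placed on planted regions;
#'   default 0.05.
#' @param size_range gene length range in bases; default 5-100 kb.
#' @param biotype_props biotype proportions, mirroring a mostly
#'   protein-coding annotation.
#' @param seed RNG seed (required).
#' @return List with `genes` (gene-model data.frame) and `truth`
#'   (data.frame `gene_id`, `on_cnvr`).
#' @export
simulate_gene_models <- function(genome, n_genes = 2000, cnvr_truth = NULL,
                                 overlap_fraction = 0.05,
                                 size_range = c(5e3, 1e5),
                                 biotype_props = c(protein_coding = 0.87,
                                                   snRNA = 0.06,
                                                   pseudogene = 0.06,
                                                   rRNA = 0.01),
                                 seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n_on <- if (is.null(cnvr_truth)) 0L else round(overlap_fraction * n_genes)
  lens <- round(stats::runif(n_genes, size_range[1], size_range[2]))
  chrom <- character(n_genes)
  start <- numeric(n_genes)
  if (n_on > 0) {
    host <- sample(nrow(cnvr_truth), n_on, replace = TRUE)
    for (j in seq_len(n_on)) {
      h <- cnvr_truth[host[j], ]
      # place the gene around a point inside the region; long genes straddle
      anchor <- round(stats::runif(1, h$start, h$end))
      start[j] <- max(0, anchor - round(lens[j] / 2))
      chrom[j] <- h$chrom
    }
  }
  tgr <- if (!is.null(cnvr_truth) && nrow(cnvr_truth)) {
    GenomicRanges::GRanges(factor(cnvr_truth$chrom, genome$chrom),
                           IRanges::IRanges(cnvr_truth$start + 1,
                                            cnvr_truth$end))
  } else NULL
  for (j in seq(n_on + 1, length.out = n_genes - n_on)) {
    repeat {
      chr <- sample(genome$chrom, 1, prob = genome$length)
      L <- genome$length[genome$chrom == chr]
      s <- round(stats::runif(1, 0, L - lens[j]))
      if (is.null(tgr)) break
      g <- GenomicRanges::GRanges(factor(chr, genome$chrom),
                                  IRanges::IRanges(s + 1, s + lens[j]))
      if (!length(GenomicRanges::findOverlaps(g, tgr))) break
    }
    chrom[j] <- chr
    start[j] <- s
  }
  genes <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_genes)),
    chrom = chrom, start = start, end = start + lens,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    biotype = sample(names(biotype_props), n_genes, replace = TRUE,
                     prob = biotype_props),
    stringsAsFactors = FALSE)
  list(genes = genes,
       truth = data.frame(gene_id = genes$gene_id,
                          on_cnvr = seq_len(n_genes) <= n_on,
                          stringsAsFactors = FALSE))
}

# one round of proposal/acceptance codon evolution
evolve_codons <- function(codons, n_proposals, omega, code) {
  n_syn <- 0L
  n_nonsyn <- 0L
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_proposals)) {
    ci <- sample.int(length(codons), 1)
    pos <- sample.int(3, 1)
    cdn <- strsplit(codons[ci], "")[[1]]
    alt <- cdn
    alt[pos] <- sample(setdiff(bases, cdn[pos]), 1)
    alt_codon <- paste(alt, collapse = "")
    if (code[alt_codon] == "*") next  # stop-creating change rejected
    if (code[alt_codon] == code[codons[ci]]) {
      codons[ci] <- alt_codon
      n_syn <- n_syn + 1L
    } else if (stats::runif(1) < omega) {
      codons[ci] <- alt_codon
      n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(codons = codons, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate ortholog coding-sequence pairs at a known dN/dS
#'
#' Each pair descends from a common ancestor of `n_codons` sense codons
#' drawn uniformly. Both lineages evolve by a proposal/acceptance scheme:
#' single-nucleotide changes are proposed uniformly, stop-creating changes
#' are rejected, synonymous changes are accepted with probability 1 and
#' nonsynonymous changes with probability `omega`. The number of proposals
#' is calibrated so that realized synonymous divergence matches `target_ds`
#' (kept below saturation).
#'
#' @param n_pairs number of pairs; default 200.
#' @param n_codons codons per sequence; default 200.
#' @param omega true dN/dS; default 0.25.
#' @param target_ds target synonymous divergence per site; default 0.2.
#' @param seed RNG seed (required).
#' @return List with `pairs` (data.frame `gene_id`, `query_cds`,
#'   `ortholog_cds`) and `truth` (data.frame `gene_id`, `omega`,
#'   `n_syn_subs`, `n_nonsyn_subs`).
#' @export
simulate_ortholog_pairs <- function(n_pairs = 200, n_codons = 200,
                                    omega = 0.25, target_ds = 0.2, seed) {
  if (missing(seed)) stop("seed is required")
  if (target_ds >= 0.5) stop("target_ds must stay well below saturation")
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  # proposals per lineage so that realized pS ~ target: pS ~ n_prop / (3L)
  p_target <- 3 / 4 * (1 - exp(-4 / 3 * target_ds))
  n_prop <- round(p_target * 3 * n_codons / 2)
  pairs <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    e1 <- evolve_codons(anc, n_prop, omega, code)
    e2 <- evolve_codons(anc, n_prop, omega, code)
    id <- sprintf("PAIR%04d", i)
    pairs[[i]] <- data.frame(gene_id = id,
                             query_cds = paste(e1$codons, collapse = ""),
                             ortholog_cds = paste(e2$codons, collapse = ""),
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(gene_id = id, omega = omega,
                             n_syn_subs = e1$n_syn + e2$n_syn,
                             n_nonsyn_subs = e1$n_nonsyn + e2$n_nonsyn,
                             stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, pairs), truth = do.call(rbind, truth))
}

#' Default 22-tissue panel
#'
#' @return Character vector of tissue names used by the expression
#'   generator.
#' @export
default_tissue_panel <- function() {
  c("mesenteric_fat", "spleen", "duodenum", "jejunum", "ileum", "brain",
    "colon", "heart", "kidney", "liver", "lung", "skeletal_muscle",
    "testes", "hypothalamus", "pituitary_gland", "uterus", "endometrium",
    "ovary", "subcutaneous_fat", "longissimus_dorsi_muscle", "rumen",
    "adipose")
}

#' Simulate expression matrices with planted breadth
#'
#' Two experiments are produced: a microarray (UPC) experiment covering five
#' tissues and an RNA-seq (FPKM) experiment covering the remaining tissues
#' plus two shared ones (spleen, duodenum), exercising the cross-experiment
#' union. Every gene gets a planted breadth (1 + Poisson, clamped to the
#' panel) drawn with a lower mean for `cnv_genes` than for the rest; its
#' expressed tissues are chosen at random. Expressed gene-tissue pairs get
#' at least one sample above the calling threshold, silent pairs stay below
#' in every sample.
#'
#' @param gene_ids character vector of gene ids.
#' @param cnv_genes subset of `gene_ids` planted with narrow expression.
#' @param tissues tissue panel; default [default_tissue_panel()].
#' @param mean_breadth_cnv,mean_breadth_neutral planted mean breadths;
#'   defaults 2 and 10.
#' @param n_samples_per_tissue samples per tissue per experiment; default 3.
#' @param seed RNG seed (required).
#' @return List with `experiments` (list of `expression_experiment`) and
#'   `truth` (data.frame `gene_id`, `breadth`, `tissues` semicolon-joined).
#' @export
simulate_expression <- function(gene_ids, cnv_genes = character(),
                                tissues = default_tissue_panel(),
                                mean_breadth_cnv = 2,
                                mean_breadth_neutral = 10,
                                n_samples_per_tissue = 3, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- length(gene_ids)
  is_cnv <- gene_ids %in% cnv_genes
  mean_b <- ifelse(is_cnv, mean_breadth_cnv, mean_breadth_neutral)
  breadth <- pmin(length(tissues),
                  1L + stats::rpois(n, pmax(0, mean_b - 1)))
  planted <- lapply(seq_len(n), function(i) sample(tissues, breadth[i]))
  micro_tissues <- intersect(c("mesenteric_fat", "spleen", "duodenum",
                               "jejunum", "ileum"), tissues)
  rna_tissues <- union(setdiff(tissues, micro_tissues),
                       intersect(c("spleen", "duodenum"), tissues))
  make_experiment <- function(id, platform, exp_tissues) {
    ncol_total <- length(exp_tissues) * n_samples_per_tissue
    tissue_of <- rep(exp_tissues, each = n_samples_per_tissue)
    if (platform == "microarray_upc") {
      vals <- matrix(stats::runif(n * ncol_total, 0, 0.45), n, ncol_total)
    } else {
      vals <- matrix(stats::runif(n * ncol_total, 0, 0.9), n, ncol_total)
    }
    for (i in seq_len(n)) {
      for (t in intersect(planted[[i]], exp_tissues)) {
        cols <- which(tissue_of == t)
        hot <- sample(cols, 1)
        vals[i, hot] <- if (platform == "microarray_upc") {
          stats::runif(1, 0.55, 1)
        } else {
          10^stats::runif(1, 0.1, 2.5)
        }
      }
    }
    rownames(vals) <- gene_ids
    colnames(vals) <- sprintf("%s_%s_r%d", id, tissue_of,
                              rep(seq_len(n_samples_per_tissue),
                                  times = length(exp_tissues)))
    expression_experiment(id, platform, vals, tissue_of)
  }
  experiments <- list(
    make_experiment("EXP_MICRO", "microarray_upc", micro_tissues),
    make_experiment("EXP_RNA", "rnaseq_fpkm", rna_tissues))
  truth <- data.frame(
    gene_id = gene_ids, breadth = breadth,
    tissues = vapply(planted, function(t) paste(sort(t), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  list(experiments = experiments, truth = truth)
}

#' Simulate an interaction network with class-specific degrees
#'
#' Configuration-model style: each gene receives a Poisson stub count with a
#' class-specific mean, stubs are paired uniformly at random, and self-loops
#' and duplicate edges are discarded (realized degrees can therefore fall
#' slightly below the targets).
#'
#' @param gene_ids character vector of gene ids (the node set).
#' @param low_degree_genes genes (e.g. CNV or duplication genes) given the
#'   lower mean degree.
#' @param mean_degree,mean_degree_low Poisson means for ordinary and
#'   low-degree genes; defaults 20 and 10.
#' @param seed RNG seed (required).
#' @return List with `edges` (data.frame `gene1`, `gene2`) and `truth`
#'   (data.frame `gene_id`, `low_degree`, `target_degree`).
#' @export
simulate_ppi <- function(gene_ids, low_degree_genes = character(),
                         mean_degree = 20, mean_degree_low = 10, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  low <- gene_ids %in% low_degree_genes
  target <- stats::rpois(length(gene_ids),
                         ifelse(low, mean_degree_low, mean_degree))
  stubs <- rep(gene_ids, target)
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  stubs <- sample(stubs)
  half <- length(stubs) / 2
  e1 <- stubs[seq_len(half)]
  e2 <- stubs[half + seq_len(half)]
  keep <- e1 != e2
  a <- pmin(e1[keep], e2[keep])
  b <- pmax(e1[keep], e2[keep])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(gene1 = a[!dup], gene2 = b[!dup],
                      stringsAsFactors = FALSE)
  list(edges = edges,
       truth = data.frame(gene_id = gene_ids, low_degree = low,
                          target_degree = target, stringsAsFactors = FALSE))
}
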