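# Binary expression calls per tissue from heterogeneous platforms, expression
# breadth (number of tissues in which a gene is expressed), tissue-specific
# genes, and the breadth contrast between CNV and neutral genes.
#
# Calling rules are strict inequalities: microarray UPC > 0.5 or RNA-seq
# FPKM/RPKM > 1.0 in at least one sample of the tissue. Tissues assayed in
# two experiments are combined by union: expressed in either experiment
# counts as expressed.

#' Call per-gene, per-tissue expression for one experiment
#'
#' @param experiment an `expression_experiment` (see
#'   [expression_experiment()] / [read_expression_experiment()]).
#' @param upc_threshold UPC cutoff for microarray data; default 0.5.
#' @param fpkm_threshold FPKM/RPKM cutoff for RNA-seq data; default 1.0.
#' @return Logical matrix, genes x tissues: `TRUE` when at least one sample
#'   of the tissue exceeds the platform threshold (strict `>`).
#' @export
call_expressed <- function(experiment, upc_threshold = 0.5,
                           fpkm_threshold = 1.0) {
  if (!inherits(experiment, "expression_experiment")) {
    stop("expected an expression_experiment")
  }
  thr <- switch(experiment$platform,
                microarray_upc = upc_threshold,
                rnaseq_fpkm = fpkm_threshold,
                stop("unknown platform: ", experiment$platform))
  tissues <- unique(experiment$tissue)
  calls <- vapply(tissues, function(t) {
    cols <- which(experiment$tissue == t)
    apply(experiment$values[, cols, drop = FALSE] > thr, 1, any)
  }, logical(nrow(experiment$values)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list(rownames(experiment$values), tissues))
  colnames(calls) <- tissues
  rownames(calls) <- rownames(experiment$values)
  calls
}

#' Combine per-experiment expression calls by union
#'
#' Tissue names are harmonized first: when a synonym table is supplied every
#' tissue label must map to a canonical name, and unmapped labels raise an
#' error listing the offenders. A gene counts as expressed in a tissue if it
#' passed the calling rule in any contributing experiment; breadth is the
#' number of tissues called expressed.
#'
#' @param callsets list of logical call matrices from [call_expressed()].
#' @param synonyms optional `data.frame` with columns `raw`, `canonical`.
#' @return An `expression_callset`: list with `calls` (logical genes x
#'   tissues matrix over the union of genes and tissues) and `breadth`
#'   (named integer vector).
#' @export
combine_experiments <- function(callsets, synonyms = NULL) {
  if (!length(callsets)) stop("no callsets supplied")
  harmonize <- function(tissues) {
    if (is.null(synonyms)) return(tissues)
    idx <- match(tissues, synonyms$raw)
    if (anyNA(idx)) {
      stop("unmapped tissue name(s): ",
           paste(unique(tissues[is.na(idx)]), collapse = ", "))
    }
    synonyms$canonical[idx]
  }
  callsets <- lapply(callsets, function(m) {
    colnames(m) <- harmonize(colnames(m))
    m
  })
  genes <- Reduce(union, lapply(callsets, rownames))
  tissues <- Reduce(union, lapply(callsets, colnames))
  combined <- matrix(FALSE, length(genes), length(tissues),
                     dimnames = list(genes, tissues))
  for (m in callsets) {
    for (t in unique(colnames(m))) {
      # a tissue may appear under several columns after harmonization
      v <- apply(m[, colnames(m) == t, drop = FALSE], 1, any)
      combined[rownames(m), t] <- combined[rownames(m), t] | v
    }
  }
  structure(list(calls = combined,
                 breadth = stats::setNames(as.integer(rowSums(combined)),
                                           genes)),
            class = "expression_callset")
}

#' @export
print.expression_callset <- function(x, ...) {
  cat("expression_callset:", nrow(x$calls), "gene(s) x", ncol(x$calls),
      "tissue(s);", sum(x$breadth > 0), "expressed gene(s)\n")
  invisible(x)
}

#' Tissue-specific genes (breadth exactly 1)
#'
#' @param callset an `expression_callset`.
#' @return `data.frame` with columns `tissue`, `gene_id`, one row per
#'   tissue-specific gene, plus zero-count tissues absent.
#' @export
tissue_specific_genes <- function(callset) {
  stopifnot(inherits(callset, "expression_callset"))
  spec <- names(callset$breadth)[callset$breadth == 1L]
  if (!length(spec)) {
    return(data.frame(tissue = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  tissue <- apply(callset$calls[spec, , drop = FALSE], 1,
                  function(r) colnames(callset$calls)[which(r)])
  out <- data.frame(tissue = unname(tissue), gene_id = spec,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tissue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tissue counts of tissue-specific genes, overall and within a gene set
#'
#' @param callset an `expression_callset`.
#' @param cnv_genes character vector of CNV gene ids.
#' @return `data.frame` with `tissue`, `n_specific`, `n_specific_cnv`
#'   covering every tissue in the panel.
#' @export
tissue_specific_counts <- function(callset, cnv_genes) {
  spec <- tissue_specific_genes(callset)
  tissues <- colnames(callset$calls)
  data.frame(
    tissue = tissues,
    n_specific = as.integer(table(factor(spec$tissue, levels = tissues))),
    n_specific_cnv = as.integer(table(factor(
      spec$tissue[spec$gene_id %in% cnv_genes], levels = tissues))),
    stringsAsFactors = FALSE)
}

#' Contrast expression breadth of CNV genes against neutral genes
#'
#' Only genes expressed in at least one tissue enter the contrast
#' ("expressed CNV genes" vs "expressed neutral genes"). One-tailed
#' Wilcoxon rank-sum test of the hypothesis that CNV genes are expressed in
#' fewer tissues.
#'
#' @param callset an `expression_callset` over the full gene panel.
#' @param cnv_genes character vector of CNV gene ids.
#' @return A `rank_sum` object (alternative `"less"`; `median_x` is the CNV
#'   group).
#' @export
compare_breadth <- function(callset, cnv_genes) {
  stopifnot(inherits(callset, "expression_callset"))
  b <- callset$breadth[callset$breadth >= 1L]
  x <- b[names(b) %in% cnv_genes]
  y <- b[!names(b) %in% cnv_genes]
  if (!length(x) || !length(y)) stop("empty expressed group")
  wilcoxon_rank_sum(as.numeric(x), as.numeric(y), alternative = "less")
}
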