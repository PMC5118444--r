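# Intersect CNVRs with gene models and partition the overlapped ("CNV")
# genes into duplication / deletion / mixed classes. Strand is carried in
# the gene table but ignored: CNVRs are unstranded.

#' Find genes overlapped by CNVRs
#'
#' A gene is a CNV gene iff it shares at least one base with at least one
#' CNVR. The overlap is `"complete"` when the gene interval is contained in
#' the union of the CNVRs that touch it, `"partial"` otherwise.
#'
#' @param cnvr_set a `cnvr_set` (states not required here).
#' @param genes gene-model `data.frame` from [read_gene_models()].
#' @return A `data.frame` with one row per CNV gene: `gene_id`, `biotype`,
#'   `overlap_kind`, `cnvr_ids` (comma-separated).
#' @export
overlap_genes <- function(cnvr_set, genes) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  cnvrs <- cnvr_set$cnvrs
  empty <- data.frame(gene_id = character(), biotype = character(),
                      overlap_kind = character(), cnvr_ids = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(cnvrs) || !nrow(genes)) return(empty)
  lv <- union(genes$chrom, cnvrs$chrom)  # shared seqlevels
  ggr <- GenomicRanges::GRanges(factor(genes$chrom, lv),
                                IRanges::IRanges(genes$start + 1, genes$end))
  cgr <- GenomicRanges::GRanges(factor(cnvrs$chrom, lv),
                                IRanges::IRanges(cnvrs$start + 1, cnvrs$end))
  hits <- GenomicRanges::findOverlaps(ggr, cgr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  by_gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  gi <- as.integer(names(by_gene))
  rec <- lapply(seq_along(gi), function(j) {
    g <- gi[j]
    cv <- by_gene[[j]]
    covered <- GenomicRanges::intersect(ggr[g],
                                        GenomicRanges::reduce(cgr[cv]),
                                        ignore.strand = TRUE)
    kind <- if (sum(GenomicRanges::width(covered)) ==
                GenomicRanges::width(ggr[g])) "complete" else "partial"
    data.frame(gene_id = genes$gene_id[g], biotype = genes$biotype[g],
               overlap_kind = kind,
               cnvr_ids = paste(cnvrs$cnvr_id[sort(cv)], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Assign duplication/deletion/mixed classes to CNV genes
#'
#' A gene overlapped only by gain CNVRs is a duplication gene; only by loss
#' CNVRs, a deletion gene; any other combination (a mixed CNVR, or both a
#' pure gain and a pure loss) makes it a mixed gene.
#'
#' @param records output of [overlap_genes()].
#' @param cnvr_set a `cnvr_set` with states assigned (see
#'   [classify_states()]).
#' @return `records` with a `gene_class` column.
#' @export
partition_gene_classes <- function(records, cnvr_set) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  if (is.null(cnvr_set$cnvrs$state)) {
    stop("CNVR states not assigned; run classify_states() first")
  }
  state_of <- stats::setNames(cnvr_set$cnvrs$state, cnvr_set$cnvrs$cnvr_id)
  records$gene_class <- vapply(records$cnvr_ids, function(ids) {
    st <- state_of[strsplit(ids, ",", fixed = TRUE)[[1]]]
    if (anyNA(st)) stop("cnvr_id without a state")
    if (all(st == "gain")) "duplication"
    else if (all(st == "loss")) "deletion"
    else "mixed"
  }, character(1), USE.NAMES = FALSE)
  records
}

#' Split gene ids by CNV class, with the neutral complement
#'
#' @param records classed records from [partition_gene_classes()].
#' @param genes full gene-model table (the gene universe).
#' @return A list of character vectors: `duplication`, `deletion`, `mixed`,
#'   `cnv` (their union) and `neutral` (all remaining genes).
#' @export
gene_class_sets <- function(records, genes) {
  sets <- list(
    duplication = records$gene_id[records$gene_class == "duplication"],
    deletion = records$gene_id[records$gene_class == "deletion"],
    mixed = records$gene_id[records$gene_class == "mixed"])
  sets$cnv <- records$gene_id
  sets$neutral <- setdiff(genes$gene_id, records$gene_id)
  sets
}
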