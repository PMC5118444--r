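# Degree centrality in a protein-protein interaction network and the
# per-class contrast against copy-number-neutral genes.

#' Node degree for every gene in an interaction edge list
#'
#' Edges are treated as undirected: self-loops are dropped and unordered
#' duplicates (including reversed pairs) collapsed, so the degree is the
#' number of distinct interaction partners. Confidence scores, if present in
#' the input, play no role.
#'
#' @param edges `data.frame` with columns `gene1`, `gene2` (see
#'   [read_edge_list()]).
#' @return Named integer vector of degrees for every gene appearing in the
#'   edge list. Genes absent from the list implicitly have degree 0 (see
#'   [compare_centrality()]).
#' @examples
#' compute_degrees(data.frame(gene1 = c("A", "B", "A"),
#'                            gene2 = c("B", "C", "C")))
#' @export
compute_degrees <- function(edges) {
  if (!all(c("gene1", "gene2") %in% names(edges))) {
    stop("edge list needs columns gene1 and gene2")
  }
  if (!nrow(edges)) return(stats::setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(edges[, c("gene1", "gene2")],
                                     directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  stats::setNames(as.integer(deg), names(deg))
}

#' Contrast network degree of a CNV gene class against neutral genes
#'
#' Both groups are restricted to genes with at least one interaction
#' (degree >= 1); genes missing from the network are treated as degree 0 and
#' therefore drop out. One-tailed Wilcoxon rank-sum test of the hypothesis
#' that the class sits at lower degree than the neutral set.
#'
#' @param class_genes,neutral_genes character vectors of gene ids.
#' @param degrees named degree vector from [compute_degrees()].
#' @return A `rank_sum` object (alternative `"less"`; `median_x` is the
#'   class group).
#' @export
compare_centrality <- function(class_genes, neutral_genes, degrees) {
  deg_of <- function(genes) {
    d <- degrees[genes]
    d[is.na(d)] <- 0L
    d <- d[d >= 1L]
    as.numeric(d)
  }
  x <- deg_of(class_genes)
  y <- deg_of(neutral_genes)
  if (!length(x) || !length(y)) {
    stop("empty group after restricting to degree >= 1")
  }
  wilcoxon_rank_sum(x, y, alternative = "less")
}
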