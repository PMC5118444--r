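# Binomial test of annotation-term over/under-representation in a gene set,
# Bonferroni-corrected, in the style of classical GO enrichment tools.
#
# With a universe of N annotated genes of which K carry a term, and a query
# of n genes of which k carry it, the expected count is n*K/N and the tail
# probability is binomial: P(X >= k) for over-representation (k > expected)
# or P(X <= k) for under-representation, X ~ Binomial(n, K/N). The Bonferroni
# multiplier m is the number of terms with K >= 1 in the annotation set used.

#' Binomial over/under-representation test for annotation terms
#'
#' @param query character vector of query gene ids (e.g. CNV genes). Genes
#'   outside the annotated universe are dropped before testing; `n` is the
#'   size of the intersection.
#' @param annotation an `annotation_table` from [read_annotation_table()],
#'   or a data.frame with columns `term_id`, `gene_id`.
#' @param universe optional explicit universe of gene ids. Defaults to all
#'   genes with at least one annotation in `annotation` — the convention of
#'   restricting both N and n to annotated genes.
#' @return A `data.frame` sorted by raw p-value with columns `term_id`,
#'   `term_name`, `aspect` (when term metadata is available), `K`, `n`, `k`,
#'   `expected`, `direction` (`"+"`/`"-"`), `p_raw`, `p_bonferroni`.
#' @examples
#' ann <- data.frame(term_id = rep(c("T1", "T2"), c(3, 2)),
#'                   gene_id = c("a", "b", "c", "c", "d"))
#' binomial_enrichment(c("a", "c"), ann)
#' @export
binomial_enrichment <- function(query, annotation, universe = NULL) {
  t2g <- if (inherits(annotation, "annotation_table")) {
    annotation$term2gene
  } else {
    annotation
  }
  meta <- if (inherits(annotation, "annotation_table")) annotation$meta else NULL
  t2g <- unique(t2g[, c("term_id", "gene_id")])
  if (is.null(universe)) {
    universe <- unique(t2g$gene_id)
  } else {
    t2g <- t2g[t2g$gene_id %in% universe, , drop = FALSE]
  }
  N <- length(unique(universe))
  query <- unique(query)
  query <- query[query %in% universe]
  n <- length(query)
  if (n == 0) stop("empty query after intersecting with the annotated universe")
  K_tab <- table(t2g$term_id)
  terms <- names(K_tab)[K_tab >= 1L]
  m <- length(terms)
  in_query <- t2g$gene_id %in% query
  k_tab <- table(factor(t2g$term_id[in_query], levels = terms))
  K <- as.integer(K_tab[terms])
  if (any(K > N)) stop("term with more annotated genes than the universe")
  k <- as.integer(k_tab)
  expected <- n * K / N
  direction <- ifelse(k > expected, "+", "-")
  p_raw <- ifelse(direction == "+",
                  stats::pbinom(k - 1L, n, K / N, lower.tail = FALSE),
                  stats::pbinom(k, n, K / N))
  out <- data.frame(term_id = terms, K = K, n = n, k = k,
                    expected = expected, direction = direction,
                    p_raw = p_raw,
                    p_bonferroni = pmin(1, m * p_raw),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    idx <- match(out$term_id, meta$term_id)
    out$term_name <- meta$term_name[idx]
    out$aspect <- if ("aspect" %in% names(meta)) meta$aspect[idx] else NA
    out <- out[, c("term_id", "term_name", "aspect", "K", "n", "k",
                   "expected", "direction", "p_raw", "p_bonferroni")]
  }
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
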