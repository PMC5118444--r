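# Selective constraint via pairwise dN/dS: translate the coding sequences,
# align the proteins (BLOSUM50, affine gaps), copy the gaps back onto the
# nucleotide sequences, and estimate synonymous / nonsynonymous substitution
# rates with the Nei-Gojobori (1986) proportion method plus Jukes-Cantor
# multiple-hit correction dX = -(3/4) * log(1 - (4/3) * pX).
#
# Site and difference counting follows the standard conventions:
# - the synonymous fraction of a site is the share of its three possible
#   single-nucleotide changes that preserve the amino acid; changes creating
#   a stop codon contribute nothing (so they fall on the nonsynonymous side
#   of N = 3*codons - S);
# - sites are averaged between the two sequences;
# - codons differing at 2 or 3 positions are scored by averaging synonymous
#   and nonsynonymous steps over all minimal mutational pathways, discarding
#   pathways that pass through a stop codon (if every pathway does, all are
#   kept rather than losing the codon);
# - columns containing gaps, ambiguous bases, or stop codons are skipped.

.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng_cache$tables)) return(.ng_cache$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  syn_frac <- rep(NA_real_, n)
  names(syn_frac) <- codons
  for (i in seq_len(n)) {
    if (code[i] == "*") next
    s <- 0
    cdn <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, cdn[pos])) {
        alt <- cdn
        alt[pos] <- b
        alt_aa <- code[paste(alt, collapse = "")]
        if (alt_aa == "*") next
        if (alt_aa == code[i]) s <- s + 1 / 3
      }
    }
    syn_frac[i] <- s
  }
  sd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(n)) {
    if (code[i] == "*") next
    for (j in seq_len(n)) {
      if (code[j] == "*") next
      d <- pathway_average(codons[i], codons[j], code)
      sd_mat[i, j] <- d[1]
      nd_mat[i, j] <- d[2]
    }
  }
  .ng_cache$tables <- list(codons = codons, code = code,
                           syn_frac = syn_frac, sd = sd_mat, nd = nd_mat)
  .ng_cache$tables
}

# average (synonymous, nonsynonymous) step counts over minimal mutational
# pathways between two sense codons
pathway_average <- function(c1, c2, code) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0) return(c(0, 0))
  perms <- permutations_of(diff_pos)
  score_path <- function(order_pos) {
    cur <- a
    sd <- 0; nsd <- 0
    through_stop <- FALSE
    for (pos in order_pos) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- code[paste(cur, collapse = "")]
      aa_nxt <- code[paste(nxt, collapse = "")]
      if (aa_nxt == "*") through_stop <- TRUE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nsd <- nsd + 1
      cur <- nxt
    }
    c(sd, nsd, through_stop)
  }
  scored <- vapply(perms, score_path, numeric(3))
  valid <- scored[3, ] == 0
  if (!any(valid)) valid <- rep(TRUE, ncol(scored))  # all paths cross a stop
  c(mean(scored[1, valid]), mean(scored[2, valid]))
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code. A terminal stop codon is trimmed silently; an
#' internal stop is an error (the sequence is not a clean CDS). Codons
#' containing `N` or other non-ACGT characters translate to `X`.
#'
#' @param nt nucleotide string, length divisible by 3.
#' @return Amino-acid string.
#' @examples
#' translate_cds("TTTGCT")  # "FA"
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3 != 0) stop("sequence length not divisible by 3")
  n_codons <- nchar(nt) / 3
  cdn <- substring(nt, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  clean <- grepl("^[ACGT]{3}$", cdn)
  aa <- rep("X", n_codons)
  aa[clean] <- Biostrings::GENETIC_CODE[cdn[clean]]
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    stop("internal stop codon at codon position ", stop_at[1])
  }
  paste(aa, collapse = "")
}

#' Globally align two protein sequences (BLOSUM50, affine gaps)
#'
#' Needleman-Wunsch global alignment maximizing the BLOSUM50 score with an
#' affine gap penalty (a gap of length L costs `gap_open + L * gap_extend`).
#' The dynamic program's tie-breaking is deterministic, so results are
#' reproducible for any input.
#'
#' @param aa1,aa2 non-empty amino-acid strings.
#' @param gap_open,gap_extend gap penalties; defaults 10 and 1.
#' @return List with aligned strings `a1`, `a2` (gaps as `-`) and `score`.
#' @export
align_proteins <- function(aa1, aa2, gap_open = 10, gap_extend = 1) {
  if (!nchar(aa1) || !nchar(aa2)) stop("empty protein sequence")
  mat <- get_blosum50()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa1), Biostrings::AAString(aa2),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(a1 = as.character(Biostrings::alignedPattern(pa)),
       a2 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

get_blosum50 <- function() {
  if (is.null(.ng_cache$blosum50)) {
    e <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = e)
    .ng_cache$blosum50 <- e$BLOSUM50
  }
  .ng_cache$blosum50
}

#' Project protein-alignment gaps onto the coding sequences
#'
#' Each amino-acid gap becomes a three-base gap, yielding a codon-aligned
#' nucleotide pair. Ungapped columns reproduce the original codons in order.
#' Terminal stop codons (trimmed during translation) are dropped.
#'
#' @param cds1,cds2 original coding sequences.
#' @param alignment result of [align_proteins()] on their translations.
#' @return List with codon-aligned nucleotide strings `nt1`, `nt2`.
#' @export
project_gaps <- function(cds1, cds2, alignment) {
  proj <- function(cds, aligned_aa) {
    cds <- toupper(cds)
    n_codons <- nchar(cds) / 3
    cdn <- substring(cds, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
    # drop terminal stop to mirror translate_cds()
    if (length(cdn) &&
        !is.na(Biostrings::GENETIC_CODE[cdn[length(cdn)]]) &&
        Biostrings::GENETIC_CODE[cdn[length(cdn)]] == "*") {
      cdn <- cdn[-length(cdn)]
    }
    chars <- strsplit(aligned_aa, "")[[1]]
    if (sum(chars != "-") != length(cdn)) {
      stop("alignment length does not match coding sequence (",
           sum(chars != "-"), " aligned residues vs ", length(cdn),
           " codons)")
    }
    out <- character(length(chars))
    out[chars == "-"] <- "---"
    out[chars != "-"] <- cdn
    paste(out, collapse = "")
  }
  list(nt1 = proj(cds1, alignment$a1), nt2 = proj(cds2, alignment$a2))
}

#' Nei-Gojobori dN/dS from a codon-aligned nucleotide pair
#'
#' @param nt1,nt2 codon-aligned nucleotide strings of equal length divisible
#'   by 3 (gaps as `-`).
#' @return A one-row `data.frame`: `S`, `N` (synonymous / nonsynonymous
#'   sites), `Sd`, `Nd` (pathway-averaged differences), `pS`, `pN`, `dS`,
#'   `dN` (Jukes-Cantor corrected; `NA` when saturated), `omega` (`NA` when
#'   dS and dN are both 0 or the pair is saturated; `Inf` when dS = 0 but
#'   dN > 0), `saturated`, `n_codons` (ungapped codon columns used).
#' @examples
#' nei_gojobori_dnds("TTTGCTGCTGCT", "TTCGCTGCTGCT")
#' @export
nei_gojobori_dnds <- function(nt1, nt2) {
  nt1 <- toupper(nt1)
  nt2 <- toupper(nt2)
  if (nchar(nt1) != nchar(nt2)) stop("aligned sequences differ in length")
  if (nchar(nt1) %% 3 != 0) stop("alignment length not divisible by 3")
  tab <- ng_tables()
  nc <- nchar(nt1) / 3
  c1 <- substring(nt1, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  c2 <- substring(nt2, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  i1 <- match(c1, tab$codons)
  i2 <- match(c2, tab$codons)
  usable <- !is.na(i1) & !is.na(i2) &
    !is.na(tab$syn_frac[i1]) & !is.na(tab$syn_frac[i2])
  if (!any(usable)) stop("no ungapped sense codon columns in alignment")
  i1 <- i1[usable]
  i2 <- i2[usable]
  S <- sum((tab$syn_frac[i1] + tab$syn_frac[i2]) / 2)
  N <- 3 * length(i1) - S
  Sd <- sum(tab$sd[cbind(i1, i2)])
  Nd <- sum(tab$nd[cbind(i1, i2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 / 3 * p
    if (arg <= 0) NA_real_ else -3 / 4 * log(arg)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega <- if (saturated) {
    NA_real_
  } else if (dS == 0) {
    if (dN == 0) NA_real_ else Inf
  } else {
    dN / dS
  }
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             dS = dS, dN = dN, omega = omega, saturated = saturated,
             n_codons = length(i1))
}

#' Full dN/dS protocol for one ortholog pair
#'
#' Translate both coding sequences, align the proteins with BLOSUM50,
#' project the gaps onto the nucleotide sequences and run the Nei-Gojobori
#' estimator.
#'
#' @param query_cds,ortholog_cds coding sequences (terminal stop allowed).
#' @inheritParams align_proteins
#' @return One-row `data.frame` as from [nei_gojobori_dnds()].
#' @export
dnds_pair <- function(query_cds, ortholog_cds, gap_open = 10, gap_extend = 1) {
  aa1 <- translate_cds(query_cds)
  aa2 <- translate_cds(ortholog_cds)
  aln <- align_proteins(aa1, aa2, gap_open, gap_extend)
  cod <- project_gaps(query_cds, ortholog_cds, aln)
  nei_gojobori_dnds(cod$nt1, cod$nt2)
}

#' dN/dS for a table of ortholog pairs
#'
#' @param pairs `data.frame` with columns `gene_id`, `query_cds`,
#'   `ortholog_cds` (see [read_ortholog_pairs()]).
#' @inheritParams align_proteins
#' @return A `data.frame`, one row per pair, `gene_id` first.
#' @export
dnds_pairs <- function(pairs, gap_open = 10, gap_extend = 1) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cbind(data.frame(gene_id = pairs$gene_id[i], stringsAsFactors = FALSE),
          dnds_pair(pairs$query_cds[i], pairs$ortholog_cds[i],
                    gap_open, gap_extend))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop saturated pairs
#'
#' Pairs whose synonymous or nonsynonymous divergence reaches the
#' Jukes-Cantor domain boundary (pX >= 3/4) have no defined rate and are
#' removed before any contrast.
#'
#' @param results output of [dnds_pairs()].
#' @return The subset with `saturated == FALSE` and both rates defined.
#' @export
filter_saturated <- function(results) {
  keep <- !results$saturated & !is.na(results$dN) & !is.na(results$dS)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast substitution rates of a CNV gene class against neutral genes
#'
#' One-tailed Wilcoxon rank-sum test of the hypothesis that the class is
#' shifted toward higher values than the neutral set (relaxed constraint).
#' For `statistic = "omega"`, pairs with undefined or infinite ratios
#' (dS = 0) are excluded.
#'
#' @param class_results,neutral_results unsaturated dN/dS tables (see
#'   [filter_saturated()]).
#' @param statistic `"omega"`, `"dN"` or `"dS"`.
#' @return A `rank_sum` object (alternative `"greater"`), with the statistic
#'   recorded in attribute `"statistic"`.
#' @export
compare_constraint <- function(class_results, neutral_results,
                               statistic = c("omega", "dN", "dS")) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "omega") "omega" else statistic
  pull <- function(df) {
    v <- df[[col]]
    v[is.finite(v)]
  }
  x <- pull(class_results)
  y <- pull(neutral_results)
  if (!length(x) || !length(y)) {
    stop("empty group after removing undefined ", statistic, " values")
  }
  out <- wilcoxon_rank_sum(x, y, alternative = "greater")
  attr(out, "statistic") <- statistic
  out
}
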