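# CNVR construction: merging per-sample CNV calls into copy number variable
# regions under a pairwise reciprocal-overlap rule, frequency filtering,
# loss/gain/mixed state classification, and genome-level summaries.

#' Reciprocal overlap between two genomic intervals
#'
#' For intervals A and B sharing `o` bases, the reciprocal overlap is
#' `min(o/|A|, o/|B|)`; "50% reciprocal overlap" requires both ratios to
#' reach 0.5. Intervals on different chromosomes, or merely abutting under
#' the half-open convention, have reciprocal overlap 0. Vectorized and
#' symmetric.
#'
#' @param start1,end1,start2,end2 0-based half-open interval coordinates.
#' @param chrom1,chrom2 optional chromosome names; when supplied, pairs on
#'   different chromosomes score 0.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' reciprocal_overlap(100, 200, 140, 240)  # 0.6
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (any(end1 <= start1) || any(end2 <= start2)) {
    stop("zero- or negative-length interval")
  }
  o <- pmin(end1, end2) - pmax(start1, start2)
  o <- pmax(o, 0)
  ro <- pmin(o / (end1 - start1), o / (end2 - start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ro[as.character(chrom1) != as.character(chrom2)] <- 0
  }
  ro
}

new_cnvr_set <- function(cnvrs, calls) {
  rownames(cnvrs) <- NULL
  rownames(calls) <- NULL
  structure(list(cnvrs = cnvrs, calls = calls), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat("cnvr_set:", nrow(x$cnvrs), "CNVR(s) from", nrow(x$calls),
      "call(s) in", length(unique(x$calls$sample)), "sample(s)\n")
  if (!is.null(x$cnvrs$state)) {
    print(table(state = x$cnvrs$state))
  }
  invisible(x)
}

#' Merge per-sample CNV calls into CNVRs by reciprocal overlap
#'
#' Calls (and, as merging proceeds, the growing regions) are agglomerated:
#' while any two current regions on the same chromosome have reciprocal
#' overlap of their extents >= `threshold`, the qualifying pair with the
#' highest reciprocal overlap is merged (ties broken by leftmost, then
#' shortest, merged extent), and the merged extent runs from the minimum
#' start to the maximum end of the members. The procedure is a deterministic
#' fixed point: input order is irrelevant because calls are first sorted by
#' (chrom, start, end, sample), and the emitted regions pairwise fall below
#' the threshold, so re-merging them changes nothing.
#'
#' Overlap-versus-threshold comparisons use exact integer arithmetic
#' (`o * q >= len * p` for threshold `p/q`) so boundary cases such as
#' exactly 50% are not subject to floating-point noise.
#'
#' @param calls CNV call `data.frame` (columns `sample`, `chrom`, `start`,
#'   `end`, `copy_number`).
#' @param threshold minimum pairwise reciprocal overlap in (0, 1];
#'   default 0.5.
#' @return A `cnvr_set`: list with `cnvrs` (data.frame `cnvr_id`, `chrom`,
#'   `start`, `end`, `n_samples`, `n_calls`) and `calls` (the input calls
#'   plus a `cnvr_id` column). Every call belongs to exactly one CNVR.
#' @export
merge_cnvs <- function(calls, threshold = 0.5) {
  stopifnot(is.data.frame(calls))
  if (!nrow(calls)) {
    cnvrs <- data.frame(cnvr_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        n_samples = integer(), n_calls = integer(),
                        stringsAsFactors = FALSE)
    return(new_cnvr_set(cnvrs, cbind(calls, cnvr_id = character(0))))
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (any(calls$end <= calls$start)) stop("invalid call interval (end <= start)")
  calls <- sort_cnv_calls(calls)
  # rational threshold p/q for exact integer comparisons
  frac <- rational_threshold(threshold)
  group <- integer(nrow(calls))
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr)
    group[idx] <- max(group) + merge_one_chrom(calls$start[idx],
                                               calls$end[idx],
                                               frac$p, frac$q)
  }
  # stable region ids ordered by (chrom, start, end)
  reg_chrom <- tapply(calls$chrom, group, `[`, 1)
  reg_start <- tapply(calls$start, group, min)
  reg_end <- tapply(calls$end, group, max)
  ord <- order(reg_chrom, reg_start, reg_end)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  cnvr_id <- paste0("CNVR_", relabel[match(group, as.integer(names(reg_start)))])
  calls$cnvr_id <- cnvr_id
  cnvrs <- data.frame(
    cnvr_id = paste0("CNVR_", seq_along(ord)),
    chrom = as.character(reg_chrom[ord]),
    start = as.numeric(reg_start[ord]),
    end = as.numeric(reg_end[ord]),
    n_samples = as.integer(tapply(calls$sample, group,
                                  function(s) length(unique(s)))[ord]),
    n_calls = as.integer(tapply(calls$sample, group, length)[ord]),
    stringsAsFactors = FALSE)
  new_cnvr_set(cnvrs, calls)
}

rational_threshold <- function(threshold) {
  # small-denominator rational approximation; exact for thresholds such as
  # 0.5 that users actually pass
  for (q in 1:1000) {
    p <- threshold * q
    if (abs(p - round(p)) < 1e-9) return(list(p = round(p), q = q))
  }
  list(p = round(threshold * 1e6), q = 1e6)
}

# Best-pair-first agglomeration on one chromosome. Returns an integer group
# label per call (1-based, arbitrary but deterministic).
merge_one_chrom <- function(start, end, p, q) {
  n <- length(start)
  grp <- seq_len(n)
  rs <- start
  re <- end
  active <- rep(TRUE, n)
  repeat {
    ai <- which(active)
    k <- length(ai)
    if (k < 2) break
    s <- rs[ai]; e <- re[ai]
    ii <- rep(seq_len(k), times = k)
    jj <- rep(seq_len(k), each = k)
    ut <- ii < jj
    ii <- ii[ut]; jj <- jj[ut]
    o <- pmin(e[ii], e[jj]) - pmax(s[ii], s[jj])
    len_i <- e[ii] - s[ii]
    len_j <- e[jj] - s[jj]
    # reciprocal overlap >= p/q  <=>  o*q >= max(len)*p, overlap positive
    qual <- o > 0 & o * q >= len_i * p & o * q >= len_j * p
    if (!any(qual)) break
    ro <- ifelse(qual, pmin(o / len_i, o / len_j), -1)
    ms <- pmin(s[ii], s[jj])
    me <- pmax(e[ii], e[jj])
    best <- order(-ro, ms, me - ms)[1]
    if (!qual[best]) break
    a <- ai[ii[best]]; b <- ai[jj[best]]
    rs[a] <- min(rs[a], rs[b])
    re[a] <- max(re[a], re[b])
    grp[grp == grp[b]] <- grp[a]
    active[b] <- FALSE
  }
  match(grp, unique(grp))
}

#' Filter CNVRs by sample frequency
#'
#' Regions supported by fewer than `min_samples` distinct samples are set
#' aside, mirroring the removal of rare and possibly false-positive regions
#' before downstream analysis.
#'
#' @param cnvr_set a `cnvr_set`.
#' @param min_samples minimum number of distinct carrier samples (>= 1);
#'   default 3.
#' @return A list with `kept` and `removed`, both `cnvr_set`s.
#' @export
filter_by_frequency <- function(cnvr_set, min_samples = 3L) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  if (min_samples < 1) stop("min_samples must be >= 1")
  keep <- cnvr_set$cnvrs$n_samples >= min_samples
  kept_ids <- cnvr_set$cnvrs$cnvr_id[keep]
  split_set <- function(sel_ids) {
    new_cnvr_set(cnvr_set$cnvrs[cnvr_set$cnvrs$cnvr_id %in% sel_ids, ,
                                drop = FALSE],
                 cnvr_set$calls[cnvr_set$calls$cnvr_id %in% sel_ids, ,
                                drop = FALSE])
  }
  list(kept = split_set(kept_ids),
       removed = split_set(setdiff(cnvr_set$cnvrs$cnvr_id, kept_ids)))
}

#' Classify copy-number state from member copy numbers
#'
#' @param copy_number integer vector of member copy numbers.
#' @param baseline expected copy number for the chromosome (2 for autosomes,
#'   1 for the X in males).
#' @return `"loss"`, `"gain"` or `"mixed"`.
#' @export
classify_cn_state <- function(copy_number, baseline) {
  if (any(copy_number == baseline)) {
    stop("member call with copy number equal to baseline (", baseline,
         "): a no-change call does not belong in a CNV list")
  }
  lo <- any(copy_number < baseline)
  hi <- any(copy_number > baseline)
  if (lo && hi) "mixed" else if (lo) "loss" else "gain"
}

#' Classify every CNVR as loss, gain or mixed
#'
#' A region is a loss if all member calls sit below the chromosome's
#' baseline copy number, a gain if all sit above, and mixed when both
#' directions occur among its carriers.
#'
#' @param cnvr_set a `cnvr_set`.
#' @param genome genome description (see [genome_description()]) providing
#'   per-chromosome baselines.
#' @return The `cnvr_set` with a `state` column added to `$cnvrs`.
#' @export
classify_states <- function(cnvr_set, genome) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  base <- genome$expected_copy_number[match(cnvr_set$cnvrs$chrom,
                                            genome$chrom)]
  if (anyNA(base)) {
    stop("no baseline copy number for chromosome(s): ",
         paste(unique(cnvr_set$cnvrs$chrom[is.na(base)]), collapse = ", "))
  }
  cn_by_region <- split(cnvr_set$calls$copy_number, cnvr_set$calls$cnvr_id)
  cnvr_set$cnvrs$state <- vapply(seq_len(nrow(cnvr_set$cnvrs)), function(i) {
    classify_cn_state(cn_by_region[[cnvr_set$cnvrs$cnvr_id[i]]], base[i])
  }, character(1))
  cnvr_set
}

#' Summarize a CNVR set
#'
#' Sizes are reported in bases; `total_unique` is the number of bases
#' covered by at least one CNVR (interval union), and `genome_fraction`
#' divides that by the total genome length.
#'
#' @param cnvr_set a `cnvr_set`, ideally with states assigned.
#' @param genome genome description covering every CNVR chromosome.
#' @return A list of class `cnvr_summary`: `count`, `min_size`, `max_size`,
#'   `mean_size`, `median_size`, `total_unique`, `genome_fraction`,
#'   `state_counts`.
#' @export
summarize_cnvrs <- function(cnvr_set, genome) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  cnvrs <- cnvr_set$cnvrs
  chrom_len <- genome$length[match(cnvrs$chrom, genome$chrom)]
  if (anyNA(chrom_len)) {
    stop("genome description missing chromosome(s): ",
         paste(unique(cnvrs$chrom[is.na(chrom_len)]), collapse = ", "))
  }
  if (any(cnvrs$end > chrom_len)) {
    stop("CNVR extends beyond chromosome length")
  }
  sizes <- cnvrs$end - cnvrs$start
  gr <- GenomicRanges::GRanges(cnvrs$chrom,
                               IRanges::IRanges(cnvrs$start + 1, cnvrs$end))
  total_unique <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(gr))))
  states <- if (!is.null(cnvrs$state)) {
    table(factor(cnvrs$state, levels = c("loss", "gain", "mixed")))
  } else NULL
  structure(list(count = nrow(cnvrs),
                 min_size = if (length(sizes)) min(sizes) else NA_real_,
                 max_size = if (length(sizes)) max(sizes) else NA_real_,
                 mean_size = if (length(sizes)) mean(sizes) else NA_real_,
                 median_size = if (length(sizes)) stats::median(sizes) else NA_real_,
                 total_unique = total_unique,
                 genome_fraction = total_unique / sum(as.numeric(genome$length)),
                 state_counts = states),
            class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("%d CNVR(s); sizes %.4g-%.4g bp (mean %.4g, median %.4g)\n",
              x$count, x$min_size, x$max_size, x$mean_size, x$median_size))
  cat(sprintf("unique coverage %.4g bp (%.3g%% of genome)\n",
              x$total_unique, 100 * x$genome_fraction))
  if (!is.null(x$state_counts)) print(x$state_counts)
  invisible(x)
}

#' Fraction of query CNVRs overlapped by a reference set
#'
#' Cross-study comparisons use a permissive rule: a query region counts as
#' overlapped as soon as it shares at least one base with any reference
#' interval (no reciprocal requirement). Half-open abutting intervals do not
#' share a base.
#'
#' @param query data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   a `cnvr_set` is also accepted.
#' @param reference data.frame with `chrom`, `start`, `end`.
#' @return Fraction in \[0, 1\] of query regions sharing >= 1 base with the
#'   reference set.
#' @export
compare_cnvr_sets <- function(query, reference) {
  if (inherits(query, "cnvr_set")) query <- query$cnvrs
  if (!nrow(query)) stop("empty query CNVR set")
  if (!nrow(reference)) return(0)
  lv <- union(query$chrom, reference$chrom)
  qgr <- GenomicRanges::GRanges(factor(query$chrom, lv),
                                IRanges::IRanges(query$start + 1, query$end))
  rgr <- GenomicRanges::GRanges(factor(reference$chrom, lv),
                                IRanges::IRanges(reference$start + 1,
                                                 reference$end))
  hits <- GenomicRanges::countOverlaps(qgr, rgr, minoverlap = 1L)
  mean(hits > 0)
}
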