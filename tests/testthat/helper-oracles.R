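# Independent brute-force oracles used to validate the package's optimized
# implementations, plus small fixture builders. Oracles deliberately share
# no code with the implementation paths they check.

# Fixed-point agglomerative merge by repeated all-pairs scanning: merge the
# qualifying pair with the highest reciprocal overlap (ties: leftmost then
# shortest merged extent) until no pair qualifies. Returns, per input call,
# the extent of the region containing it.
oracle_merge <- function(calls, threshold = 0.5) {
  regs <- lapply(seq_len(nrow(calls)), function(i) {
    list(chrom = calls$chrom[i], start = calls$start[i],
         end = calls$end[i], members = i)
  })
  repeat {
    best <- NULL
    best_key <- NULL
    n <- length(regs)
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          a <- regs[[i]]
          b <- regs[[j]]
          if (a$chrom != b$chrom) next
          o <- min(a$end, b$end) - max(a$start, b$start)
          if (o <= 0) next
          ro <- min(o / (a$end - a$start), o / (b$end - b$start))
          if (ro < threshold) next
          key <- c(-ro, min(a$start, b$start),
                   max(a$end, b$end) - min(a$start, b$start))
          if (is.null(best_key) || lexicographically_less(key, best_key)) {
            best <- c(i, j)
            best_key <- key
          }
        }
      }
    }
    if (is.null(best)) break
    a <- regs[[best[1]]]
    b <- regs[[best[2]]]
    merged <- list(chrom = a$chrom, start = min(a$start, b$start),
                   end = max(a$end, b$end),
                   members = sort(c(a$members, b$members)))
    regs <- c(regs[-best], list(merged))
  }
  extent <- matrix(NA_real_, nrow(calls), 2)
  chrom <- character(nrow(calls))
  for (r in regs) {
    extent[r$members, 1] <- r$start
    extent[r$members, 2] <- r$end
    chrom[r$members] <- r$chrom
  }
  data.frame(chrom = chrom, start = extent[, 1], end = extent[, 2],
             stringsAsFactors = FALSE)
}

lexicographically_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# random merge instance on one or two chromosomes with dense overlaps
random_calls <- function(n, n_chrom = 1, max_pos = 300) {
  starts <- sample.int(max_pos, n, replace = TRUE)
  lens <- sample(10:120, n, replace = TRUE)
  data.frame(
    sample = sample(paste0("S", 1:5), n, replace = TRUE),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    start = starts, end = starts + lens,
    copy_number = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# per-call region extents from a merged cnvr_set, aligned to `calls` rows
merged_extents <- function(cnvr_set, calls) {
  key <- paste(calls$sample, calls$chrom, calls$start, calls$end,
               calls$copy_number)
  mkey <- paste(cnvr_set$calls$sample, cnvr_set$calls$chrom,
                cnvr_set$calls$start, cnvr_set$calls$end,
                cnvr_set$calls$copy_number)
  idx <- match(key, mkey)
  rid <- cnvr_set$calls$cnvr_id[idx]
  pos <- match(rid, cnvr_set$cnvrs$cnvr_id)
  data.frame(chrom = cnvr_set$cnvrs$chrom[pos],
             start = cnvr_set$cnvrs$start[pos],
             end = cnvr_set$cnvrs$end[pos], stringsAsFactors = FALSE)
}

# one-sided rank-sum p-value by full enumeration of group assignments
enum_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(ii) sum(r[ii]))
  if (alternative == "greater") mean(ws >= w_obs) else mean(ws <= w_obs)
}

# binomial tail by direct term summation
binom_tail_sum <- function(k, n, p, upper) {
  js <- if (upper) k:n else 0:k
  sum(choose(n, js) * p^js * (1 - p)^(n - js))
}

# maximum global alignment score by exhaustive enumeration of alignments
# (affine gap cost open + len * ext), for short sequences only
enum_align_score <- function(s1, s2, open = 10, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  B <- e$BLOSUM50
  a1 <- strsplit(s1, "")[[1]]
  a2 <- strsplit(s2, "")[[1]]
  best <- -Inf
  score_cols <- function(top, bottom) {
    s <- 0
    for (k in seq_along(top)) {
      if (top[k] != "-" && bottom[k] != "-") s <- s + B[top[k], bottom[k]]
    }
    gap_cost <- function(row) {
      r <- rle(row == "-")
      sum(ifelse(r$values, open + ext * r$lengths, 0))
    }
    s - gap_cost(top) - gap_cost(bottom)
  }
  rec <- function(i, j, top, bottom) {
    if (i > length(a1) && j > length(a2)) {
      best <<- max(best, score_cols(top, bottom))
      return(invisible())
    }
    if (i <= length(a1) && j <= length(a2)) {
      rec(i + 1, j + 1, c(top, a1[i]), c(bottom, a2[j]))
    }
    if (i <= length(a1)) rec(i + 1, j, c(top, a1[i]), c(bottom, "-"))
    if (j <= length(a2)) rec(i, j + 1, c(top, "-"), c(bottom, a2[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# per-base coverage count on a small interval set (bitmap union oracle)
bitmap_unique_bases <- function(chrom, start, end, chrom_len) {
  total <- 0
  for (chr in unique(chrom)) {
    hit <- rep(FALSE, chrom_len)
    sel <- which(chrom == chr)
    for (i in sel) hit[(start[i] + 1):end[i]] <- TRUE
    total <- total + sum(hit)
  }
  total
}

tiny_genome <- function() {
  genome_description(c("chr1", "chr2", "chrX"), c(1e6, 8e5, 6e5))
}
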