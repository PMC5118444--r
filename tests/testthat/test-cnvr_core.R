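test_that("reciprocal overlap follows the min-of-both-fractions rule", {
  expect_equal(reciprocal_overlap(100, 200, 140, 240), 0.6)
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1.0)
  # half-open adjacency shares no base
  expect_equal(reciprocal_overlap(0, 100, 100, 200), 0.0)
  expect_equal(reciprocal_overlap(0, 100, 50, 150, "chr1", "chr2"), 0.0)
  # symmetry
  expect_equal(reciprocal_overlap(10, 30, 20, 100),
               reciprocal_overlap(20, 100, 10, 30))
  expect_error(reciprocal_overlap(10, 10, 0, 5), "length")
})

test_that("two overlapping calls merge into one region spanning a to d", {
  # a < c < b < d with reciprocal overlap >= 0.5 merges into [a, d)
  calls <- data.frame(sample = c("S1", "S2"), chrom = "chr1",
                      start = c(100, 140), end = c(200, 240),
                      copy_number = c(1L, 1L), stringsAsFactors = FALSE)
  m <- merge_cnvs(calls, 0.5)
  expect_equal(nrow(m$cnvrs), 1)
  expect_equal(m$cnvrs$start, 100)
  expect_equal(m$cnvrs$end, 240)
  expect_equal(m$cnvrs$n_samples, 2L)
})

test_that("single calls and sub-threshold pairs stay separate", {
  one <- data.frame(sample = "S1", chrom = "chr1", start = 10, end = 60,
                    copy_number = 1L, stringsAsFactors = FALSE)
  m <- merge_cnvs(one)
  expect_equal(m$cnvrs[, c("start", "end")],
               data.frame(start = 10, end = 60))
  two <- data.frame(sample = c("S1", "S2"), chrom = "chr1",
                    start = c(0, 90), end = c(100, 190),
                    copy_number = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_cnvs(two, 0.5)$cnvrs), 2)  # overlap 10/100 = 0.1
})

test_that("exactly 50% reciprocal overlap qualifies at the boundary", {
  calls <- data.frame(sample = c("S1", "S2"), chrom = "chr1",
                      start = c(0, 50), end = c(100, 150),
                      copy_number = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_cnvs(calls, 0.5)$cnvrs), 1)
})

test_that("merging matches the brute-force fixed-point oracle", {
  set.seed(101)
  for (rep in 1:150) {
    calls <- random_calls(sample(2:20, 1), n_chrom = sample(1:2, 1))
    m <- merge_cnvs(calls, 0.5)
    sorted <- calls[order(calls$chrom, calls$start, calls$end,
                          calls$sample), , drop = FALSE]
    expect_equal(merged_extents(m, sorted), oracle_merge(sorted, 0.5),
                 ignore_attr = TRUE)
  }
})

test_that("merging is idempotent and permutation-invariant", {
  set.seed(77)
  for (rep in 1:25) {
    calls <- random_calls(15)
    m <- merge_cnvs(calls, 0.5)
    # partition property: every call in exactly one region
    expect_equal(sum(m$cnvrs$n_calls), nrow(calls))
    expect_true(all(table(m$calls$cnvr_id)[m$cnvrs$cnvr_id] ==
                      m$cnvrs$n_calls))
    # permutation invariance
    perm <- calls[sample(nrow(calls)), , drop = FALSE]
    m2 <- merge_cnvs(perm, 0.5)
    expect_equal(m$cnvrs, m2$cnvrs)
    # idempotence: re-merging emitted extents as pseudo-calls is a no-op
    pseudo <- data.frame(sample = m$cnvrs$cnvr_id, chrom = m$cnvrs$chrom,
                         start = m$cnvrs$start, end = m$cnvrs$end,
                         copy_number = 1L, stringsAsFactors = FALSE)
    m3 <- merge_cnvs(pseudo, 0.5)
    expect_equal(m3$cnvrs[, c("chrom", "start", "end")],
                 m$cnvrs[, c("chrom", "start", "end")])
  }
})

test_that("frequency filter splits regions by distinct carrier count", {
  calls <- data.frame(
    sample = c("S1", "S2", "S1", "S2", "S3", "S1"), chrom = "chr1",
    start = c(0, 0, 1000, 1000, 1000, 5000),
    end = c(100, 100, 1100, 1100, 1100, 5100),
    copy_number = rep(1L, 6), stringsAsFactors = FALSE)
  m <- merge_cnvs(calls)
  flt <- filter_by_frequency(m, 3)
  expect_equal(nrow(flt$kept$cnvrs), 1)
  expect_equal(flt$kept$cnvrs$n_samples, 3L)
  expect_equal(nrow(flt$removed$cnvrs), 2)
  # duplicate calls from one sample count once
  dup <- data.frame(sample = c("S1", "S1", "S2"), chrom = "chr1",
                    start = c(0, 5, 0), end = c(100, 105, 100),
                    copy_number = rep(1L, 3), stringsAsFactors = FALSE)
  md <- merge_cnvs(dup)
  expect_equal(md$cnvrs$n_samples, 2L)
  expect_equal(nrow(filter_by_frequency(md, 3)$kept$cnvrs), 0)
  expect_error(filter_by_frequency(md, 0), "min_samples")
})

test_that("state classification is a trichotomy over member copy numbers", {
  expect_equal(classify_cn_state(c(0L, 1L), 2L), "loss")
  expect_equal(classify_cn_state(c(3L, 4L), 2L), "gain")
  expect_equal(classify_cn_state(c(1L, 3L), 2L), "mixed")
  expect_equal(classify_cn_state(0L, 1L), "loss")
  expect_error(classify_cn_state(c(1L, 2L), 2L), "baseline")

  calls <- data.frame(sample = c("S1", "S2", "S1"),
                      chrom = c("chr1", "chr1", "chrX"),
                      start = c(0, 10, 0), end = c(100, 110, 50),
                      copy_number = c(1L, 3L, 2L), stringsAsFactors = FALSE)
  cs <- classify_states(merge_cnvs(calls), tiny_genome())
  expect_setequal(cs$cnvrs$state, c("mixed", "gain"))  # CN 2 on X is a gain
  expect_true(all(cs$cnvrs$state %in% c("loss", "gain", "mixed")))
})

test_that("summaries report sizes and bitmap-exact unique coverage", {
  calls <- data.frame(sample = paste0("S", 1:2), chrom = "chr1",
                      start = c(0, 50), end = c(100, 150),
                      copy_number = c(1L, 1L), stringsAsFactors = FALSE)
  m <- merge_cnvs(calls, 0.9)  # keep the two regions separate
  expect_equal(nrow(m$cnvrs), 2)
  s <- summarize_cnvrs(m, tiny_genome())
  expect_equal(s$mean_size, 100)
  expect_equal(s$median_size, 100)
  expect_equal(s$total_unique, 150)  # union of [0,100) and [50,150)
  expect_equal(s$genome_fraction, 150 / sum(tiny_genome()$length))

  set.seed(5)
  n <- 50
  starts <- sample.int(500, n)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  ends <- starts + sample(5:80, n, replace = TRUE)
  cs <- merge_cnvs(data.frame(sample = "S1", chrom = chrom, start = starts,
                              end = ends, copy_number = 1L,
                              stringsAsFactors = FALSE), 0.999999)
  su <- summarize_cnvrs(cs, tiny_genome())
  expect_equal(su$total_unique,
               bitmap_unique_bases(cs$cnvrs$chrom, cs$cnvrs$start,
                                   cs$cnvrs$end, 1e3))
  expect_error(
    summarize_cnvrs(merge_cnvs(data.frame(sample = "S1", chrom = "chr1",
                                          start = 0, end = 2e6,
                                          copy_number = 1L)), tiny_genome()),
    "beyond")
})

test_that("any-shared-base set comparison matches an all-pairs check", {
  q <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0, 200, 0), end = c(100, 300, 50))
  ref <- data.frame(chrom = "chr1", start = 100, end = 250)
  # [0,100) abuts [100,250): not overlapped; [200,300) shares bases
  expect_equal(compare_cnvr_sets(q, ref), 1 / 3)
  inner <- data.frame(chrom = "chr1", start = 210, end = 220)
  expect_equal(compare_cnvr_sets(inner, ref), 1)
  expect_error(compare_cnvr_sets(q[0, ], ref), "empty")

  set.seed(11)
  for (rep in 1:20) {
    qq <- random_calls(10)[, c("chrom", "start", "end")]
    rr <- random_calls(8)[, c("chrom", "start", "end")]
    brute <- mean(vapply(seq_len(nrow(qq)), function(i) {
      any(rr$chrom == qq$chrom[i] & rr$start < qq$end[i] &
            rr$end > qq$start[i])
    }, logical(1)))
    expect_equal(compare_cnvr_sets(qq, rr), brute)
  }
})
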