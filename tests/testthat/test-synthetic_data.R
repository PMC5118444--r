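test_that("generators are byte-deterministic under a fixed seed", {
  g <- simulate_genome(n_autosomes = 4)
  a <- simulate_cnv_calls(g, n_samples = 10, n_cnvrs = 10, seed = 5)
  b <- simulate_cnv_calls(g, n_samples = 10, n_cnvrs = 10, seed = 5)
  expect_identical(a, b)
  expect_false(identical(
    a$calls, simulate_cnv_calls(g, n_samples = 10, n_cnvrs = 10,
                                seed = 6)$calls))
  p1 <- simulate_ortholog_pairs(n_pairs = 3, n_codons = 30, seed = 5)
  p2 <- simulate_ortholog_pairs(n_pairs = 3, n_codons = 30, seed = 5)
  expect_identical(p1, p2)
  e1 <- simulate_expression(c("a", "b"), "a", seed = 5)
  e2 <- simulate_expression(c("a", "b"), "a", seed = 5)
  expect_identical(e1, e2)
  n1 <- simulate_ppi(letters, seed = 5)
  expect_identical(n1, simulate_ppi(letters, seed = 5))
  expect_error(simulate_cnv_calls(g, n_samples = 2, n_cnvrs = 2), "seed")
})

test_that("zero jitter reproduces the planted regions exactly", {
  g <- simulate_genome(n_autosomes = 6, include_x = FALSE)
  sim <- simulate_cnv_calls(g, n_samples = 15, n_cnvrs = 25, jitter_sd = 0,
                            rare_fraction = 0, seed = 21)
  m <- merge_cnvs(sim$calls)
  expect_equal(nrow(m$cnvrs), nrow(sim$truth))
  got <- m$cnvrs[order(m$cnvrs$chrom, m$cnvrs$start),
                 c("chrom", "start", "end")]
  want <- sim$truth[order(sim$truth$chrom, sim$truth$start),
                    c("chrom", "start", "end")]
  expect_equal(got, want, ignore_attr = TRUE)
  # carrier bookkeeping matches the truth table
  expect_equal(sort(as.integer(m$cnvrs$n_samples)),
               sort(sim$truth$n_carriers))
})

test_that("rare planted regions fall to the frequency filter", {
  g <- simulate_genome(n_autosomes = 6, include_x = FALSE)
  sim <- simulate_cnv_calls(g, n_samples = 20, n_cnvrs = 30, jitter_sd = 0,
                            rare_fraction = 0.3, seed = 33)
  expect_gt(sum(sim$truth$n_carriers < 3), 0)
  m <- merge_cnvs(sim$calls)
  flt <- filter_by_frequency(m, 3)
  expect_equal(nrow(flt$kept$cnvrs), sum(sim$truth$n_carriers >= 3))
  expect_equal(nrow(flt$removed$cnvrs), sum(sim$truth$n_carriers < 3))
})

test_that("planted states survive merging and classification", {
  g <- simulate_genome(n_autosomes = 8)
  sim <- simulate_cnv_calls(g, n_samples = 20, n_cnvrs = 30, jitter_sd = 0,
                            rare_fraction = 0, seed = 41)
  cs <- classify_states(merge_cnvs(sim$calls), g)
  got <- cs$cnvrs[order(cs$cnvrs$chrom, cs$cnvrs$start), ]
  want <- sim$truth[order(sim$truth$chrom, sim$truth$start), ]
  expect_equal(got$state, want$state)
})

test_that("jittered calls keep reciprocal overlap with their region >= 0.5", {
  g <- simulate_genome(n_autosomes = 6, include_x = FALSE)
  sim <- simulate_cnv_calls(g, n_samples = 20, n_cnvrs = 40,
                            jitter_sd = 0.10, rare_fraction = 0, seed = 51)
  tr <- sim$truth[match(sim$calls$true_cnvr, sim$truth$cnvr_id), ]
  ro <- reciprocal_overlap(sim$calls$start, sim$calls$end,
                           tr$start, tr$end)
  expect_true(all(ro >= 0.5))
})

test_that("simulated codon pairs at omega = 0 diverge only synonymously", {
  sim <- simulate_ortholog_pairs(n_pairs = 4, n_codons = 60, omega = 0,
                                 seed = 61)
  expect_true(all(sim$truth$n_nonsyn_subs == 0))
  res <- dnds_pairs(sim$pairs)
  expect_true(all(res$Nd == 0))
  # translated proteins are identical when omega = 0
  expect_equal(translate_cds(sim$pairs$query_cds[1]),
               translate_cds(sim$pairs$ortholog_cds[1]))
})

test_that("expression generator respects platform value ranges", {
  sim <- simulate_expression(sprintf("g%d", 1:30), "g1", seed = 71)
  for (e in sim$experiments) {
    if (e$platform == "microarray_upc") {
      expect_true(all(e$values >= 0 & e$values <= 1))
    } else {
      expect_true(all(e$values >= 0))
    }
  }
  expect_equal(length(unique(unlist(lapply(sim$experiments,
                                           function(e) e$tissue)))), 22)
})

test_that("ppi generator emits clean undirected edges", {
  sim <- simulate_ppi(sprintf("g%d", 1:50), seed = 81)
  expect_true(all(sim$edges$gene1 != sim$edges$gene2))
  key <- paste(sim$edges$gene1, sim$edges$gene2)
  expect_false(any(duplicated(key)))
  # realized degrees track the Poisson targets on average
  deg <- compute_degrees(sim$edges)
  expect_gt(mean(deg), 10)
})
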