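upc_fixture <- function() {
  vals <- matrix(c(0.2, 0.6,   # gene A, spleen: one sample over 0.5
                   0.4, 0.45,  # gene B, spleen: all under
                   0.9, 0.8),  # gene C
                 nrow = 3, byrow = TRUE)
  rownames(vals) <- c("A", "B", "C")
  colnames(vals) <- c("s1", "s2")
  expression_experiment("E1", "microarray_upc", vals, c("spleen", "spleen"))
}

test_that("expression calls use strict platform thresholds", {
  calls <- call_expressed(upc_fixture())
  expect_true(calls["A", "spleen"])
  expect_false(calls["B", "spleen"])

  vals <- matrix(c(1.0, 1.0, 1.01, 0.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("X", "Y"), c("s1", "s2")))
  rna <- expression_experiment("E2", "rnaseq_fpkm", vals,
                               c("liver", "liver"))
  calls2 <- call_expressed(rna)
  expect_false(calls2["X", "liver"])  # FPKM exactly 1.0 is not expressed
  expect_true(calls2["Y", "liver"])
  expect_error(expression_experiment("E3", "microarray_upc",
                                     matrix(1.5), "t"), "\\[0, 1\\]")
})

test_that("experiments combine by union with tissue harmonization", {
  m1 <- matrix(TRUE, 1, 1, dimnames = list("g1", "Liver"))
  m2 <- matrix(FALSE, 1, 1, dimnames = list("g1", "liver"))
  syn <- data.frame(raw = c("Liver", "liver"), canonical = "liver")
  cs <- combine_experiments(list(m1, m2), syn)
  expect_true(cs$calls["g1", "liver"])
  expect_equal(unname(cs$breadth["g1"]), 1L)
  expect_error(combine_experiments(list(m1), data.frame(raw = "x",
                                                        canonical = "x")),
               "unmapped.*Liver")

  # disjoint tissue calls add up; union never shrinks breadth
  ma <- matrix(c(TRUE, FALSE), 1, 2, dimnames = list("g", c("t1", "t2")))
  mb <- matrix(c(TRUE, TRUE), 1, 2, dimnames = list("g", c("t3", "t4")))
  cs2 <- combine_experiments(list(ma, mb))
  expect_equal(unname(cs2$breadth["g"]), 3L)
  expect_gte(cs2$breadth["g"], combine_experiments(list(ma))$breadth["g"])
})

test_that("tissue-specific genes have breadth exactly one", {
  calls <- matrix(c(TRUE, FALSE, FALSE,
                    TRUE, TRUE, FALSE,
                    FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE), 4, 3, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4),
                                  c("testes", "brain", "spleen")))
  cs <- structure(list(calls = calls,
                       breadth = setNames(as.integer(rowSums(calls)),
                                          rownames(calls))),
                  class = "expression_callset")
  spec <- tissue_specific_genes(cs)
  expect_equal(spec$gene_id[spec$tissue == "testes"], "g1")
  expect_equal(spec$gene_id[spec$tissue == "spleen"], "g4")
  expect_false("g2" %in% spec$gene_id)
  counts <- tissue_specific_counts(cs, cnv_genes = "g4")
  expect_equal(sum(counts$n_specific), sum(cs$breadth == 1))
  expect_equal(counts$n_specific_cnv[counts$tissue == "spleen"], 1L)
  expect_equal(counts$n_specific_cnv[counts$tissue == "testes"], 0L)
})

test_that("breadth contrast is one-tailed CNV-below-neutral on expressed genes", {
  calls <- rbind(
    c1 = c(TRUE, FALSE, FALSE, FALSE),
    c2 = c(TRUE, FALSE, FALSE, FALSE),
    n1 = c(TRUE, TRUE, TRUE, FALSE),
    n2 = c(TRUE, TRUE, TRUE, TRUE),
    silent = c(FALSE, FALSE, FALSE, FALSE))
  colnames(calls) <- paste0("t", 1:4)
  cs <- structure(list(calls = calls,
                       breadth = setNames(as.integer(rowSums(calls)),
                                          rownames(calls))),
                  class = "expression_callset")
  rs <- compare_breadth(cs, cnv_genes = c("c1", "c2", "silent"))
  # silent genes are excluded: groups are {1,1} vs {3,4} => exact p = 1/6
  expect_equal(rs$n1, 2)
  expect_equal(rs$n2, 2)
  expect_equal(rs$p_one_tailed, 1 / 6)
  expect_equal(rs$median_x, 1)
  expect_equal(rs$median_y, 3.5)
  expect_error(compare_breadth(cs, cnv_genes = character()), "empty")
})

test_that("planted expression truth is recovered exactly from synthetic data", {
  genes <- sprintf("G%03d", 1:120)
  cnv <- genes[1:20]
  sim <- simulate_expression(genes, cnv, seed = 61)
  callsets <- lapply(sim$experiments, call_expressed)
  cs <- combine_experiments(callsets)
  expect_equal(unname(cs$breadth[sim$truth$gene_id]), sim$truth$breadth)
  spec <- tissue_specific_genes(cs)
  expect_setequal(spec$gene_id, sim$truth$gene_id[sim$truth$breadth == 1])
  # planted gap shows up as a strongly significant contrast
  rs <- compare_breadth(cs, cnv)
  expect_lt(rs$p_one_tailed, 0.001)
  expect_lt(rs$median_x, rs$median_y)
})
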