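make_table <- function(signals, cond = c(A1 = "A", A2 = "A", A3 = "A",
                                         B1 = "B", B2 = "B", B3 = "B"),
                       sets = list()) {
  expression_table(signals, cond, sets)
}

test_that("normalization scales every sample mean to exactly 500", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("A1", "B1")))
  out <- normalize_signals(m)
  expect_equal(unname(out[1, ]), c(500, 500))
  m2 <- rbind(g1 = c(1, 10), g2 = c(3, 30))
  colnames(m2) <- c("A1", "B1")
  out2 <- normalize_signals(m2)
  expect_equal(unname(colMeans(out2)), c(500, 500))
  expect_equal(unname(out2[, 1]), c(250, 750))          # the [1,3] sample
  expect_equal(out2[1, 1] / out2[2, 1], 1 / 3)          # ratios preserved
  already <- matrix(c(400, 600), 2, 1, dimnames = list(c("g1", "g2"), "A1"))
  expect_equal(normalize_signals(already), already)     # mean-500 fixed point
  expect_error(normalize_signals(matrix(0, 2, 1,
                                        dimnames = list(c("a", "b"), "A1"))),
               "all-zero")
})

test_that("exact one-sided Mann-Whitney matches its spec cases", {
  expect_equal(gene_set_shift_test(c(1, 2, 3), c(4, 5, 6), "greater"), 0.05)
  expect_equal(gene_set_shift_test(c(4, 5, 6), c(1, 2, 3), "less"), 0.05)
  # identical groups under the documented mid-p continuity handling
  expect_equal(gene_set_shift_test(c(1, 2, 3), c(1, 2, 3), "greater",
                                   continuity = "midp"), 0.5)
})

test_that("exact enumeration agrees with brute force for all m, n <= 8", {
  withr::with_seed(33, {
    for (m in 1:8) for (n in 1:8) {
      a <- stats::rnorm(m)
      b <- stats::rnorm(n, 0.5)
      expect_equal(gene_set_shift_test(a, b, "greater"),
                   brute_force_mw_p(a, b), tolerance = 1e-12)
    }
    # tied data too
    a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
    expect_equal(gene_set_shift_test(a, b, "greater"), brute_force_mw_p(a, b),
                 tolerance = 1e-12)
  })
})

test_that("exact p equals the classical exact test on untied data", {
  withr::with_seed(8, {
    for (i in 1:10) {
      a <- stats::rnorm(6); b <- stats::rnorm(7, 0.3)
      ref <- stats::wilcox.test(b, a, alternative = "greater",
                                exact = TRUE)$p.value
      expect_equal(gene_set_shift_test(a, b, "greater"), ref,
                   tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact branch at moderate sizes", {
  withr::with_seed(14, {
    a <- stats::rnorm(8); b <- stats::rnorm(8, 0.4)
    p_exact <- gene_set_shift_test(a, b, "greater")
    p_approx <- gene_set_shift_test(a, b, "greater", max_exact = 0L)
    expect_lt(abs(p_exact - p_approx), 0.01)
    # large-sample branch stays a valid p-value under heavy ties
    at <- rep(1:3, 12); bt <- rep(2:4, 12)
    p <- gene_set_shift_test(at, bt, "greater")
    expect_gt(p, 0); expect_lt(p, 1)
  })
})

test_that("volcano classification applies the log2FC >= 1 / p < 0.05 rule
           with the sign-corrected down rule", {
  expect_equal(classify_de(1.2, 0.01), "up")
  expect_equal(classify_de(-1.5, 0.04), "down")
  expect_equal(classify_de(0.5, 0.001), "ns")
  expect_equal(classify_de(1.2, 0.06), "ns")
  expect_equal(classify_de(c(1, -1, 2), c(0.04, 0.04, 0.5)),
               c("up", "down", "ns"))
})

test_that("fold-change classification uses the symmetric 1.5-fold cutoff", {
  expect_equal(classify_fold_cutoff(1.6), "up")
  expect_equal(classify_fold_cutoff(1.0), "ns")
  expect_equal(classify_fold_cutoff(0.6), "down")   # 0.6 < 1/1.5
  expect_equal(classify_fold_cutoff(1.5), "up")
  expect_error(classify_fold_cutoff(-1), "positive")
})

test_that("classification is invariant to the normalization scale", {
  withr::with_seed(3, {
    sig <- matrix(stats::rlnorm(60, 5, 1), 10, 6,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  c("A1", "A2", "A3", "B1", "B2", "B3")))
    tb <- make_table(sig)
    d1 <- de_table(tb, "A", "B", pseudo = 0)
    tb2 <- tb; tb2$signals <- tb$signals * 37
    d2 <- de_table(tb2, "A", "B", pseudo = 0)
    expect_equal(d1$log2fc, d2$log2fc, tolerance = 1e-9)
    expect_equal(d1$p, d2$p, tolerance = 1e-9)
    expect_equal(d1$class, d2$class)
  })
})

test_that("set summary computes hand-checked quartiles and degenerate boxes", {
  # 5 genes with known per-gene mean log2 values in condition A
  vals <- c(1, 2, 3, 4, 10)
  sig <- cbind(A1 = 2^vals, A2 = 2^vals, A3 = 2^vals,
               B1 = 2^(vals + 1), B2 = 2^(vals + 1), B3 = 2^(vals + 1))
  rownames(sig) <- sprintf("g%d", 1:5)
  tb <- make_table(sig, sets = list(S = rownames(sig)))
  ss <- set_summary(tb, "S", "A", "B", pseudo = 0)
  expect_equal(unname(ss$stats$a), c(1, 2, 3, 4, 10))  # type-7 quartiles
  expect_equal(ss$median_diff, 1)
  csig <- matrix(8, 3, 6, dimnames = list(sprintf("h%d", 1:3),
                                          c("A1", "A2", "A3", "B1", "B2", "B3")))
  const <- make_table(csig, sets = list(S = sprintf("h%d", 1:3)))
  sc <- set_summary(const, "S", "A", "B", pseudo = 0)
  expect_equal(unname(sc$stats$a["q1"]), unname(sc$stats$a["q3"]))
})

test_that("a +1 log2 set shift at n = 50 is detected with median diff 1", {
  withr::with_seed(99, {
    n <- 50
    base <- stats::rnorm(n, 8, 1)
    noise <- function() matrix(stats::rnorm(n * 3, 0, 0.1), n, 3)
    sig <- cbind(2^(base + noise()), 2^(base + 1 + noise()))
    dimnames(sig) <- list(sprintf("g%02d", 1:n),
                          c("A1", "A2", "A3", "B1", "B2", "B3"))
    tb <- make_table(sig, sets = list(S = rownames(sig)))
    ss <- set_summary(tb, "S", "A", "B", direction = "greater", pseudo = 0)
    expect_lt(ss$p_value, 0.05)
    expect_equal(ss$median_diff, 1, tolerance = 0.1)
    expect_gt(ss$frac_up, 0.5)
  })
})

test_that("genes in both CMP and AbrB sets are excluded from both tests", {
  withr::with_seed(17, {
    genes <- sprintf("g%02d", 1:20)
    sig <- matrix(stats::rlnorm(120, 6, 0.5), 20, 6,
                  dimnames = list(genes, c("A1", "A2", "A3", "B1", "B2", "B3")))
    sets <- list(CMP = genes[1:10], AbrB = genes[8:15])
    tb <- make_table(sig, sets = sets)
    ss_cmp <- set_summary(tb, "CMP", "A", "B")
    ss_abrb <- set_summary(tb, "AbrB", "A", "B")
    expect_equal(ss_cmp$n, 7)       # 3 dual members removed
    expect_equal(ss_cmp$n_excluded, 3)
    expect_equal(ss_abrb$n, 5)
    expect_equal(ss_abrb$n_excluded, 3)
    # a set outside the exclusion pair keeps all members
    tb$sets$other <- genes[1:5]
    expect_equal(set_summary(tb, "other", "A", "B")$n, 5)
  })
})
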