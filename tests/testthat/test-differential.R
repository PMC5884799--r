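test_that("vectorized t statistics match stats::t.test on random data", {
  set.seed(101)
  for (variant in c("welch", "pooled")) {
    case <- matrix(rnorm(40 * 6, mean = 1), nrow = 40)
    control <- matrix(rnorm(40 * 8), nrow = 40)
    rownames(case) <- rownames(control) <- paste0("g", 1:40)
    res <- rowTTest(case, control, variant)
    for (i in c(1, 7, 23, 40)) {
      oracle <- t.test(case[i, ], control[i, ],
                       var.equal = variant == "pooled")
      expect_equal(res$statistic[i], unname(oracle$statistic), tolerance = 1e-12)
      expect_equal(res$pvalue[i], oracle$p.value, tolerance = 1e-12)
      expect_equal(res$df[i], unname(oracle$parameter), tolerance = 1e-12)
    }
  }
})

test_that("two-sample t handles symmetry and degeneracies", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- twoSampleT(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)

  a <- twoSampleT(c(1, 2, 3), c(4, 6, 8))
  b <- twoSampleT(c(4, 6, 8), c(1, 2, 3))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$pvalue, b$pvalue)

  # textbook pooled case: shift +10, within-group sd 1
  pooled <- twoSampleT(c(11, 12, 13), c(1, 2, 3), variant = "pooled")
  expect_equal(pooled$statistic, 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(pooled$pvalue, 2 * pt(-10 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)

  # zero variance in both arms
  flat <- twoSampleT(c(5, 5, 5), c(5, 5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pvalue, 1)
  shifted <- twoSampleT(c(7, 7, 7), c(5, 5, 5))
  expect_equal(shifted$statistic, Inf)
  expect_equal(shifted$pvalue, 0)

  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches the step-up oracle and its edge cases", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))          # never smaller than the input
    expect_true(all(adj <= 1))
    expect_equal(order(adj, p), order(p, p))  # rank preservation
  }
})

test_that("poor-comparison fallback picks the unadjusted column", {
  fb <- choosePvalueColumn(c(0.01, 0.2, 0.5), c(0.2, 0.6, 0.9))
  expect_false(fb$usedAdjusted)
  expect_equal(fb$chosen, c(0.01, 0.2, 0.5))

  ok <- choosePvalueColumn(c(0.001, 0.3), c(0.01, 0.6))
  expect_true(ok$usedAdjusted)
  expect_equal(ok$chosen, c(0.01, 0.6))

  nothing <- choosePvalueColumn(numeric(0), numeric(0))
  expect_true(nothing$usedAdjusted)
  expect_length(nothing$chosen, 0)

  expect_error(choosePvalueColumn(c(0.1), c(0.1, 0.2)), "equal length")
})

test_that("log2 fold change respects the input scale", {
  expect_equal(log2FoldChange(c(6, 6), c(4, 4)), 2)
  expect_equal(log2FoldChange(c(8, 8), c(2, 2), scale = "linear"), 2)
  expect_equal(log2FoldChange(c(3, 5), c(3, 5)), 0)
  expect_error(log2FoldChange(c(-2, 1), c(1, 1), scale = "linear"),
               "positive means")
  expect_error(log2FoldChange(numeric(0), 1), "non-empty")
})

test_that("significance thresholding is strict and idempotent", {
  rec <- makeRecords(c("a", "b", "c", "d"),
                     c(1.2, 1.0, 2.5, -1.5),
                     c(0.01, 0.01, 0.05, 0.002))
  tab <- ComparisonTable("c1", "treated", 4, 4, rec)
  kept <- thresholdSignificant(tab)
  ids <- deRecords(kept)$source_id
  expect_setequal(ids, c("a", "d"))     # b fails strict |lfc| > 1,
                                        # c fails strict p < 0.05
  again <- thresholdSignificant(kept)
  expect_equal(deRecords(again)$source_id, deRecords(kept)$source_id)
})

test_that("runDifferential flags planted genes and respects the fallback", {
  cfg <- syntheticConfig(
    nGenes = 300, groups = c(treated = 1), nCase = 10, nControl = 10,
    dropoutRate = 0, signFlipRate = 0, noiseSd = 0.5,
    planted = list(plantedGene("HIT", "treated", 3, 1)), seed = 5)
  cmp <- generateComparison(cfg, "treated", 1)
  tab <- runDifferential(cmp$case, cmp$control, "t1", "treated")
  rec <- deRecords(tab)
  expect_true(rec$passed[rec$source_id == "HIT"])
  expect_true(attr(tab, "usedAdjusted"))  # strong signal survives BH
  expect_true(all(c("chosen_p", "passed") %in% names(rec)))
})

test_that("null comparisons produce uniform raw p-values", {
  cfg <- syntheticConfig(nGenes = 2000, groups = c(treated = 1),
                         planted = NULL, dropoutRate = 0, seed = 33)
  cmp <- generateComparison(cfg, "treated", 1)
  tt <- rowTTest(cmp$case, cmp$control)
  rate <- mean(tt$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(tt))
  expect_lt(abs(rate - 0.05), 4 * se)
})
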