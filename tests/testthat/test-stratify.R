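test_that("feature matrix has union shape and zero fill", {
  long <- rbind(longRow("g1", "c1", "treated", 1),
                longRow("g2", "c1", "treated", 2),
                longRow("g2", "c2", "treated", -1),
                longRow("g3", "c2", "treated", 0.5),
                longRow("g4", "c3", "treated", 3),
                longRow("g5", "c3", "treated", 1))
  m <- buildFeatureMatrix(long)
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(m["c1", "g1"], 1)
  expect_equal(m["c2", "g1"], 0)          # absent -> 0 fill
  expect_equal(sum(m[, "g4"] != 0), 1L)   # gene seen once -> one nonzero

  expect_error(buildFeatureMatrix(longRow("g", "c1", "treated", 1)),
               "at least 2")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(17)
  m <- matrix(rnorm(12), nrow = 4, ncol = 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  pca <- runPca(m)

  centered <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(cov(centered))
  r <- min(nrow(m) - 1, ncol(m))
  for (j in seq_len(r)) {
    v <- eig$vectors[, j]
    w <- pca$loadings[, j]
    flip <- sign(sum(v * w))
    expect_equal(w, flip * v, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(pca$scores[, j]),
                 flip * as.vector(centered %*% v), tolerance = 1e-8)
  }
  expect_equal(pca$explainedVarianceRatio[seq_len(r)],
               (eig$values / sum(eig$values))[seq_len(r)],
               tolerance = 1e-8)

  # full reconstruction of the centered matrix
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(recon - centered)) / max(abs(centered)), 1e-8)
})

test_that("PCA flags rank-1 structure and degenerate input", {
  base <- c(1, 2, 3, 4)
  m <- outer(c(1, 2, 3), base)
  rownames(m) <- paste0("c", 1:3)
  pca <- runPca(m)
  expect_equal(pca$explainedVarianceRatio[1], 1, tolerance = 1e-12)

  flat <- matrix(5, 3, 4, dimnames = list(paste0("c", 1:3), NULL))
  expect_error(runPca(flat), "degenerate")

  # duplicating a row leaves the loading span unchanged
  m2 <- rbind(m, c4 = m[3, ])
  pca2 <- runPca(m2)
  v1 <- pca$loadings[, 1]; v2 <- pca2$loadings[, 1]
  expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-8)
})

test_that("robust outlier rule flags constructed outliers only", {
  set.seed(23)
  scores <- cbind(PC1 = c(rnorm(10, sd = 0.1), 10), PC2 = rnorm(11, sd = 0.1))
  rownames(scores) <- paste0("c", 1:11)
  pca <- list(scores = scores)
  expect_equal(flagOutliers(pca, k = 3, nComponents = 2), "c11")

  # all identical -> MAD 0 -> skipped with warning, nothing flagged
  same <- list(scores = matrix(1, 5, 2,
                               dimnames = list(paste0("c", 1:5), NULL)))
  expect_warning(out <- flagOutliers(same, k = 3, nComponents = 1),
                 "zero MAD")
  expect_length(out, 0)

  # order invariance
  perm <- sample(nrow(scores))
  pcaPerm <- list(scores = scores[perm, ])
  expect_equal(flagOutliers(pcaPerm, k = 3, nComponents = 2), "c11")

  # manual override honoured
  expect_setequal(flagOutliers(pca, k = 3, nComponents = 2,
                               override = "c2"), c("c2", "c11"))
})

test_that("aberrant sign-shuffled comparisons are flagged in simulation", {
  set.seed(31)
  flaggedBoth <- 0L
  for (rep in 1:25) {
    normal <- matrix(rnorm(20 * 50, sd = 0.2), nrow = 20)
    normal[, 1:10] <- normal[, 1:10] + 2    # shared signature
    aberrant <- matrix(rnorm(2 * 50, sd = 0.2), nrow = 2)
    aberrant[, 1:10] <- aberrant[, 1:10] - 2  # shuffled/opposite signs
    m <- rbind(normal, aberrant)
    rownames(m) <- c(paste0("ok", 1:20), paste0("bad", 1:2))
    flagged <- flagOutliers(runPca(m), k = 3, nComponents = 2)
    if (all(c("bad1", "bad2") %in% flagged)) flaggedBoth <- flaggedBoth + 1L
  }
  expect_gte(flaggedBoth, 24L)
})

test_that("group assignment partitions retained comparisons", {
  meta <- data.frame(
    comparison_id = c(paste0("h", 1:13), paste0("t", 1:22)),
    group_label = c(rep("non_treated", 13), rep("treated", 22)))
  plan <- assignGroups(meta, meta$comparison_id)
  expect_length(plan$groups$general, 35L)
  expect_length(plan$groups$non_treated, 13L)
  expect_length(plan$groups$treated, 22L)
  expect_equal(length(plan$groups$non_treated) + length(plan$groups$treated),
               length(plan$groups$general))

  # outliers leave all three groups
  plan2 <- assignGroups(meta, meta$comparison_id,
                        removed = c(outlier = "h1", outlier = "t5"))
  expect_length(plan2$groups$general, 33L)
  expect_false("h1" %in% plan2$groups$non_treated)
  expect_equal(plan2$removed$reason, c("outlier", "outlier"))

  expect_error(assignGroups(meta, c(meta$comparison_id, "mystery")),
               "unlabeled")
})
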