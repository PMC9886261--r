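test_that("subject means average days and keep missing cells visible", {
  df <- rbind(feature_row("A", "2020-01-01", G3 = 2, label = "frail"),
              feature_row("A", "2020-01-02", G3 = 4, label = "frail"),
              feature_row("B", "2020-01-01", G3 = 10, label = "robust"))
  sm <- suppressWarnings(subject_means(df))
  expect_equal(sm$G3[sm$subject == "A"], 3)
  expect_equal(sm$G3[sm$subject == "B"], 10)   # single day = identity
  expect_true(is.na(sm$G5[1]))
  expect_equal(nrow(sm), 2)
})

test_that("z-score scaling uses the population SD convention", {
  z <- zscore_scale(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # idempotent on already-standardised input
  z2 <- zscore_scale(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  expect_error(zscore_scale(rep(5, 4)), "constant-column")
  # sample-SD convention available
  zs <- zscore_scale(c(1, 2, 3), sd_type = "sample")
  expect_equal(as.numeric(zs), c(-1, 0, 1))
})

test_that("sigmoid scaling is the logistic of the z-score", {
  x <- c(4, 7, 9, 12, 30)
  expect_equal(as.numeric(sigmoid_scale(x)),
               plogis(as.numeric(zscore_scale(x))), tolerance = 1e-12)
  # value at the mean maps to 0.5; one SD above to 1/(1+e^-1)
  s <- sigmoid_scale(x, mu = 10, sigma = 2)
  expect_equal(as.numeric(sigmoid_scale(c(10, 12), mu = 10, sigma = 2)),
               c(0.5, 1 / (1 + exp(-1))), tolerance = 1e-12)
  # monotone: ranks preserved
  expect_equal(rank(as.numeric(sigmoid_scale(x))), rank(x))
})

test_that("rank-sum selection separates shifted groups and spares null ones", {
  sm <- data.frame(label = rep(c("frail", "robust"), each = 9))
  sm$G3 <- c(1:9, 101:109)                 # complete separation
  sm$G1 <- rep(c(5, 7, 3, 8, 2, 9, 4, 6, 1), 2)  # identical distributions
  sel <- rank_sum_select(sm, features = c("G3", "G1"))
  expect_true(sel$retained[sel$feature == "G3"])
  expect_lt(sel$p_value[sel$feature == "G3"], 5e-4)
  expect_false(sel$retained[sel$feature == "G1"])
  expect_equal(sel$p_value[sel$feature == "G1"], 1, tolerance = 0.01)
})

test_that("rank-sum selection is invariant under monotone transforms", {
  set.seed(21)
  sm <- data.frame(label = rep(c("frail", "robust"), each = 9),
                   G3 = c(rnorm(9, 0), rnorm(9, 1.5)))
  p1 <- rank_sum_select(sm, features = "G3")$p_value
  sm$G3 <- exp(sm$G3)
  p2 <- rank_sum_select(sm, features = "G3")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(rank_sum_select(data.frame(label = rep("frail", 4), G3 = 1:4)),
               "insufficient-data")
})

test_that("PCA recovers rank-1 structure and is rotation invariant", {
  set.seed(8)
  u <- rnorm(40)
  line <- outer(u, c(1, -2, 0.5, 3, 1))
  p <- pca_2d(line)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  expect_lt(p$explained[2], 1e-9)

  x <- matrix(rnorm(40 * 5), 40, 5)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(pca_2d(x)$explained, pca_2d(x %*% q)$explained,
               tolerance = 1e-9)
  expect_error(pca_2d(x[1:2, ]), "insufficient-data")
})

test_that("PCA sign convention makes the largest loading positive", {
  set.seed(9)
  x <- matrix(rnorm(60 * 3), 60, 3)
  p <- pca_2d(x)
  for (j in 1:2)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("scale_features drops constant columns and applies fold params", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(2, 4))
  expect_warning(sc <- scale_features(x), "constant")
  expect_equal(colnames(sc$scaled), "a")
  # train params applied to new rows preserve the training map
  xnew <- cbind(a = c(2.5))
  out <- scale_features(xnew, params = sc$params)
  expect_equal(as.numeric(out$scaled),
               plogis((2.5 - mean(x[, "a"])) /
                        (stats::sd(x[, "a"]) * sqrt(3 / 4))),
               tolerance = 1e-12)
})

test_that("median imputation fills missing cells with training medians", {
  x <- cbind(G5 = c(1, NA, 3), G3 = c(5, 6, 7))
  imp <- impute_median(x)
  expect_equal(imp$imputed[2, "G5"], 2, ignore_attr = TRUE)
  y <- cbind(G5 = c(NA, 10), G3 = c(1, 2))
  expect_equal(impute_median(y, imp$medians)$imputed[1, "G5"], 2,
               ignore_attr = TRUE)
})
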