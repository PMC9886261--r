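# a small linearly separable two-class cohort for sanity checks
toy_cohort <- function(n_subj = 8, days = 6, gap = 6, seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n_subj))
  lab <- rep(c("frail", "robust"), each = n_subj / 2)
  x <- NULL; labels <- NULL; subjects <- NULL; dates <- NULL
  for (i in seq_len(n_subj)) {
    mu <- if (lab[i] == "frail") c(0, 0) else c(gap, gap)
    x <- rbind(x, sweep(matrix(rnorm(days * 2, 0, 0.5), days, 2), 2, mu, "+"))
    labels <- c(labels, rep(lab[i], days))
    subjects <- c(subjects, rep(subj[i], days))
    dates <- c(dates, seq_len(days))
  }
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = labels, subjects = subjects, dates = dates)
}

test_that("confusion identities hold exactly on random counts", {
  set.seed(13)
  for (i in 1:25) {
    truth <- runif(60) < 0.5
    pred <- runif(60) < 0.5
    r <- classification_report(truth, pred)
    expect_equal(r$sensitivity, 100 * r$TP / (r$TP + r$FN))
    expect_equal(r$specificity, 100 * r$TN / (r$TN + r$FP))
    expect_equal(r$accuracy,
                 100 * (r$TP + r$TN) / (r$TP + r$TN + r$FP + r$FN))
    expect_equal(r$TP + r$TN + r$FP + r$FN, 60)
  }
})

test_that("every model family is perfect on separable data", {
  tc <- toy_cohort()
  for (fam in c("NN", "SVM", "kNN", "RF", "GBM")) {
    r <- lso_cv(tc$x, tc$labels, tc$subjects, model_spec(fam, seed = 3))
    expect_equal(r$report$accuracy, 100)
  }
})

test_that("subject-shuffled labels give chance-level accuracy", {
  tc <- toy_cohort(n_subj = 10, days = 8, gap = 6, seed = 2)
  set.seed(99)
  subj <- unique(tc$subjects)
  new_lab <- setNames(sample(rep(c("frail", "robust"), each = 5)), subj)
  r <- lso_cv(tc$x, new_lab[tc$subjects], tc$subjects,
              model_spec("kNN", seed = 3))
  expect_gt(r$report$accuracy, 20)
  expect_lt(r$report$accuracy, 80)
})

test_that("LSO never trains on the held-out subject", {
  tc <- toy_cohort()
  r <- lso_cv(tc$x, tc$labels, tc$subjects, model_spec("kNN", seed = 1))
  expect_equal(nrow(r$predictions), nrow(tc$x))
  expect_setequal(unique(r$predictions$subject), unique(tc$subjects))
  expect_error(lso_cv(tc$x, tc$labels, rep("S01", length(tc$labels)),
                      model_spec("kNN")), "insufficient-data")
})

test_that("averaging blocks are block means with remainder dropped", {
  x <- matrix(1:20, ncol = 2)             # 10 days, 2 features
  b <- aggregate_averaging(x, k = 5)
  expect_equal(nrow(b), 2)
  expect_equal(b[1, ], c(3, 13), ignore_attr = TRUE)   # mean of 1..5, 11..15
  expect_equal(nrow(aggregate_averaging(x[1:4, ], k = 5)), 0)
  # constant features aggregate to themselves
  cc <- matrix(7, 5, 2)
  expect_equal(aggregate_averaging(cc, 5)[1, ], c(7, 7), ignore_attr = TRUE)
  expect_error(aggregate_averaging(x, k = 0), "parameter error")
})

test_that("voting takes the majority with the documented tie rule", {
  expect_equal(aggregate_voting(c(FALSE, FALSE, FALSE, FALSE, TRUE)), FALSE)
  expect_equal(aggregate_voting(c(TRUE, TRUE, TRUE, FALSE, FALSE)), TRUE)
  # all-correct dailies give all-correct blocks
  expect_equal(aggregate_voting(rep(TRUE, 10)), c(TRUE, TRUE))
  # k = 1 equals the daily design
  p <- c(TRUE, FALSE, TRUE)
  expect_equal(aggregate_voting(p, k = 1), p)
  expect_equal(aggregate_averaging(matrix(1:3), k = 1), matrix(1:3 * 1),
               ignore_attr = TRUE)
  # even-k ties default to the positive (frail) class
  expect_true(aggregate_voting(c(TRUE, FALSE), k = 2))
  expect_false(aggregate_voting(c(TRUE, FALSE), k = 2, tie = "negative"))
})

test_that("majority voting amplifies a below-half error rate", {
  set.seed(31)
  p_err <- 0.3
  truth <- rep(TRUE, 5000)
  daily <- runif(5000) > p_err           # correct with prob 0.7
  blocks <- aggregate_voting(daily, k = 5)
  expect_lt(mean(!blocks), p_err)        # binomial tail beats p
})

test_that("evaluate_designs reports all designs with exact identities", {
  tc <- toy_cohort(n_subj = 8, days = 10, gap = 6)
  models <- list(model_spec("kNN", seed = 2), model_spec("RF", seed = 2))
  rep <- evaluate_designs(tc$x, tc$labels, tc$subjects, tc$dates, models,
                          n_longitudinal = 2)
  expect_setequal(unique(rep$design), c("daily", "averaging-5", "voting-5"))
  expect_equal(rep$accuracy,
               100 * (rep$TP + rep$TN) / (rep$TP + rep$TN + rep$FP + rep$FN))
  # noiseless-limit: all designs agree at 100%
  expect_true(all(rep$accuracy == 100))
})

test_that("model runs are reproducible under a fixed seed", {
  tc <- toy_cohort(n_subj = 6, days = 5, gap = 2, seed = 4)
  r1 <- lso_cv(tc$x, tc$labels, tc$subjects, model_spec("NN", seed = 11))
  r2 <- lso_cv(tc$x, tc$labels, tc$subjects, model_spec("NN", seed = 11))
  expect_identical(r1$predictions$pred, r2$predictions$pred)
})

test_that("model_spec validates families and hyperparameters", {
  expect_error(model_spec("NN", wrong = 1), "unknown hyperparameter")
  expect_error(model_spec("kNN", k = -1), "positive")
  expect_equal(model_spec("GBM")$params$eta, 0.4)
  expect_equal(model_spec("RF")$params$ntree, 10)
  expect_equal(model_spec("NN")$params$size, 15)
  expect_equal(model_spec("kNN")$params$k, 5)
})
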