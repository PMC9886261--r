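#' Classifier specification
#'
#' The five classifier families evaluated on the selected feature matrix,
#' configured as: NN, one hidden layer of 15 neurons with sigmoidal
#' activation; SVM with RBF kernel; k-NN with k = 5; random forest of 10
#' estimators with maximum depth 5; gradient boosting of 100 estimators
#' with learning rate 0.4. Internals the configuration leaves open (NN
#' optimiser and iteration cap, SVM cost and kernel width, GBM tree depth)
#' are fixed documented defaults.
#'
#' @param family One of `"NN"`, `"SVM"`, `"kNN"`, `"RF"`, `"GBM"`.
#' @param seed Integer seed used before every fit for reproducibility.
#' @param ... Overrides of the per-family hyperparameters listed above.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("NN", "SVM", "kNN", "RF", "GBM"),
                       seed = 1L, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    NN  = list(size = 15, decay = 0.3, maxit = 300),
    SVM = list(cost = 1, gamma = NULL),     # gamma NULL -> 1/n_features
    kNN = list(k = 5),
    RF  = list(ntree = 10, max_depth = 5),
    GBM = list(nrounds = 100, eta = 0.4, max_depth = 3))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("parameter error: unknown hyperparameter(s) ",
                        paste(bad, collapse = ", "), " for ", family)
  defaults[names(over)] <- over
  if (any(vapply(defaults, function(v) is.numeric(v) && any(v <= 0), logical(1))))
    stop("parameter error: hyperparameters must be positive")
  structure(list(family = family, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

fit_predict <- function(spec, x_train, y_train, x_test, fold_seed = 0L) {
  # y_train logical (TRUE = positive/frail); returns logical predictions
  p <- spec$params
  set.seed(spec$seed + fold_seed)
  yf <- factor(ifelse(y_train, "pos", "neg"), levels = c("neg", "pos"))
  pred <- switch(spec$family,
    NN = {
      fit <- nnet::nnet(x_train, as.numeric(y_train), size = p$size,
                        decay = p$decay, maxit = p$maxit, trace = FALSE,
                        entropy = TRUE)
      as.numeric(stats::predict(fit, x_test)) > 0.5
    },
    SVM = {
      gamma <- if (is.null(p$gamma)) 1 / ncol(x_train) else p$gamma
      fit <- e1071::svm(x_train, yf, kernel = "radial", cost = p$cost,
                        gamma = gamma)
      stats::predict(fit, x_test) == "pos"
    },
    kNN = class::knn(x_train, x_test, yf, k = p$k) == "pos",
    RF = {
      fit <- randomForest::randomForest(x_train, yf, ntree = p$ntree,
                                        maxnodes = 2^p$max_depth)
      stats::predict(fit, x_test) == "pos"
    },
    GBM = {
      dtr <- xgboost::xgb.DMatrix(x_train, label = as.numeric(y_train))
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              eta = p$eta,
                                              max_depth = p$max_depth,
                                              tree_method = "exact",
                                              nthread = 1,
                                              seed = spec$seed + fold_seed),
                                data = dtr, nrounds = p$nrounds, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(x_test)) > 0.5
    })
  as.logical(pred)
}

#' Confusion counts and derived metrics
#'
#' @param truth,pred Logical vectors (TRUE = positive/frail class).
#' @param design,model Labels carried into the report.
#' @return A one-row data frame of class `classification_report`:
#'   `model,design,TP,FP,TN,FN,sensitivity,specificity,accuracy`
#'   (percentages).
#' @export
classification_report <- function(truth, pred, design = "daily", model = "") {
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  out <- data.frame(model = model, design = design,
                    TP = tp, FP = fp, TN = tn, FN = fn,
                    sensitivity = 100 * tp / (tp + fn),
                    specificity = 100 * tn / (tn + fp),
                    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
                    stringsAsFactors = FALSE)
  class(out) <- c("classification_report", class(out))
  out
}

#' Leave-subject-out cross-validation (daily design)
#'
#' Trains on all days of all-but-one subject and predicts every day of the
#' held-out subject, cycling through the subjects; the pooled confusion
#' counts over all folds give the daily-design metrics. Missing cells are
#' median-imputed and columns scaled inside each training fold by default
#' (`fold_safe = TRUE`); `fold_safe = FALSE` reproduces whole-matrix
#' pre-scaling, which leaks test information and exists for comparison
#' only.
#'
#' @param x Numeric matrix of daily feature rows (selected columns).
#' @param labels Class label per row; `positive` marks the frail class.
#' @param subjects Subject identifier per row.
#' @param model A [model_spec()].
#' @param positive Positive-class label (default `"frail"`).
#' @param scale_method `"sigmoid"` (default), `"zscore"` or `"none"`.
#' @param fold_safe Fit scaling/imputation on training rows only (default
#'   TRUE).
#' @return A list with `report` (a [classification_report()]) and
#'   `predictions` (data frame `subject,row,truth,pred`, in input row
#'   order).
#' @export
lso_cv <- function(x, labels, subjects, model, positive = "frail",
                   scale_method = c("sigmoid", "zscore", "none"),
                   fold_safe = TRUE) {
  scale_method <- match.arg(scale_method)
  x <- as.matrix(x)
  truth <- labels == positive
  subjects <- as.character(subjects)
  per_subj <- table(unique(data.frame(subjects, truth))$truth)
  if (length(per_subj) < 2L || min(per_subj) < 2L)
    stop("insufficient-data error: need >= 2 subjects per class")
  pred <- logical(nrow(x))
  if (!fold_safe && scale_method != "none") {
    imp <- impute_median(x)
    x <- scale_features(imp$imputed, method = scale_method)$scaled
  }
  folds <- unique(subjects)
  for (f in seq_along(folds)) {
    te <- subjects == folds[f]
    xtr <- x[!te, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (fold_safe && scale_method != "none") {
      imp <- impute_median(xtr)
      sc <- scale_features(imp$imputed, method = scale_method)
      xtr <- sc$scaled
      xte <- scale_features(impute_median(xte, imp$medians)$imputed,
                            method = scale_method, params = sc$params)$scaled
      xte <- xte[, colnames(xtr), drop = FALSE]
    }
    pred[te] <- fit_predict(model, xtr, truth[!te], xte, fold_seed = f)
  }
  list(report = classification_report(truth, pred, design = "daily",
                                      model = model$family),
       predictions = data.frame(subject = subjects, row = seq_len(nrow(x)),
                                truth = truth, pred = pred,
                                stringsAsFactors = FALSE))
}

#' Average one subject's daily rows over consecutive k-day blocks
#'
#' Non-overlapping blocks of `k` consecutive (date-ordered) days collapse to
#' their mean row; a trailing remainder shorter than `k` is dropped.
#'
#' @param x Date-ordered numeric matrix of one subject's daily rows.
#' @param k Block length in days (default 5).
#' @return Matrix with one row per complete block.
#' @export
aggregate_averaging <- function(x, k = 5) {
  if (k < 1) stop("parameter error: k must be >= 1")
  x <- as.matrix(x)
  nb <- nrow(x) %/% k
  if (nb == 0L) return(x[0, , drop = FALSE])
  out <- matrix(NA_real_, nb, ncol(x), dimnames = list(NULL, colnames(x)))
  for (b in seq_len(nb))
    out[b, ] <- colMeans(x[((b - 1) * k + 1):(b * k), , drop = FALSE],
                         na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Majority vote over consecutive k-day blocks of daily predictions
#'
#' @param pred Logical vector of date-ordered daily predictions for one
#'   subject (TRUE = positive).
#' @param k Block length (default 5); a trailing remainder is dropped.
#' @param tie How to break even-`k` ties: `"positive"` (default; safer for
#'   an alerting system) or `"negative"`.
#' @return Logical vector, one element per complete block.
#' @export
aggregate_voting <- function(pred, k = 5, tie = c("positive", "negative")) {
  tie <- match.arg(tie)
  if (k < 1) stop("parameter error: k must be >= 1")
  nb <- length(pred) %/% k
  if (nb == 0L) return(logical(0))
  vapply(seq_len(nb), function(b) {
    block <- pred[((b - 1) * k + 1):(b * k)]
    pos <- sum(block)
    if (2 * pos == k) tie == "positive" else pos > k / 2
  }, logical(1))
}

#' Evaluate daily and 5-day decision designs
#'
#' Runs the daily leave-subject-out design for every supplied model, then
#' the two longitudinal designs for the models with the highest daily
#' accuracy: *averaging* (each sample fed to the daily-trained classifier
#' represents the feature means over a non-overlapping k-day block) and
#' *voting* (majority vote over the k daily predictions of each block).
#' Blocks are anchored at each subject's first recorded day; remainder
#' days are dropped. Both longitudinal designs reuse the models trained on
#' the daily rows of the other subjects, so the three designs differ only
#' in how a decision is formed from a held-out subject's days.
#'
#' @param x Daily feature matrix (selected columns).
#' @param labels,subjects Per-row class label and subject id.
#' @param dates Per-row dates (sortable); rows are date-ordered within
#'   subject before blocking.
#' @param models List of [model_spec()]s.
#' @param k Block length (default 5).
#' @param n_longitudinal How many top-accuracy models get the 5-day designs
#'   (default 3).
#' @param positive Positive-class label.
#' @param ... Passed to [lso_cv()].
#' @return Data frame of pooled [classification_report()] rows, one per
#'   (model, design).
#' @export
evaluate_designs <- function(x, labels, subjects, dates, models, k = 5,
                             n_longitudinal = 3, positive = "frail", ...) {
  x <- as.matrix(x)
  subjects <- as.character(subjects)
  ord <- order(subjects, dates)
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]; subjects <- subjects[ord]
  truth <- labels == positive

  subj_list <- split(seq_along(subjects), subjects)
  blocks <- lapply(subj_list, function(rows)
    aggregate_averaging(x[rows, , drop = FALSE], k))

  daily <- vector("list", length(models))
  reports <- NULL
  for (i in seq_along(models))
    daily[[i]] <- lso_designs(x, truth, subjects, models[[i]], blocks, ...)
  reports <- do.call(rbind, lapply(daily, function(d)
    classification_report(truth, d$daily,
                          design = "daily", model = d$family)))

  top <- order(reports$accuracy,
               decreasing = TRUE)[seq_len(min(n_longitudinal, length(models)))]
  for (i in top) {
    d <- daily[[i]]
    # averaging: the daily-trained fold models score the block means
    avg_rep <- classification_report(d$block_truth, d$block_pred,
                                     design = sprintf("averaging-%d", k),
                                     model = d$family)
    # voting: majority over the k daily predictions of each block
    vt <- list(); vtruth <- list()
    for (s in names(subj_list)) {
      rows <- subj_list[[s]]
      v <- aggregate_voting(d$daily[rows], k)
      if (length(v)) {
        vt[[s]] <- v
        vtruth[[s]] <- rep(truth[rows[1]], length(v))
      }
    }
    vote_rep <- classification_report(unlist(vtruth), unlist(vt),
                                      design = sprintf("voting-%d", k),
                                      model = d$family)
    reports <- rbind(reports, avg_rep, vote_rep)
  }
  rownames(reports) <- NULL
  reports
}

# one LSO pass: per fold, train on the other subjects' daily rows and
# predict both the held-out subject's daily rows and its k-day block means
lso_designs <- function(x, truth, subjects, model, blocks,
                        scale_method = c("sigmoid", "zscore", "none"),
                        fold_safe = TRUE) {
  scale_method <- match.arg(scale_method)
  folds <- unique(subjects)
  pred <- logical(nrow(x))
  block_pred <- list(); block_truth <- list()
  for (f in seq_along(folds)) {
    te <- subjects == folds[f]
    xtr <- x[!te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    xbl <- blocks[[folds[f]]]
    if (scale_method != "none" && fold_safe) {
      imp <- impute_median(xtr)
      sc <- scale_features(imp$imputed, method = scale_method)
      xtr <- sc$scaled
      prep <- function(z) {
        z <- scale_features(impute_median(z, imp$medians)$imputed,
                            method = scale_method, params = sc$params)$scaled
        z[, colnames(xtr), drop = FALSE]
      }
      xte <- prep(xte)
      if (nrow(xbl)) xbl <- prep(xbl)
    }
    both <- rbind(xte, xbl)
    out <- fit_predict(model, xtr, truth[!te], both, fold_seed = f)
    pred[te] <- out[seq_len(nrow(xte))]
    if (nrow(xbl)) {
      block_pred[[folds[f]]] <- out[nrow(xte) + seq_len(nrow(xbl))]
      block_truth[[folds[f]]] <- rep(truth[which(te)[1]], nrow(xbl))
    }
  }
  list(family = model$family, daily = pred,
       block_pred = unlist(block_pred), block_truth = unlist(block_truth))
}
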