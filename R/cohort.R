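#' Per-subject feature means
#'
#' Averages the daily feature matrix per subject, ignoring missing entries
#' (a subject whose feature is missing on every day keeps a missing cell,
#' with a warning). One row per distinct subject.
#'
#' @param features Daily feature data frame in the feature-CSV layout
#'   (`subject,date,G1..G9,label`).
#' @return Data frame `subject,label,G1..G9`, one row per subject.
#' @export
subject_means <- function(features) {
  if (nrow(features) == 0L) stop("empty-input error: no feature rows")
  gcols <- paste0("G", 1:9)
  subj <- unique(features$subject)
  out <- data.frame(subject = subj,
                    label = features$label[match(subj, features$subject)],
                    stringsAsFactors = FALSE)
  for (g in gcols) {
    v <- tapply(features[[g]], features$subject, mean, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    out[[g]] <- as.numeric(v[subj])
  }
  if (anyNA(out[gcols]))
    warning("some subjects have an all-missing feature; cells left NA")
  out
}

#' Z-score scaling
#'
#' `f_hat = (f - mu)/sigma`. By default `mu` and `sigma` are estimated from
#' the column itself with the population SD convention (divide by n); pass
#' `mu`/`sigma` to apply training-set parameters to held-out rows.
#'
#' @param column Numeric vector.
#' @param mu,sigma Optional pre-fit location/scale.
#' @param sd_type `"population"` (default) or `"sample"` SD convention.
#' @return Scaled vector with attributes `mu` and `sigma`.
#' @export
zscore_scale <- function(column, mu = NULL, sigma = NULL,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- column[!is.na(column)]
  if (is.null(mu)) mu <- mean(x)
  if (is.null(sigma)) {
    sigma <- stats::sd(x)
    if (sd_type == "population") sigma <- sigma * sqrt((length(x) - 1) / length(x))
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("constant-column error: zero variance")
  structure((column - mu) / sigma, mu = mu, sigma = sigma)
}

#' Sigmoid scaling
#'
#' `f_hat = 1 / (1 + exp(-(f - mu)/sigma))`: the z-score pushed through the
#' logistic function, mapping each column into (0, 1) while preserving
#' order. Exactly `logistic(zscore_scale(x))`.
#'
#' @inheritParams zscore_scale
#' @return Scaled vector in (0,1) with attributes `mu` and `sigma`.
#' @export
sigmoid_scale <- function(column, mu = NULL, sigma = NULL,
                          sd_type = c("population", "sample")) {
  z <- zscore_scale(column, mu, sigma, sd_type)
  structure(stats::plogis(as.numeric(z)),
            mu = attr(z, "mu"), sigma = attr(z, "sigma"))
}

#' Scale the columns of a feature matrix
#'
#' Fits per-column scaling parameters (or applies supplied ones) and returns
#' the scaled matrix; columns with zero variance are dropped with a warning.
#' Used with `params` from a training fold to scale test rows without
#' information leakage.
#'
#' @param x Numeric matrix or data frame of feature columns.
#' @param method `"sigmoid"` (default) or `"zscore"`.
#' @param params Optional list of per-column `c(mu, sigma)` from a previous
#'   fit.
#' @param sd_type SD convention, see [zscore_scale()].
#' @return A list with `scaled` (matrix) and `params`.
#' @export
scale_features <- function(x, method = c("sigmoid", "zscore"), params = NULL,
                           sd_type = c("population", "sample")) {
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  fun <- if (method == "sigmoid") sigmoid_scale else zscore_scale
  if (is.null(params)) {
    params <- list()
    keep <- logical(ncol(x))
    for (j in seq_len(ncol(x))) {
      res <- tryCatch(fun(x[, j], sd_type = sd_type), error = function(e) NULL)
      keep[j] <- !is.null(res)
      if (keep[j]) params[[colnames(x)[j]]] <- c(mu = attr(res, "mu"),
                                                 sigma = attr(res, "sigma"))
    }
    if (!all(keep))
      warning("dropping constant column(s): ",
              paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    pr <- params[[colnames(x)[j]]]
    out[, j] <- fun(x[, j], mu = pr[["mu"]], sigma = pr[["sigma"]])
  }
  list(scaled = out, params = params)
}

#' Rank-sum feature retention
#'
#' Runs the two-sample Wilcoxon rank-sum (Mann-Whitney) test per feature on
#' the subject-level means, frail versus robust, and retains the features
#' with `p < alpha`. The exact null distribution is used for group sizes up
#' to 10 (no ties), the normal approximation with continuity correction
#' otherwise. Constant features (no variation in either direction) get
#' `p = 1`.
#'
#' @param subject_features Data frame from [subject_means()] (or any data
#'   frame with a `label` column plus feature columns).
#' @param alpha Significance level (default 0.05).
#' @param positive Label of the frail class (default `"frail"`).
#' @param features Character vector of feature columns to test (default all
#'   `G1..G9` present).
#' @return Data frame `feature,p_value,retained`.
#' @export
rank_sum_select <- function(subject_features, alpha = 0.05,
                            positive = "frail", features = NULL) {
  lab <- subject_features$label
  if (length(unique(lab)) != 2L)
    stop("insufficient-data error: both classes must be present")
  if (min(table(lab)) < 2L)
    stop("insufficient-data error: need at least 2 subjects per class")
  if (is.null(features))
    features <- intersect(paste0("G", 1:9), names(subject_features))
  p <- vapply(features, function(g) {
    a <- subject_features[[g]][lab == positive]
    b <- subject_features[[g]][lab != positive]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b) ||
        (length(unique(c(a, b))) == 1L)) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  data.frame(feature = features, p_value = p, retained = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-component PCA
#'
#' Projects the scaled matrix onto its top-two variance-maximising
#' orthogonal directions. A deterministic sign convention is applied: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param x Scaled numeric matrix (>= 2 columns, >= 3 rows).
#' @return A list with `scores` (n x 2), `explained` (fraction of variance
#'   per retained component) and `loadings`.
#' @export
pca_2d <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("insufficient-data error: PCA needs >= 2 features and >= 3 rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  if (k < 2L) warning("rank-deficient input: fewer than 2 components")
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loadings = rot)
}

#' Median-impute missing cells of selected columns
#'
#' Missing daily values (for example the gait period G5 on days with no
#' periodic movement) are replaced by the training-set median; pass
#' `medians` to apply training medians to held-out rows.
#'
#' @param x Matrix or data frame.
#' @param medians Optional named vector of training medians.
#' @return A list with `imputed` and `medians`.
#' @export
impute_median <- function(x, medians = NULL) {
  x <- as.matrix(x)
  if (is.null(medians)) {
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[[colnames(x)[j]]]
  }
  list(imputed = x, medians = medians)
}
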