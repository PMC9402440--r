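#' Filter a replication-timing track by total signal strength
#'
#' Regions whose summed raw signal falls below the threshold carry mostly
#' noise and are removed; remaining values are left untouched.
#'
#' @param track data.frame with at least columns `signal` and `sum_signal`.
#' @param min_sum Minimum sum signal retained (default 95; regions with
#'   sum signal < 95 are removed).
#' @return The filtered data.frame.
#' @export
preprocess_replication_timing <- function(track, min_sum = 95) {
  if (!"sum_signal" %in% names(track)) stop("track must have a sum_signal column")
  track[track$sum_signal >= min_sum, , drop = FALSE]
}

#' Assemble the regression table of included bins plus sampled zero bins
#'
#' Takes the bins flagged as included for the signature under analysis and
#' appends a seeded random sample (without replacement) of zero-mutation
#' bins sized so that zero bins make up `zero_bin_fraction` of the final
#' table.
#'
#' @param bins data.frame with a `count` column and an `included` flag.
#' @param zero_bin_fraction Fraction of the final table that should be
#'   zero-count bins (default 0.10).
#' @param seed Integer seed for the sample.
#' @return data.frame of the selected rows; attribute `zero_bins_short`
#'   is TRUE when fewer zero bins existed than requested.
#' @export
assemble_regression_table <- function(bins, zero_bin_fraction = 0.10, seed = 1L) {
  stopifnot(all(c("count", "included") %in% names(bins)))
  inc <- bins[bins$included & bins$count > 0, , drop = FALSE]
  short <- FALSE
  if (zero_bin_fraction > 0) {
    zeros <- bins[bins$count == 0, , drop = FALSE]
    # n_zero such that n_zero = fraction * (n_included + n_zero)
    n_zero <- round(zero_bin_fraction * nrow(inc) / (1 - zero_bin_fraction))
    if (n_zero > nrow(zeros)) { n_zero <- nrow(zeros); short <- TRUE }
    set.seed(seed)
    pick <- zeros[sample.int(nrow(zeros), n_zero), , drop = FALSE]
    inc <- rbind(inc, pick)
  }
  rownames(inc) <- NULL
  attr(inc, "zero_bins_short") <- short
  inc
}

.spline_basis <- function(x, df = 9L) {
  splines::ns(x, df = df)
}

#' Fit a sparsity-penalized additive model of counts on feature tracks
#'
#' Each feature is expanded in a natural-spline basis (dimension 10:
#' 9 basis columns plus the model intercept) and the concatenated basis is
#' fitted to the per-bin counts with the lasso. The penalty is chosen by
#' k-fold cross-validation on a seeded training split (two-thirds of the
#' rows); a feature is selected when any of its basis coefficients is
#' non-zero at the chosen penalty. The reported R-squared is computed on
#' the full table.
#'
#' @param table data.frame with a `count` column and numeric feature
#'   columns (all non-count, non-coordinate columns are used).
#' @param features Optional character vector naming the feature columns.
#' @param folds Cross-validation folds (default 5).
#' @param train_fraction Fraction of rows used for CV (default 2/3).
#' @param seed Integer seed for the split and fold assignment.
#' @return Object of class `gam_lasso_fit`: `selected` (named logical),
#'   `r_squared`, `lambda`, the fitted glmnet object and basis metadata.
#' @export
fit_penalized_additive <- function(table, features = NULL, folds = 5L,
                                   train_fraction = 2 / 3, seed = 1L) {
  if (is.null(features)) {
    features <- setdiff(names(table),
                        c("chrom", "start", "end", "count",
                          grep("^included", names(table), value = TRUE)))
  }
  if (length(features) < 2L) stop("need at least 2 features")
  if (nrow(table) < 500L) stop("need at least 500 bins")
  X <- as.matrix(table[, features, drop = FALSE])
  dup <- duplicated(t(X))
  if (any(dup)) {
    stop("collinear (duplicated) feature columns: ",
         paste(features[dup], collapse = ", "))
  }
  y <- table$count

  bases <- lapply(features, function(f) .spline_basis(X[, f]))
  B <- do.call(cbind, bases)
  group <- rep(features, vapply(bases, ncol, 1L))

  set.seed(seed)
  n <- nrow(B)
  train <- sample.int(n, round(train_fraction * n))
  foldid <- sample(rep_len(seq_len(folds), length(train)))
  cv <- glmnet::cv.glmnet(B[train, ], y[train], foldid = foldid,
                          family = "gaussian")
  # one-standard-error rule: the sparsest model within one SE of the CV optimum
  fit <- glmnet::glmnet(B, y, family = "gaussian", lambda = cv$lambda.1se)
  beta <- as.vector(fit$beta)
  selected <- vapply(features, function(f) any(beta[group == f] != 0), TRUE)
  pred <- as.vector(stats::predict(fit, B))
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(list(selected = selected, r_squared = r2,
                 lambda = cv$lambda.min, fit = fit, features = features,
                 bases = bases, group = group),
            class = "gam_lasso_fit")
}

#' @export
print.gam_lasso_fit <- function(x, ...) {
  cat("Lasso-penalized additive model\n")
  cat(sprintf("  lambda (CV): %.4g;  R-squared (full table): %.3f\n",
              x$lambda, x$r_squared))
  cat("  selected:", paste(names(x$selected)[x$selected], collapse = ", "),
      "\n")
  invisible(x)
}

#' R-squared of a single-feature smooth regression
#'
#' Fits count ~ s(feature) with a thin-plate penalized spline (basis
#' dimension 10, mgcv) and reports the fraction of variance explained on
#' the fitted data.
#'
#' @param table data.frame with a `count` column.
#' @param feature Name of the feature column.
#' @return List: r_squared (in [0, 1]), constant flag.
#' @export
individual_feature_r2 <- function(table, feature) {
  if (!feature %in% names(table)) stop("feature not present: ", feature)
  x <- table[[feature]]
  y <- table$count
  if (stats::sd(x) < 1e-12) {
    return(list(r_squared = 0, constant = TRUE))
  }
  df <- data.frame(y = y, x = x)
  fit <- mgcv::gam(y ~ s(x, k = 10), data = df)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(r_squared = max(min(r2, 1), 0), constant = FALSE)
}

#' Rank features by individual explanatory power
#'
#' @param table data.frame with `count` and feature columns.
#' @param features Feature column names.
#' @return data.frame sorted by decreasing individual R-squared.
#' @export
rank_features_by_r2 <- function(table, features) {
  r2 <- vapply(features, function(f) individual_feature_r2(table, f)$r_squared,
               numeric(1))
  out <- data.frame(feature = features, r_squared = r2)
  out[order(-out$r_squared), ]
}
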