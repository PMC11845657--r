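#' Assemble the group-by-feature table
#'
#' Stacks per-group named feature vectors (member-level features already
#' averaged to group level upstream) into a matrix, drops features present
#' in no group, optionally imputes missing entries with the column median
#' (flagging them), and z-scores the columns (constant columns become 0).
#'
#' @param group_features named list: group id -> named numeric vector.
#' @param impute impute missing values with the column median
#'   (default `TRUE`; the LOO harness re-imputes per training fold anyway).
#' @param zscore z-score the columns (default `TRUE`).
#' @return matrix `[group, feature]` with attribute `imputed` (logical
#'   matrix of the same shape).
#' @export
build_feature_table <- function(group_features, impute = TRUE,
                                zscore = TRUE) {
  stopifnot(length(group_features) >= 1)
  feats <- unique(unlist(lapply(group_features, names)))
  X <- matrix(NA_real_, length(group_features), length(feats),
              dimnames = list(names(group_features), feats))
  for (g in seq_along(group_features)) {
    v <- group_features[[g]]
    X[g, names(v)] <- unname(v)
  }
  allna <- colSums(!is.na(X)) == 0
  if (any(allna)) {
    warning("dropping features present in no group: ",
            paste(feats[allna], collapse = ", "))
    X <- X[, !allna, drop = FALSE]
  }
  imputed <- is.na(X)
  if (impute && any(imputed)) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- stats::median(X[, j], na.rm = TRUE)
    }
  }
  if (zscore) {
    mu <- colMeans(X, na.rm = TRUE)
    sg <- apply(X, 2, stats::sd, na.rm = TRUE)
    sg[!is.finite(sg) | sg < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sg, "/")
  }
  attr(X, "imputed") <- imputed
  X
}

#' Default sparse selector: L1-penalized regression with inner CV
#'
#' Returns a selector closure for [loo_evaluate()]: lasso via
#' `glmnet::cv.glmnet` with deterministic fold assignment, selecting the
#' features with nonzero coefficients at `lambda.min`. The study's
#' FDR-controlled dummy-variable selector is intentionally not
#' re-implemented; any function `(X, y) -> integer indices` can take this
#' slot.
#'
#' @param nfolds inner CV folds (capped at the training size).
#' @return function `(X, y) -> integer vector` of selected column indices.
#' @export
selector_lasso <- function(nfolds = 10) {
  function(X, y) {
    n <- nrow(X)
    nf <- max(3L, min(nfolds, n))
    foldid <- rep_len(seq_len(nf), n)
    # glmnet warns that per-fold R2 is unavailable below 3 obs per fold
    # ("grouped=FALSE enforced"); expected at LOO training sizes
    fit <- withCallingHandlers(
      glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                        standardize = TRUE),
      warning = function(w) {
        if (grepl("grouped=FALSE", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    b <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
    unname(which(abs(b) > 1e-8))
  }
}

#' Leave-one-out evaluation with pluggable feature selection
#'
#' For each fold: impute the held-in rows by training-column medians, run
#' the selector on the training rows, fit ordinary least squares on the
#' selected columns, and predict the held-out row. Predictive R-squared is
#' pooled over the held-out predictions; explanatory R-squared comes from a
#' full-data selection and fit (all datapoints). An empty selection falls
#' back to the intercept-only model for that fold (flagged).
#'
#' @param X feature matrix `[group, feature]` (NAs allowed; imputed per
#'   fold without leakage).
#' @param y outcome vector, one per group (n >= 3).
#' @param selector function `(X, y) -> integer indices`; default
#'   [selector_lasso()].
#' @param seed integer; `set.seed(seed + fold)` precedes every selector
#'   call so stochastic selectors are reproducible.
#' @return a `loo_result`: list with `folds` (selected sets and held-out
#'   predictions), `predictions`, `r2_predictive`, `r2_explanatory`,
#'   `explanatory` (selection, coefficients, residuals, fitted),
#'   `jaccard`, `empty_folds`.
#' @export
loo_evaluate <- function(X, y, selector = selector_lasso(), seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  impute_cols <- function(M, ref = M) {
    for (j in seq_len(ncol(M))) {
      miss <- is.na(M[, j])
      if (any(miss)) M[miss, j] <- stats::median(ref[, j], na.rm = TRUE)
    }
    M
  }
  preds <- numeric(n)
  sets <- vector("list", n)
  empty <- logical(n)
  for (f in seq_len(n)) {
    tr <- setdiff(seq_len(n), f)
    Xtr <- impute_cols(X[tr, , drop = FALSE])
    Xte <- impute_cols(X[f, , drop = FALSE], ref = X[tr, , drop = FALSE])
    set.seed(seed + f)
    sel <- selector(Xtr, y[tr])
    if (length(sel) > length(tr) - 2) {
      # more features than OLS can support: keep the strongest marginals
      sc <- abs(stats::cor(Xtr[, sel, drop = FALSE], y[tr]))[, 1]
      sel <- sel[order(-sc)[seq_len(length(tr) - 2)]]
    }
    sets[[f]] <- sort(sel)
    if (!length(sel)) {
      empty[f] <- TRUE
      preds[f] <- mean(y[tr])
      next
    }
    df <- data.frame(y = y[tr], Xtr[, sel, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    nd <- as.data.frame(Xte[, sel, drop = FALSE])
    names(nd) <- names(df)[-1]
    preds[f] <- stats::predict(fit, newdata = nd)
  }
  r2_pred <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  # explanatory: full-data selection and fit
  Xfull <- impute_cols(X)
  set.seed(seed)
  sel_full <- sort(selector(Xfull, y))
  if (length(sel_full)) {
    dff <- data.frame(y = y, Xfull[, sel_full, drop = FALSE])
    fit_full <- stats::lm(y ~ ., data = dff)
    r2_exp <- 1 - sum(stats::residuals(fit_full)^2) /
      sum((y - mean(y))^2)
    expl <- list(selected = sel_full,
                 coefficients = stats::coef(fit_full),
                 residuals = stats::residuals(fit_full),
                 fitted = stats::fitted(fit_full))
  } else {
    r2_exp <- 0
    expl <- list(selected = integer(0),
                 coefficients = c(`(Intercept)` = mean(y)),
                 residuals = y - mean(y), fitted = rep(mean(y), n))
  }
  structure(list(folds = sets, predictions = preds,
                 r2_predictive = r2_pred, r2_explanatory = r2_exp,
                 explanatory = expl,
                 jaccard = jaccard_stability(sets),
                 empty_folds = which(empty)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %d folds | predictive R2 = %.3f | explanatory R2 = %.3f | Jaccard = %.3f\n",
    length(x$folds), x$r2_predictive, x$r2_explanatory, x$jaccard))
  invisible(x)
}

#' Jaccard stability of per-fold feature selections
#'
#' Mean over fold pairs of `|A n B| / |A u B|`; 1 = identical sets in every
#' fold, 0 = pairwise disjoint nonempty sets. Two empty sets count as 1.
#'
#' @param selected_sets list of integer/character vectors (>= 2).
#' @return number in `[0, 1]`.
#' @export
jaccard_stability <- function(selected_sets) {
  stopifnot(length(selected_sets) >= 2)
  pairs <- utils::combn(length(selected_sets), 2)
  mean(vapply(seq_len(ncol(pairs)), function(pi) {
    A <- selected_sets[[pairs[1, pi]]]
    B <- selected_sets[[pairs[2, pi]]]
    if (!length(A) && !length(B)) return(1)
    length(intersect(A, B)) / length(union(A, B))
  }, 0))
}

#' Regression diagnostics mirroring the standard OLS checklist
#'
#' Residual normality (Shapiro-Wilk), mean residual, serial independence
#' (Ljung-Box), and homoscedasticity (Goldfeld-Quandt, residual variance
#' ratio between the upper and lower thirds ordered by fitted value).
#' Tests whose sample-size requirements fail are reported as `NA` with a
#' note.
#'
#' @param residuals residual vector of the explanatory fit.
#' @param fitted fitted values (ordering variable for Goldfeld-Quandt);
#'   defaults to the residual order.
#' @return data.frame with columns `test`, `statistic`, `p_value`, `note`.
#' @export
regression_diagnostics <- function(residuals, fitted = NULL) {
  r <- as.numeric(residuals)
  n <- length(r)
  out <- list()
  if (n >= 3 && n <= 5000 && stats::sd(r) > 0) {
    sw <- stats::shapiro.test(r)
    out$normality <- c(sw$statistic, sw$p.value, "")
  } else out$normality <- c(NA, NA, "n outside [3, 5000] or constant")
  out$mean_residual <- c(mean(r), NA, "")
  if (n >= 5) {
    lb <- stats::Box.test(r, lag = max(1, min(10, n %/% 5)),
                          type = "Ljung-Box")
    out$independence <- c(lb$statistic, lb$p.value, "")
  } else out$independence <- c(NA, NA, "n too small")
  if (n >= 9) {
    ord <- if (is.null(fitted)) seq_len(n) else order(fitted)
    k <- n %/% 3
    lo <- r[ord][seq_len(k)]
    hi <- r[ord][(n - k + 1):n]
    f <- stats::var(hi) / stats::var(lo)
    p <- 2 * min(stats::pf(f, k - 1, k - 1),
                 1 - stats::pf(f, k - 1, k - 1))
    out$homoscedasticity <- c(f, p, "")
  } else out$homoscedasticity <- c(NA, NA, "n too small")
  data.frame(test = names(out),
             statistic = as.numeric(vapply(out, `[`, "", 1)),
             p_value = as.numeric(vapply(out, `[`, "", 2)),
             note = vapply(out, `[`, "", 3), row.names = NULL)
}
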