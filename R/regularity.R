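#' Shannon entropy of a member's 2-D PACS location distribution
#'
#' A square window of `window_area` square meters, cut into square bins of
#' `bin_size` meters a side, is centered on the member's mean PACS location;
#' frames falling outside are clipped into the border bins. The entropy of
#' the normalized 2-D histogram (base-2 by default) quantifies the spread
#' of the member's location within the group: 0 for a member pinned to one
#' bin, `log2(n_bins)` for uniform occupancy.
#'
#' @param x,y PACS coordinates of one member (equal-length vectors).
#' @param bin_size bin side, meters (default 1).
#' @param window_area window area, square meters (default 100, i.e. a
#'   10 x 10 m window = 100 one-meter bins).
#' @param base logarithm base, 2 (bits, default) or `exp(1)` (nats).
#' @return entropy in `[0, log(n_bins, base)]`.
#' @export
location_entropy <- function(x, y, bin_size = 1, window_area = 100,
                             base = 2) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 1)
  side <- sqrt(window_area)
  nb <- round(side / bin_size)
  if (abs(nb * bin_size - side) > 1e-9)
    stop("window side must be divisible by bin size")
  ix <- pmin(nb, pmax(1, floor((x - mean(x) + side / 2) / bin_size) + 1))
  iy <- pmin(nb, pmax(1, floor((y - mean(y) + side / 2) / bin_size) + 1))
  counts <- table(factor(ix + nb * (iy - 1), levels = seq_len(nb * nb)))
  .shannon(as.numeric(counts), base)
}

.shannon <- function(counts, base = 2) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Shannon entropy of a 1-D time series histogram
#'
#' Histograms the values of a series and returns the Shannon entropy of the
#' normalized histogram. For comparability across members and groups the
#' bin edges should be shared dataset-wide: pass explicit `breaks`;
#' otherwise `bins` equal-width bins over the series' own range are used.
#' A constant series occupies a single bin and has entropy 0.
#'
#' @param series numeric vector (NAs dropped).
#' @param bins number of equal-width bins when `breaks` is `NULL`
#'   (default 20).
#' @param breaks optional shared bin-edge vector; values outside are
#'   clipped into the border bins.
#' @param base logarithm base (default 2, bits).
#' @return entropy, `0 <= H <= log(bins, base)`.
#' @export
series_entropy <- function(series, bins = 20, breaks = NULL, base = 2) {
  x <- series[!is.na(series)]
  if (!length(x)) return(NA_real_)
  if (is.null(breaks)) {
    r <- range(x)
    if (diff(r) < 1e-12) return(0)
    breaks <- seq(r[1], r[2], length.out = bins + 1)
  }
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1)
  .shannon(counts, base)
}

# OLS fit of d_t ~ const + d_{t-lags} (+ exogenous), returns coefficient
# matrix or NULL on rank deficiency (unless ridge-stabilized)
.var_fit <- function(dz, order, exog = NULL, ridge = FALSE) {
  n <- nrow(dz)
  if (n <= order + 2) return(NULL)
  idx <- (order + 1):n
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(l)
    dz[idx - l, , drop = FALSE])))
  if (!is.null(exog)) X <- cbind(X, exog[idx, , drop = FALSE])
  Y <- dz[idx, , drop = FALSE]
  XtX <- crossprod(X)
  flag <- FALSE
  if (ridge || rcond(XtX) < 1e-12) {
    XtX <- XtX + diag(1e-8 * max(diag(XtX)), ncol(X))
    flag <- TRUE
  }
  B <- tryCatch(solve(XtX, crossprod(X, Y)), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  list(B = B, ridged = flag)
}

# forecast `horizon` differenced steps and re-integrate from p0
.var_forecast <- function(B, dz_hist, order, horizon, p0, exog_future = NULL) {
  hist <- dz_hist
  preds <- matrix(NA_real_, horizon, 2)
  for (hstep in seq_len(horizon)) {
    xrow <- c(1, as.vector(t(hist[nrow(hist) - seq_len(order) + 1, ,
                                  drop = FALSE])))
    if (!is.null(exog_future)) xrow <- c(xrow, exog_future[hstep, ])
    preds[hstep, ] <- as.vector(xrow %*% B)
    hist <- rbind(hist, preds[hstep, ])
  }
  sweep(apply(preds, 2, cumsum), 2, p0, "+")
}

.rolling_var <- function(pos, exog_all = NULL, window = 100, train = 95,
                         horizon = 5, order = 1, stride = horizon) {
  stopifnot(train + horizon == window)
  nT <- nrow(pos)
  if (nT < window) stop("series shorter than the rolling window")
  starts <- seq(1L, nT - window + 1L, by = stride)
  errs <- numeric(0)
  skipped <- 0L
  ridged <- FALSE
  for (a in starts) {
    tr_idx <- a:(a + train - 1L)
    te_idx <- (a + train):(a + window - 1L)
    dz <- diff(pos[tr_idx, , drop = FALSE])
    exog_tr <- exog_fut <- NULL
    if (!is.null(exog_all)) {
      # dexog row r is the exogenous difference at window position r + 1,
      # aligning 1:1 with the rows of dz
      dexog <- diff(exog_all[c(tr_idx, te_idx), , drop = FALSE])
      exog_tr <- dexog[seq_len(train - 1L), , drop = FALSE]
      exog_fut <- dexog[train:(window - 1L), , drop = FALSE]
    }
    fit <- .var_fit(dz, order, exog = exog_tr,
                    ridge = FALSE)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    ridged <- ridged || fit$ridged
    pred <- .var_forecast(fit$B, dz, order, horizon,
                          p0 = pos[a + train - 1L, ],
                          exog_future = exog_fut)
    obs <- pos[te_idx, , drop = FALSE]
    errs <- c(errs, sqrt(mean(rowSums((pred - obs)^2))))
  }
  structure(if (length(errs)) mean(errs) else NA_real_,
            skipped = skipped, n_windows = length(starts), ridged = ridged)
}

#' Rolling vector-autoregressive forecast error (movement predictability)
#'
#' Fits a VAR of the given order to the first-differenced 2-D positions of
#' one member over each rolling window (95 training samples), forecasts the
#' next 5 positions by re-integrating the predicted differences, and scores
#' the RMSE in position space; the feature is the mean over windows (which
#' advance by the horizon so forecasts do not overlap). Lower error =
#' more predictable movement.
#'
#' @param pos matrix `[time, 2]` of one member's positions (planar or
#'   PACS coordinates).
#' @param window,train,horizon rolling protocol (defaults 100/95/5;
#'   `train + horizon` must equal `window`).
#' @param order VAR order (default 1).
#' @return mean RMSE in meters, with attributes `skipped` (singular
#'   windows) and `n_windows`.
#' @export
var_error <- function(pos, window = 100, train = 95, horizon = 5,
                      order = 1) {
  .rolling_var(as.matrix(pos), NULL, window, train, horizon, order)
}

#' @rdname var_error
#' @param exog matrix `[time, 2k]` of other members' positions, column
#'   pairs per member, used (differenced) as exogenous regressors; forecast
#'   windows use the observed exogenous path.
#' @export
varx_error <- function(pos, exog, window = 100, train = 95, horizon = 5,
                       order = 1) {
  .rolling_var(as.matrix(pos), as.matrix(exog), window, train, horizon,
               order)
}
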