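# Discrimination and calibration: Mann-Whitney AUC, DeLong intervals,
# Harrell-style bootstrap optimism correction, calibration curves.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case outscores a randomly
#' chosen control, ties counted half; computed from ranks, which equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param y 0/1 outcome vector with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as.numeric(y)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

#' DeLong confidence interval for the AUC
#'
#' Placement-value (structural components) variance estimator with a
#' normal-theory interval, clipped to `[0, 1]`.
#'
#' @param scores Numeric risk scores.
#' @param y 0/1 outcomes; at least 2 cases and 2 controls.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `variance`, `lo`, `hi`, `level`.
#' @export
delong_ci <- function(scores, y, level = 0.95) {
  y <- as.numeric(y)
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  m <- length(cases); n <- length(controls)
  if (m < 2 || n < 2) {
    stop("DeLong interval needs at least 2 cases and 2 controls",
         call. = FALSE)
  }
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  # placement values: V10_i = mean_j psi(case_i, control_j), and the
  # mirror V01_j; vectorised via outer
  P <- outer(cases, controls, psi)
  v10 <- rowMeans(P)
  v01 <- colMeans(P)
  auc <- mean(P)
  variance <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  list(auc = auc, variance = variance,
       lo = max(0, auc - half), hi = min(1, auc + half), level = level)
}

# Smooth observed outcome against predicted probability and evaluate on
# a grid. Local linear smoother (lowess, f = span, no robustness
# iterations); constant predictions degenerate to the event rate.
smooth_calibration <- function(pred, y, grid, span = 0.75) {
  if (stats::sd(pred) < 1e-12) {
    return(rep(mean(y), length(grid)))
  }
  sm <- stats::lowess(pred, y, f = span, iter = 0)
  stats::approx(sm$x, sm$y, xout = grid, rule = 2, ties = mean)$y
}

#' Calibration curve and error summaries
#'
#' Smooths observed outcomes against predicted probabilities (local
#' linear smoother, span 0.75, or 10 equal-count bins) and evaluates the
#' apparent curve on an evenly spaced grid of 50 points within the
#' observed predicted-probability range. Error summaries compare the
#' curve with the ideal diagonal: `mae` (mean absolute error), `mse`,
#' and `p90_abs_error` (90th percentile of absolute error over the
#' grid).
#'
#' @param pred Predicted probabilities.
#' @param y 0/1 observed outcomes.
#' @param method `"loess"` (local linear smoother; default) or
#'   `"bins"` (10 equal-count bins, interpolated to the grid).
#' @param grid_size Number of grid points (default 50).
#' @param span Smoother span on the probability scale (default 0.75).
#' @return List with `grid`, `observed` (smoothed observed risk at the
#'   grid), `mae`, `mse`, `p90_abs_error`, `method`.
#' @export
calibration_curve <- function(pred, y, method = c("loess", "bins"),
                              grid_size = 50, span = 0.75) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (length(pred) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 20) {
    stop("calibration smoothing needs at least 20 samples", call. = FALSE)
  }
  grid <- seq(min(pred), max(pred), length.out = grid_size)
  observed <- if (method == "loess") {
    smooth_calibration(pred, y, grid, span)
  } else {
    qs <- unique(stats::quantile(pred, probs = seq(0, 1, 0.1), names = FALSE))
    bin <- cut(pred, breaks = qs, include.lowest = TRUE)
    ctr <- tapply(pred, bin, mean)
    obs <- tapply(y, bin, mean)
    stats::approx(ctr, obs, xout = grid, rule = 2, ties = mean)$y
  }
  abs_err <- abs(grid - observed)
  list(grid = grid, observed = observed,
       mae = mean(abs_err), mse = mean(abs_err^2),
       p90_abs_error = unname(stats::quantile(abs_err, 0.9)),
       method = method)
}

# Refit-on-linear-predictor recalibration: slope from a univariate
# logistic fit of y on lp; intercept from an intercept-only fit with
# slope*lp as offset.
recalibrate <- function(lp, y) {
  if (length(unique(y)) < 2 || stats::sd(lp) < 1e-12) {
    return(c(slope = NA_real_, intercept = NA_real_))
  }
  fit <- tryCatch(
    fit_logistic(matrix(lp, ncol = 1, dimnames = list(NULL, "lp")), y),
    error = function(e) NULL)
  if (is.null(fit)) return(c(slope = NA_real_, intercept = NA_real_))
  slope <- unname(fit$coefficients["lp"])
  # intercept-only Newton with offset slope*lp
  off <- slope * lp
  b0 <- 0
  for (i in 1:50) {
    mu <- stats::plogis(b0 + off)
    w <- sum(pmax(mu * (1 - mu), 1e-12))
    step <- sum(y - mu) / w
    b0 <- b0 + step
    if (abs(step) < 1e-10) break
  }
  c(slope = slope, intercept = b0)
}

#' Bootstrap optimism-corrected internal validation
#'
#' Harrell-style internal validation of a logistic model: refit on each
#' bootstrap resample, measure the drop in AUC between the resample and
#' the original sample (`optimism`), and report the apparent AUC minus
#' the mean optimism. Calibration slope and intercept follow the
#' linear-predictor recalibration convention (slope from a univariate
#' refit of the original outcomes on the bootstrap model's original-data
#' linear predictor; intercept with the slope applied as an offset),
#' averaged over resamples. The calibration curve is bias-corrected
#' pointwise by the bootstrap-estimated curve optimism. Resamples with a
#' single-class outcome or a failed fit are skipped and counted; more
#' than 20% skipped triggers a warning recorded in the report.
#'
#' @param X Predictor matrix (as for [fit_logistic()]).
#' @param y 0/1 outcomes.
#' @param B Number of bootstrap resamples (default 1000). `B = 0`
#'   returns apparent metrics with `optimism = 0`, slope 1, intercept 0.
#' @param seed Integer seed for the resampling RNG.
#' @param grid_size,span Calibration-curve controls, see
#'   [calibration_curve()].
#' @return An object of class `validation_report`: list with
#'   `apparent_auc`, `optimism`, `corrected_auc`, `calibration_slope`,
#'   `calibration_intercept`, `calibration` (grid, apparent and
#'   bias-corrected observed curves, `mae`, `mse`, `p90_abs_error`
#'   computed on the bias-corrected curve), `n_bootstrap`, `n_skipped`,
#'   `warnings`.
#' @export
bootstrap_validate <- function(X, y, B = 1000, seed = 1,
                               grid_size = 50, span = 0.75) {
  y <- as.numeric(y)
  fit0 <- fit_logistic(X, y)
  pred0 <- fit0$fitted_probabilities
  apparent_auc <- auc_mann_whitney(pred0, y)
  grid <- seq(min(pred0), max(pred0), length.out = grid_size)
  apparent_obs <- smooth_calibration(pred0, y, grid, span)

  if (B == 0) {
    abs_err <- abs(grid - apparent_obs)
    rep0 <- list(apparent_auc = apparent_auc, optimism = 0,
                 corrected_auc = apparent_auc,
                 calibration_slope = 1, calibration_intercept = 0,
                 calibration = list(grid = grid, apparent = apparent_obs,
                                    corrected = apparent_obs,
                                    mae = mean(abs_err),
                                    mse = mean(abs_err^2),
                                    p90_abs_error = unname(stats::quantile(abs_err, 0.9))),
                 n_bootstrap = 0L, n_skipped = 0L, warnings = character(0))
    return(structure(rep0, class = "validation_report"))
  }

  set.seed(seed)
  n <- length(y)
  opt_auc <- numeric(0)
  slopes <- numeric(0)
  intercepts <- numeric(0)
  curve_opt <- matrix(numeric(0), nrow = 0, ncol = grid_size)
  skipped <- 0L
  Xm <- if (is.null(X)) NULL else as.matrix(X)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2) { skipped <- skipped + 1L; next }
    Xb <- if (is.null(Xm)) NULL else Xm[idx, , drop = FALSE]
    fitb <- tryCatch(suppressWarnings(fit_logistic(Xb, yb)),
                     error = function(e) NULL)
    if (is.null(fitb) || !fitb$converged) { skipped <- skipped + 1L; next }
    pred_bb <- fitb$fitted_probabilities
    pred_bo <- predict_prob(fitb, Xm)
    opt_auc <- c(opt_auc,
                 auc_mann_whitney(pred_bb, yb) - auc_mann_whitney(pred_bo, y))
    lp_bo <- stats::qlogis(pmin(pmax(pred_bo, 1e-12), 1 - 1e-12))
    rc <- recalibrate(lp_bo, y)
    slopes <- c(slopes, rc["slope"])
    intercepts <- c(intercepts, rc["intercept"])
    # calibration-curve optimism: (boot-sample curve) - (original curve)
    # for the bootstrap model, both evaluated at the common grid
    ob_bb <- smooth_calibration(pred_bb, yb, grid, span)
    ob_bo <- smooth_calibration(pred_bo, y, grid, span)
    curve_opt <- rbind(curve_opt, ob_bb - ob_bo)
  }

  warns <- character(0)
  if (skipped > 0.2 * B) {
    warns <- c(warns, sprintf("%d of %d bootstrap resamples skipped", skipped, B))
  }
  optimism <- if (length(opt_auc)) mean(opt_auc) else 0
  corrected_obs <- apparent_obs -
    (if (nrow(curve_opt)) colMeans(curve_opt) else 0)
  abs_err <- abs(grid - corrected_obs)
  structure(list(
    apparent_auc = apparent_auc,
    optimism = optimism,
    corrected_auc = apparent_auc - optimism,
    calibration_slope = mean(slopes, na.rm = TRUE),
    calibration_intercept = mean(intercepts, na.rm = TRUE),
    calibration = list(grid = grid, apparent = apparent_obs,
                       corrected = corrected_obs,
                       mae = mean(abs_err), mse = mean(abs_err^2),
                       p90_abs_error = unname(stats::quantile(abs_err, 0.9))),
    n_bootstrap = B, n_skipped = skipped, warnings = warns
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> apparent AUC %.3f, optimism %.3f,",
                     " corrected AUC %.3f\n"),
              x$apparent_auc, x$optimism, x$corrected_auc))
  cat(sprintf("  calibration slope %.3f, intercept %.3f (B = %d, skipped %d)\n",
              x$calibration_slope, x$calibration_intercept,
              x$n_bootstrap, x$n_skipped))
  cat(sprintf("  curve MAE %.4f, MSE %.5f, p90 |err| %.4f\n",
              x$calibration$mae, x$calibration$mse,
              x$calibration$p90_abs_error))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
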