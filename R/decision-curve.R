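# Decision-curve analysis: net benefit across threshold probabilities,
# treat-all/treat-none references, optional case-control prevalence
# re-weighting.

#' Net benefit at a threshold probability
#'
#' Standard decision-analytic net benefit
#' `(TP - FP * t/(1-t)) / n` where a sample is "treated" when its
#' predicted probability is `>= t` (boundary inclusive). `t = 0` is the
#' treat-all limit and returns the event rate. Optional case weights
#' support prevalence-adjusted curves.
#'
#' @param probabilities Predicted probabilities.
#' @param y 0/1 outcomes.
#' @param threshold Threshold probability `t` in `[0, 1)`.
#' @param weights Optional non-negative per-sample weights (default 1).
#' @return Net benefit (can be negative).
#' @export
net_benefit <- function(probabilities, y, threshold, weights = NULL) {
  y <- as.numeric(y)
  if (length(probabilities) != length(y)) stop("length mismatch", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  W <- sum(weights)
  if (threshold == 0) {
    return(sum(weights * y) / W)
  }
  treated <- probabilities >= threshold
  tp <- sum(weights * (treated & y == 1))
  fp <- sum(weights * (treated & y == 0))
  (tp - fp * threshold / (1 - threshold)) / W
}

#' Decision-curve analysis over a threshold grid
#'
#' Computes net benefit for one or more models over a grid of threshold
#' probabilities (default 0 to 0.60 in steps of 0.01), together with the
#' treat-all and treat-none references. With `target_prevalence` set
#' (case-control designs), cases and controls are re-weighted so the
#' weighted event rate equals the target before computing net benefit.
#'
#' @param probabilities Numeric vector of predicted probabilities, or a
#'   named list of such vectors (one per model).
#' @param y 0/1 outcomes.
#' @param thresholds Threshold grid (default `seq(0, 0.60, 0.01)`).
#' @param standardized Logical; divide all curves by the (weighted)
#'   event rate so the treat-all curve starts at 1 (default `FALSE`).
#' @param target_prevalence Optional target population prevalence in
#'   (0, 1) for case-control re-weighting.
#' @return An object of class `decision_curve`: a data.frame with
#'   columns `threshold`, one `nb_<model>` column per model, `nb_all`,
#'   `nb_none`, plus attributes `event_rate`, `standardized`,
#'   `target_prevalence`.
#' @export
decision_curve <- function(probabilities, y,
                           thresholds = seq(0, 0.60, by = 0.01),
                           standardized = FALSE,
                           target_prevalence = NULL) {
  y <- as.numeric(y)
  if (!is.list(probabilities)) probabilities <- list(model = probabilities)
  if (is.null(names(probabilities))) {
    names(probabilities) <- paste0("model", seq_along(probabilities))
  }
  if (any(thresholds < 0 | thresholds >= 1)) {
    stop("thresholds must lie in [0, 1)", call. = FALSE)
  }
  weights <- rep(1, length(y))
  if (!is.null(target_prevalence)) {
    if (target_prevalence <= 0 || target_prevalence >= 1) {
      stop("target_prevalence must be in (0, 1)", call. = FALSE)
    }
    rate <- mean(y)
    if (rate == 0 || rate == 1) stop("need both classes", call. = FALSE)
    weights <- ifelse(y == 1, target_prevalence / rate,
                      (1 - target_prevalence) / (1 - rate))
  }
  event_rate <- sum(weights * y) / sum(weights)
  if (standardized && event_rate == 0) {
    stop("cannot standardize with zero events", call. = FALSE)
  }
  cols <- lapply(probabilities, function(p) {
    vapply(thresholds, function(t) net_benefit(p, y, t, weights), numeric(1))
  })
  nb_all <- vapply(thresholds, function(t) {
    if (t == 0) event_rate else event_rate - (1 - event_rate) * t / (1 - t)
  }, numeric(1))
  out <- data.frame(threshold = thresholds)
  for (nm in names(cols)) out[[paste0("nb_", nm)]] <- cols[[nm]]
  out$nb_all <- nb_all
  out$nb_none <- 0
  if (standardized) {
    nbcols <- setdiff(names(out), "threshold")
    out[nbcols] <- out[nbcols] / event_rate
  }
  structure(out, class = c("decision_curve", "data.frame"),
            event_rate = event_rate, standardized = standardized,
            target_prevalence = target_prevalence)
}

#' Standardize a decision curve by the event rate
#'
#' Divides every net-benefit column by the curve's (weighted) event
#' rate, so a perfect predictor scores 1 at every threshold and the
#' treat-all curve starts at 1.
#'
#' @param curve A [decision_curve()].
#' @return The standardized `decision_curve`.
#' @export
standardized_net_benefit <- function(curve) {
  stopifnot(inherits(curve, "decision_curve"))
  if (isTRUE(attr(curve, "standardized"))) return(curve)
  rate <- attr(curve, "event_rate")
  if (rate == 0) stop("cannot standardize with zero events", call. = FALSE)
  nbcols <- setdiff(names(curve), "threshold")
  curve[nbcols] <- curve[nbcols] / rate
  attr(curve, "standardized") <- TRUE
  curve
}
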