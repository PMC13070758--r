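# Points-based nomogram for a fitted logistic model: per-predictor
# point axes on a 0-100 scale, total points mapped to predicted risk.

#' Build a points-based nomogram from a logistic fit
#'
#' Converts a fitted logistic model into the usual nomogram convention:
#' for predictor `j` with coefficient `beta_j` over range
#' `[lo_j, hi_j]`, points are
#' `100 * beta_j * (x - ref_j) / maxspan` where `ref_j` is the range
#' endpoint minimising the contribution `beta_j * x` (so points are
#' always non-negative) and `maxspan = max_j |beta_j| * (hi_j - lo_j)`.
#' The predictor with the largest `|beta|*range` spans exactly 0-100.
#' Total points map to risk through the reconstructed linear predictor.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param predictor_ranges Named list of `c(lo, hi)` ranges, one per
#'   fitted predictor, covering the data.
#' @param grid_size Number of grid points per axis (default 101).
#' @return An object of class `nomogram_spec`: list with `axes` (per
#'   predictor: data.frame `value`, `points`), `total_points` map
#'   (data.frame `total_points`, `probability`), `reference` values,
#'   `points_per_unit_lp` and the underlying coefficients.
#' @export
build_nomogram <- function(fit, predictor_ranges, grid_size = 101) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  preds <- fit$predictors
  if (!length(preds)) stop("intercept-only model has no nomogram", call. = FALSE)
  if (!all(preds %in% names(predictor_ranges))) {
    stop("predictor_ranges must cover: ", paste(preds, collapse = ", "),
         call. = FALSE)
  }
  beta <- fit$coefficients[preds]
  lo <- vapply(predictor_ranges[preds], `[`, numeric(1), 1)
  hi <- vapply(predictor_ranges[preds], `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("zero-width predictor range", call. = FALSE)
  span <- abs(beta) * (hi - lo)
  maxspan <- max(span)
  # reference end: the endpoint where beta*x is smallest
  ref <- ifelse(beta >= 0, lo, hi)
  axes <- lapply(seq_along(preds), function(j) {
    v <- seq(lo[j], hi[j], length.out = grid_size)
    data.frame(value = v, points = 100 * beta[j] * (v - ref[j]) / maxspan)
  })
  names(axes) <- preds
  # total points -> probability: lp = b0 + sum(beta*ref) + maxspan/100 * pts
  base_lp <- unname(fit$coefficients["(Intercept)"] + sum(beta * ref))
  pts_grid <- seq(0, sum(100 * span / maxspan), length.out = 201)
  prob <- stats::plogis(base_lp + maxspan / 100 * pts_grid)
  structure(list(
    axes = axes,
    total_points = data.frame(total_points = pts_grid, probability = prob),
    reference = stats::setNames(ref, preds),
    base_lp = base_lp,
    points_per_unit_lp = 100 / maxspan,
    coefficients = fit$coefficients
  ), class = "nomogram_spec")
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec> axes:\n")
  for (nm in names(x$axes)) {
    ax <- x$axes[[nm]]
    cat(sprintf("  %-14s value %g..%g -> points %.1f..%.1f\n", nm,
                min(ax$value), max(ax$value),
                min(ax$points), max(ax$points)))
  }
  invisible(x)
}

#' Score an individual on a nomogram
#'
#' Per-predictor points by linear interpolation on each axis, summed to
#' total points, then mapped to predicted probability. Values outside an
#' axis range are an error unless `clamp = TRUE`, which snaps them to
#' the range ends.
#'
#' @param spec A [build_nomogram()] result.
#' @param values Named list/vector of predictor values.
#' @param clamp Clamp out-of-range values to the axis ends
#'   (default `FALSE`).
#' @return List with `points` (per predictor), `total_points`,
#'   `probability`.
#' @export
score_individual <- function(spec, values, clamp = FALSE) {
  stopifnot(inherits(spec, "nomogram_spec"))
  preds <- names(spec$axes)
  values <- unlist(values)
  if (!all(preds %in% names(values))) {
    stop("values must be named for every predictor: ",
         paste(preds, collapse = ", "), call. = FALSE)
  }
  pts <- vapply(preds, function(nm) {
    ax <- spec$axes[[nm]]
    v <- values[[nm]]
    rng <- range(ax$value)
    if (v < rng[1] || v > rng[2]) {
      if (!clamp) {
        stop(sprintf("value %g for '%s' outside axis range [%g, %g]",
                     v, nm, rng[1], rng[2]), call. = FALSE)
      }
      v <- min(max(v, rng[1]), rng[2])
    }
    stats::approx(ax$value, ax$points, xout = v, ties = mean)$y
  }, numeric(1))
  total <- sum(pts)
  prob <- stats::plogis(spec$base_lp + total / spec$points_per_unit_lp)
  list(points = pts, total_points = total, probability = prob)
}
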