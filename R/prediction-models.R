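# Maximum-likelihood logistic regression via iteratively reweighted
# least squares, with internal standardisation for numerical stability,
# plus the three model specifications used throughout the pipeline.

#' Model specifications
#'
#' The three multivariable logistic models compared by the pipeline:
#' \describe{
#'   \item{clin_only}{the concise clinical set "Clin4": age, BMI,
#'     prior GDM, fasting plasma glucose.}
#'   \item{micro_only}{the micro-balance log-ratio alone.}
#'   \item{combined}{Clin4 plus the micro-balance.}
#' }
#'
#' @param name One of `"clin_only"`, `"micro_only"`, `"combined"`.
#' @return An object of class `model_spec` with fields `name` and
#'   `predictors` (ordered).
#' @export
model_spec <- function(name = c("clin_only", "micro_only", "combined")) {
  name <- match.arg(name)
  predictors <- switch(name,
    clin_only = c("age", "bmi", "prior_gdm", "fpg"),
    micro_only = "micro_balance",
    combined = c("age", "bmi", "prior_gdm", "fpg", "micro_balance"))
  structure(list(name = name, predictors = predictors),
            class = "model_spec")
}

#' Assemble a design matrix for a model specification
#'
#' Builds the predictor matrix (without intercept column; the intercept
#' is handled inside [fit_logistic()]) from a cohort's clinical table
#' and per-sample balance values. Predictors enter linearly and
#' untransformed; `prior_gdm` is coded 0/1. Missing values are an
#' error (complete-case policy), reported with sample and field.
#'
#' @param clinical data.frame with one row per participant, containing
#'   the clinical predictor columns and `sample_id`.
#' @param spec A [model_spec()].
#' @param balance_values Named per-sample micro-balance vector (required
#'   when the spec includes `micro_balance`).
#' @return Numeric matrix, rows named by `sample_id`, columns in spec
#'   order.
#' @export
build_design <- function(clinical, spec, balance_values = NULL) {
  stopifnot(is.data.frame(clinical), inherits(spec, "model_spec"))
  ids <- as.character(clinical$sample_id)
  cols <- lapply(spec$predictors, function(p) {
    if (p == "micro_balance") {
      if (is.null(balance_values)) {
        stop("balance_values required for predictor 'micro_balance'",
             call. = FALSE)
      }
      v <- balance_values[ids]
      missing <- ids[is.na(v)]
      if (length(missing)) {
        stop("missing micro_balance for sample ", missing[1], call. = FALSE)
      }
      unname(v)
    } else {
      if (!p %in% names(clinical)) {
        stop("clinical table lacks predictor column '", p, "'",
             call. = FALSE)
      }
      v <- clinical[[p]]
      if (any(is.na(v))) {
        stop("missing value of '", p, "' for sample ",
             ids[which(is.na(v))[1]], call. = FALSE)
      }
      as.numeric(v)
    }
  })
  X <- do.call(cbind, cols)
  dimnames(X) <- list(ids, spec$predictors)
  X
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression implemented as Newton/IRLS
#' on internally standardised predictors (centred and scaled; binary
#' 0/1 columns are left untouched), with coefficients and covariance
#' back-transformed to the natural predictor scale. The covariance is
#' the inverse observed information. Convergence is declared when the
#' largest coefficient change falls below `tol`; quasi-separation is
#' flagged when any standardised coefficient magnitude exceeds
#' `separation_guard`.
#'
#' When the number of outcome events per fitted predictor drops below
#' 10 a low-EPV warning is recorded in the fit (no shrinkage is
#' applied; small-sample optimism is instead quantified by
#' [bootstrap_validate()]).
#'
#' @param X Numeric predictor matrix (no intercept column), or `NULL` /
#'   zero-column matrix for an intercept-only model.
#' @param y 0/1 outcome vector with both classes present.
#' @param tol Convergence tolerance on the max coefficient change
#'   (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param separation_guard Standardised-coefficient magnitude beyond
#'   which quasi-separation is flagged (default 15).
#' @return An object of class `logistic_fit`: list with `coefficients`
#'   (named, intercept first), `covariance`, `linear_predictors`,
#'   `fitted_probabilities`, `log_likelihood`, `converged`, `separation`,
#'   `n`, `n_events`, `epv`, `warnings`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 50,
                         separation_guard = 15) {
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (ncol(X) > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant predictor column: ",
           paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  if (length(y) < ncol(X) + 1) {
    stop("need at least p + 1 observations", call. = FALSE)
  }
  p <- ncol(X)
  nm <- c("(Intercept)", colnames(X))
  warns <- character(0)
  n_events <- sum(y)
  epv <- if (p > 0) n_events / p else Inf
  if (p > 0 && epv < 10) {
    warns <- c(warns, sprintf("low events-per-variable: %.1f", epv))
  }

  # standardise continuous columns; keep binary 0/1 columns as-is
  ctr <- rep(0, p); scl <- rep(1, p)
  if (p > 0) {
    is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    ctr[!is_binary] <- colMeans(X[, !is_binary, drop = FALSE])
    scl[!is_binary] <- apply(X[, !is_binary, drop = FALSE], 2, stats::sd)
  }
  Z <- if (p > 0) sweep(sweep(X, 2, ctr), 2, scl, "/") else X
  Z1 <- cbind(1, Z)

  beta <- rep(0, p + 1)
  converged <- FALSE
  loglik <- function(b) {
    eta <- drop(Z1 %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (it in seq_len(max_iter)) {
    eta <- drop(Z1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(Z1, Z1 * w)
    score <- crossprod(Z1, y - mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving to keep the log-likelihood non-decreasing
    ll0 <- loglik(beta)
    shrink <- 1
    repeat {
      cand <- beta + shrink * drop(step)
      if (loglik(cand) >= ll0 - 1e-12 || shrink < 1e-4) break
      shrink <- shrink / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (delta < tol) { converged <- TRUE; break }
  }
  separation <- any(abs(beta) > separation_guard)
  if (separation) {
    warns <- c(warns, "possible quasi-separation: standardised coefficient beyond guard")
  }
  if (!converged) warns <- c(warns, "IRLS did not converge")

  eta <- drop(Z1 %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(Z1, Z1 * w)
  cov_std <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p + 1, p + 1)
  })

  # back-transform: beta_nat_j = beta_std_j / s_j,
  # intercept_nat = b0 - sum(beta_std_j * m_j / s_j)
  Tm <- diag(p + 1)
  if (p > 0) {
    Tm[1, -1] <- -ctr / scl
    diag(Tm)[-1] <- 1 / scl
  }
  beta_nat <- drop(Tm %*% beta)
  cov_nat <- Tm %*% cov_std %*% t(Tm)
  names(beta_nat) <- nm
  dimnames(cov_nat) <- list(nm, nm)

  structure(list(
    coefficients = beta_nat,
    covariance = cov_nat,
    linear_predictors = stats::setNames(eta, rownames(X)),
    fitted_probabilities = stats::setNames(mu, rownames(X)),
    log_likelihood = loglik(beta),
    converged = converged,
    separation = separation,
    n = length(y), n_events = n_events, epv = epv,
    y = y,
    predictors = colnames(X),
    warnings = warns
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, events = %d, logLik = %.3f%s\n",
              x$n, x$n_events, x$log_likelihood,
              if (!x$converged) " [not converged]" else ""))
  se <- sqrt(pmax(diag(x$covariance), 0))
  print(data.frame(estimate = x$coefficients, se = se,
                   row.names = names(x$coefficients)))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Predict probabilities from a logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @param X_new New predictor matrix with the same columns (order and
#'   names) as the fitting matrix; `NULL` for intercept-only fits.
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(fit, X_new = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  p <- length(fit$coefficients) - 1
  if (p == 0) {
    n <- if (is.null(X_new)) 1 else nrow(as.matrix(X_new))
    return(rep(stats::plogis(fit$coefficients[1]), n))
  }
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != p) {
    stop("X_new must have ", p, " columns to match the fit", call. = FALSE)
  }
  if (!is.null(colnames(X_new)) && !is.null(fit$predictors) &&
      !identical(colnames(X_new), fit$predictors)) {
    stop("X_new columns do not match the fitted predictors", call. = FALSE)
  }
  eta <- drop(cbind(1, X_new) %*% fit$coefficients)
  stats::plogis(eta)
}

#' Wald 95% confidence intervals for logistic coefficients
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `estimate`, `se`, `lo`, `hi`.
#' @export
confint_wald <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(fit$covariance), 0))
  data.frame(estimate = fit$coefficients, se = se,
             lo = fit$coefficients - z * se,
             hi = fit$coefficients + z * se,
             row.names = names(fit$coefficients))
}
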