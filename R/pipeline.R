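# End-to-end orchestration: data (or synthetic cohort) -> features ->
# three logistic models -> validation -> decision curves -> nomogram,
# with machine-readable CSV/JSON outputs.

#' Pipeline configuration
#'
#' @param input_dir Directory with `clinical.csv` / `abundance.tsv`
#'   (see [read_cohort()]); `NULL` to simulate instead.
#' @param simulation A [simulation_config()] used when `input_dir` is
#'   `NULL`.
#' @param min_prevalence,min_mean_rel_abundance Taxon filter thresholds
#'   (defaults 0.15 and 0.001, see [filter_taxa()]).
#' @param balance A [balance_spec()], or `"auto"` to nominate the
#'   balance taxa from the data: filtered genera are screened against
#'   the outcome ([differential_screen()]), the top three by mean
#'   baseline abundance become the balance, and the numerator is the
#'   highest-abundance candidate enriched in the outcome-negative
#'   group (falling back to the overall top candidate).
#' @param models Character vector of [model_spec()] names to fit.
#' @param n_bootstrap Bootstrap draws for [bootstrap_validate()]
#'   (default 1000; 0 skips optimism correction).
#' @param dca_thresholds Decision-curve threshold grid.
#' @param target_prevalence Optional prevalence for case-control
#'   decision-curve re-weighting.
#' @param epsilon Balance pseudocount used in `"auto"` mode.
#' @param seed Seed for the bootstrap (and the simulation when no
#'   explicit simulation config is given).
#' @param output_dir Directory for result files; `NULL` writes nothing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = NULL,
                            min_prevalence = 0.15,
                            min_mean_rel_abundance = 0.001,
                            balance = "auto",
                            models = c("clin_only", "micro_only", "combined"),
                            n_bootstrap = 1000,
                            dca_thresholds = seq(0, 0.60, by = 0.01),
                            target_prevalence = NULL,
                            epsilon = 1e-6,
                            seed = 1,
                            output_dir = NULL) {
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (is.null(input_dir) && is.null(simulation)) {
    simulation <- simulation_config(seed = seed)
  }
  if (n_bootstrap < 0) stop("n_bootstrap must be >= 0", call. = FALSE)
  models <- match.arg(models, c("clin_only", "micro_only", "combined"),
                      several.ok = TRUE)
  structure(list(
    input_dir = input_dir, simulation = simulation,
    min_prevalence = min_prevalence,
    min_mean_rel_abundance = min_mean_rel_abundance,
    balance = balance, models = models, n_bootstrap = n_bootstrap,
    dca_thresholds = dca_thresholds,
    target_prevalence = target_prevalence,
    epsilon = epsilon, seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

# Nominate the balance from the data: screen filtered genera against
# the outcome, rank the flagged candidates by mean abundance, take the
# top three; the numerator is the highest-abundance candidate enriched
# in the outcome-negative (protective) direction. When fewer than three
# genera are flagged, the list is padded with the most abundant
# remaining genera.
auto_balance <- function(filtered, outcome, epsilon) {
  if (length(filtered$taxa) < 3) {
    stop("need at least 3 filtered taxa to nominate a balance",
         call. = FALSE)
  }
  scr <- differential_screen(
    abundance_table(filtered$values[outcome == 0, , drop = FALSE],
                    is_relative = FALSE),
    abundance_table(filtered$values[outcome == 1, , drop = FALSE],
                    is_relative = FALSE))
  flagged <- scr$taxon[scr$flagged]
  candidates <- unique(c(rank_by_mean_abundance(filtered, flagged),
                         rank_by_mean_abundance(filtered, filtered$taxa)))
  top3 <- candidates[1:3]
  # direction > 0: higher mean in the outcome-negative group
  dirs <- scr$direction[match(top3, scr$taxon)]
  protective <- top3[dirs > 0]
  numerator <- if (length(protective)) protective[1] else top3[1]
  balance_spec(numerator, setdiff(top3, numerator), epsilon = epsilon)
}

#' Run the full clinical-microbiome GDM analysis pipeline
#'
#' Stages: load or simulate the cohort; normalise counts; collapse to
#' genus; apply the prevalence/abundance filter; derive (or accept) the
#' micro-balance; fit the requested logistic models; compute AUCs with
#' DeLong intervals; bootstrap optimism-corrected validation of the
#' combined model; decision curves; nomogram of the combined model.
#' When `config$output_dir` is set, writes `features.csv`,
#' `coefficients.csv`, `filter_report.csv`, `decision_curve.csv`,
#' `nomogram_axes.csv` and `summary.json` (schema-versioned, stamped
#' with the seed).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `cohort`,
#'   `balance_spec`, `balance`, `fits`, `aucs` (per-model DeLong
#'   summaries), `validation` (combined-model [bootstrap_validate()]
#'   report), `dca`, `nomogram`, `filter_report`, `summary` (the JSON
#'   payload as a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("data", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else generate_cohort(config$simulation)
  })
  clinical <- cohort$clinical
  outcome <- clinical$gdm

  feats <- stage("features", {
    rel <- to_relative(cohort$abundances)
    gen <- collapse_to_genus(rel)
    filt <- filter_taxa(gen, config$min_prevalence,
                        config$min_mean_rel_abundance)
    bspec <- if (identical(config$balance, "auto")) {
      auto_balance(filt, outcome, config$epsilon)
    } else config$balance
    stopifnot(inherits(bspec, "balance_spec"))
    list(genus = gen, filtered = filt, bspec = bspec,
         balance = compute_balance(gen, bspec),
         report = attr(filt, "filter_report"))
  })

  fits <- stage("fit", {
    out <- list()
    for (m in config$models) {
      sp <- model_spec(m)
      X <- build_design(clinical, sp, feats$balance)
      out[[m]] <- list(spec = sp, X = X, fit = fit_logistic(X, outcome))
    }
    out
  })

  aucs <- stage("discrimination", {
    lapply(fits, function(f) {
      delong_ci(f$fit$fitted_probabilities, outcome)
    })
  })

  validation <- stage("validation", {
    key <- if ("combined" %in% names(fits)) "combined" else names(fits)[1]
    bootstrap_validate(fits[[key]]$X, outcome, B = config$n_bootstrap,
                       seed = config$seed)
  })

  dca <- stage("decision_curve", {
    probs <- lapply(fits, function(f) unname(f$fit$fitted_probabilities))
    decision_curve(probs, outcome, thresholds = config$dca_thresholds,
                   standardized = TRUE,
                   target_prevalence = config$target_prevalence)
  })

  nomo <- stage("nomogram", {
    key <- if ("combined" %in% names(fits)) "combined" else names(fits)[1]
    X <- fits[[key]]$X
    ranges <- lapply(colnames(X), function(cn) range(X[, cn]))
    names(ranges) <- colnames(X)
    # widen degenerate ranges (e.g. all-zero prior_gdm would error)
    ranges <- lapply(names(ranges), function(cn) {
      r <- ranges[[cn]]
      if (diff(r) == 0) r + c(0, 1) else r
    })
    names(ranges) <- colnames(X)
    if (fits[[key]]$fit$converged) build_nomogram(fits[[key]]$fit, ranges)
    else NULL
  })

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    n = nrow(clinical),
    n_events = sum(outcome),
    balance = list(numerator = feats$bspec$numerator,
                   denominators = feats$bspec$denominators,
                   epsilon = feats$bspec$epsilon),
    n_taxa_input = length(cohort$abundances$taxa),
    n_taxa_after_filter = length(feats$filtered$taxa),
    models = lapply(names(fits), function(m) {
      list(name = m,
           coefficients = as.list(fits[[m]]$fit$coefficients),
           auc = aucs[[m]]$auc,
           auc_ci = c(aucs[[m]]$lo, aucs[[m]]$hi))
    }),
    validation = list(
      apparent_auc = validation$apparent_auc,
      optimism = validation$optimism,
      corrected_auc = validation$corrected_auc,
      calibration_slope = validation$calibration_slope,
      calibration_intercept = validation$calibration_intercept,
      calibration_mae = validation$calibration$mae,
      calibration_mse = validation$calibration$mse,
      calibration_p90 = validation$calibration$p90_abs_error,
      n_bootstrap = validation$n_bootstrap,
      n_skipped = validation$n_skipped
    )
  )

  result <- structure(list(
    cohort = cohort, balance_spec = feats$bspec, balance = feats$balance,
    fits = fits, aucs = aucs, validation = validation, dca = dca,
    nomogram = nomo, filter_report = feats$report, summary = summary
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    stage("write", write_pipeline_outputs(result, config$output_dir))
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clinical <- result$cohort$clinical
  feats <- data.frame(sample_id = clinical$sample_id,
                      micro_balance = unname(result$balance[clinical$sample_id]),
                      gdm = clinical$gdm)
  utils::write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  coefs <- do.call(rbind, lapply(names(result$fits), function(m) {
    cf <- result$fits[[m]]$fit$coefficients
    data.frame(model = m, term = names(cf), estimate = unname(cf),
               se = sqrt(pmax(diag(result$fits[[m]]$fit$covariance), 0)))
  }))
  utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(result$filter_report,
                   file.path(dir, "filter_report.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$dca),
                   file.path(dir, "decision_curve.csv"), row.names = FALSE)
  if (!is.null(result$nomogram)) {
    axes <- do.call(rbind, lapply(names(result$nomogram$axes), function(nm) {
      cbind(predictor = nm, result$nomogram$axes[[nm]])
    }))
    utils::write.csv(axes, file.path(dir, "nomogram_axes.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> n = %d, events = %d\n",
              x$summary$n, x$summary$n_events))
  for (m in names(x$aucs)) {
    cat(sprintf("  %-10s AUC %.3f (%.3f-%.3f)\n", m, x$aucs[[m]]$auc,
                x$aucs[[m]]$lo, x$aucs[[m]]$hi))
  }
  cat(sprintf("  combined corrected AUC %.3f (B = %d)\n",
              x$validation$corrected_auc, x$validation$n_bootstrap))
  invisible(x)
}
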