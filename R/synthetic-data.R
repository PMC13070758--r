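# Seeded synthetic cohort generator: clinical predictors, zero-inflated
# Dirichlet-multinomial genus abundances, a logistic outcome on the
# clinical predictors plus the micro-balance, and OGTT triplets with an
# outcome-linked post-load shift.

# Default genus panel with rank-prefixed lineages across the dominant
# gut phyla; includes the three balance genera and one genus-free
# lineage to exercise the family-proxy collapse.
default_taxon_names <- function() {
  lin <- function(p, c, o, f, g) {
    sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s", p, c, o, f, g)
  }
  c(
    lin("Actinobacteriota", "Actinobacteria", "Bifidobacteriales",
        "Bifidobacteriaceae", "Bifidobacterium"),
    lin("Actinobacteriota", "Coriobacteriia", "Coriobacteriales",
        "Coriobacteriaceae", "Collinsella"),
    lin("Firmicutes", "Negativicutes", "Acidaminococcales",
        "Acidaminococcaceae", "Phascolarctobacterium"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Lachnoclostridium"),
    lin("Firmicutes", "Clostridia", "Oscillospirales",
        "Ruminococcaceae", "Faecalibacterium"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Blautia"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Roseburia"),
    lin("Firmicutes", "Clostridia", "Oscillospirales",
        "Ruminococcaceae", "Ruminococcus"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Dorea"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Agathobacter"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Fusicatenibacter"),
    lin("Firmicutes", "Bacilli", "Lactobacillales",
        "Lactobacillaceae", "Lactobacillus"),
    lin("Firmicutes", "Bacilli", "Lactobacillales",
        "Lactobacillaceae", "Limosilactobacillus"),
    lin("Firmicutes", "Bacilli", "Lactobacillales",
        "Streptococcaceae", "Streptococcus"),
    lin("Firmicutes", "Clostridia", "Oscillospirales",
        "Ruminococcaceae", "Subdoligranulum"),
    lin("Firmicutes", "Clostridia", "Lachnospirales",
        "Lachnospiraceae", "Anaerostipes"),
    lin("Firmicutes", "Negativicutes", "Veillonellales-Selenomonadales",
        "Veillonellaceae", "Dialister"),
    lin("Firmicutes", "Negativicutes", "Veillonellales-Selenomonadales",
        "Selenomonadaceae", "Megamonas"),
    lin("Firmicutes", "Clostridia", "Clostridiales",
        "Clostridiaceae", "Clostridium_sensu_stricto_1"),
    # genus unresolved: collapses to the family proxy f__Lachnospiraceae
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__",
    lin("Bacteroidota", "Bacteroidia", "Bacteroidales",
        "Bacteroidaceae", "Bacteroides"),
    lin("Bacteroidota", "Bacteroidia", "Bacteroidales",
        "Prevotellaceae", "Prevotella_9"),
    lin("Bacteroidota", "Bacteroidia", "Bacteroidales",
        "Tannerellaceae", "Parabacteroides"),
    lin("Bacteroidota", "Bacteroidia", "Bacteroidales",
        "Rikenellaceae", "Alistipes"),
    lin("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Escherichia-Shigella"),
    lin("Proteobacteria", "Gammaproteobacteria", "Burkholderiales",
        "Sutterellaceae", "Sutterella"),
    lin("Proteobacteria", "Gammaproteobacteria", "Burkholderiales",
        "Sutterellaceae", "Parasutterella"),
    lin("Desulfobacterota", "Desulfovibrionia", "Desulfovibrionales",
        "Desulfovibrionaceae", "Bilophila"),
    lin("Verrucomicrobiota", "Verrucomicrobiae", "Verrucomicrobiales",
        "Akkermansiaceae", "Akkermansia")
  )
}

# Mean relative abundances matched to the default panel above.
default_taxon_means <- function() {
  c(0.025, 0.010,            # Bifidobacterium, Collinsella
    0.030, 0.020, 0.080, 0.060, 0.030, 0.025, 0.020, 0.030, 0.015,
    0.006, 0.004, 0.010, 0.020, 0.012, 0.010, 0.012, 0.008,
    0.030,                   # f__Lachnospiraceae proxy
    0.180, 0.080, 0.030, 0.030,
    0.025, 0.012, 0.008,
    0.006, 0.020)
}

default_zero_inflation <- function() {
  c(0.10, 0.30,
    0.15, 0.20, 0.02, 0.05, 0.20, 0.20, 0.25, 0.20, 0.30,
    0.45, 0.50, 0.30, 0.25, 0.30, 0.35, 0.40, 0.40,
    0.05,
    0.00, 0.35, 0.15, 0.15,
    0.25, 0.35, 0.40,
    0.45, 0.35)
}

#' Simulation configuration for a synthetic GDM cohort
#'
#' Defines the cohort the generator emulates: a trial-sized group of
#' pregnant women at elevated GDM risk (default n = 98 with a target
#' event prevalence of 22/98), clinical predictors matched to the
#' baseline characteristics of such a cohort, zero-inflated
#' Dirichlet-multinomial genus abundances including *Bifidobacterium*,
#' *Phascolarctobacterium* and *Lachnoclostridium*, and an outcome
#' drawn from a logistic model on the Clin4 predictors plus the
#' micro-balance.
#'
#' @param n_participants Cohort size (>= 2); default 98.
#' @param taxon_names Lineage strings; must include genus-level entries
#'   for the three balance genera. Default: a 29-taxon gut panel.
#' @param clinical_means_sds Named list of `c(mean, sd)` for `age`
#'   (years), `bmi` (kg/m^2) and `fpg` (mmol/L).
#' @param prior_gdm_prevalence Probability of a prior-GDM history.
#' @param outcome_coefficients Named log-odds coefficients on the
#'   natural predictor scale: `intercept` (or `NA` to auto-solve so the
#'   mean outcome probability equals `target_prevalence`), `age`,
#'   `bmi`, `prior_gdm`, `fpg`, `micro_balance`.
#' @param target_prevalence Target mean outcome probability used when
#'   `intercept` is `NA`; default `22/98`.
#' @param dirichlet_concentration Positive per-taxon Dirichlet
#'   concentrations; default: the panel's mean abundances times a total
#'   concentration of 50 (moderate overdispersion).
#' @param zero_inflation Per-taxon probability of a structural zero.
#' @param library_size_range Integer `c(min, max)` read depth per
#'   sample; default `c(20000, 60000)`.
#' @param ogtt_effect Added mean post-load glucose (mmol/L) for
#'   outcome-positive subjects; default 1.8 at 1 h (and 80% of it at
#'   2 h).
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 98,
                              taxon_names = default_taxon_names(),
                              clinical_means_sds = list(
                                age = c(33, 4.5),
                                bmi = c(25.5, 3.5),
                                fpg = c(4.5, 0.45)),
                              prior_gdm_prevalence = 0.12,
                              outcome_coefficients = c(
                                intercept = NA_real_,
                                age = 0.08, bmi = 0.12, prior_gdm = 1.1,
                                fpg = 0.9, micro_balance = -0.35),
                              target_prevalence = 22 / 98,
                              dirichlet_concentration = NULL,
                              zero_inflation = NULL,
                              library_size_range = c(20000, 60000),
                              ogtt_effect = 1.8,
                              seed = 1) {
  err <- function(field, msg) {
    stop(sprintf("invalid simulation config: '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_participants) || n_participants < 2) {
    err("n_participants", "must be >= 2")
  }
  if (anyDuplicated(taxon_names)) err("taxon_names", "must be unique")
  for (g in c("Bifidobacterium", "Phascolarctobacterium",
              "Lachnoclostridium")) {
    if (!any(grepl(paste0("g__", g), taxon_names, fixed = TRUE))) {
      err("taxon_names", paste("must include genus", g))
    }
  }
  k <- length(taxon_names)
  if (is.null(dirichlet_concentration)) {
    means <- if (identical(taxon_names, default_taxon_names())) {
      default_taxon_means()
    } else {
      rep(1 / k, k)
    }
    dirichlet_concentration <- 50 * means / sum(means)
  }
  if (length(dirichlet_concentration) != k ||
      any(dirichlet_concentration <= 0)) {
    err("dirichlet_concentration", "must be positive, one per taxon")
  }
  if (is.null(zero_inflation)) {
    zero_inflation <- if (identical(taxon_names, default_taxon_names())) {
      default_zero_inflation()
    } else {
      rep(0.1, k)
    }
  }
  if (length(zero_inflation) != k || any(zero_inflation < 0) ||
      any(zero_inflation > 1)) {
    err("zero_inflation", "must be probabilities, one per taxon")
  }
  if (prior_gdm_prevalence < 0 || prior_gdm_prevalence > 1) {
    err("prior_gdm_prevalence", "must be in [0, 1]")
  }
  if (!is.na(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    err("target_prevalence", "must be in (0, 1)")
  }
  need <- c("intercept", "age", "bmi", "prior_gdm", "fpg", "micro_balance")
  if (!all(need %in% names(outcome_coefficients))) {
    err("outcome_coefficients",
        paste("must name", paste(need, collapse = ", ")))
  }
  if (is.na(outcome_coefficients["intercept"]) && is.na(target_prevalence)) {
    err("outcome_coefficients",
        "intercept NA requires a target_prevalence to solve for")
  }
  for (nm in c("age", "bmi", "fpg")) {
    v <- clinical_means_sds[[nm]]
    if (is.null(v) || length(v) != 2 || v[2] <= 0) {
      err("clinical_means_sds", paste("must give c(mean, sd>0) for", nm))
    }
  }
  library_size_range <- as.integer(library_size_range)
  if (length(library_size_range) != 2 || library_size_range[1] < 1 ||
      library_size_range[2] < library_size_range[1]) {
    err("library_size_range", "must be c(min >= 1, max >= min)")
  }
  if (!is.numeric(ogtt_effect) || !is.finite(ogtt_effect)) {
    err("ogtt_effect", "must be finite")
  }
  if (!is.numeric(seed) || !is.finite(seed)) err("seed", "must be an integer")
  structure(list(
    n_participants = as.integer(n_participants),
    taxon_names = taxon_names,
    clinical_means_sds = clinical_means_sds,
    prior_gdm_prevalence = prior_gdm_prevalence,
    outcome_coefficients = outcome_coefficients,
    target_prevalence = target_prevalence,
    dirichlet_concentration = dirichlet_concentration,
    zero_inflation = zero_inflation,
    library_size_range = library_size_range,
    ogtt_effect = ogtt_effect,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default micro-balance specification
#'
#' *Bifidobacterium* over the geometric mean of
#' *Phascolarctobacterium* and *Lachnoclostridium*, pseudocount 1e-6.
#'
#' @return A [balance_spec()].
#' @export
default_balance_spec <- function() {
  balance_spec("g__Bifidobacterium",
               c("g__Phascolarctobacterium", "g__Lachnoclostridium"),
               epsilon = 1e-6)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

#' Generate a synthetic cohort
#'
#' Draws, in a fixed stage order from a single RNG stream seeded by
#' `config$seed`: (1) clinical predictors; (2) per-sample taxon
#' proportions from a Dirichlet with per-taxon structural zeros and
#' renormalisation, then counts from a multinomial at a uniformly drawn
#' library size; (3) the micro-balance on the true (pre-count) relative
#' abundances; (4) the outcome from the logistic model on Clin4 plus
#' micro-balance (intercept solved for the target prevalence when not
#' supplied); (5) OGTT post-load glucose with the configured shift for
#' outcome-positive subjects; (6) weights and a preterm flag.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `clinical`
#'   (data.frame: sample_id, age, bmi, prior_gdm, fpg, pg1h, pg2h,
#'   weight_20w, weight_25w, gdm, preterm), `abundances` (count
#'   [abundance_table()]), and `truth` (coefficients incl. realized
#'   intercept, per-sample true probabilities, true relative
#'   abundances, balance values, seed, config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("S%04d", seq_len(n))

  # stage 1: clinical predictors
  cm <- config$clinical_means_sds
  age <- rtrunc_norm(n, cm$age[1], cm$age[2], 18)
  bmi <- rtrunc_norm(n, cm$bmi[1], cm$bmi[2], 16)
  fpg <- rtrunc_norm(n, cm$fpg[1], cm$fpg[2], 2.5)
  prior_gdm <- stats::rbinom(n, 1, config$prior_gdm_prevalence)

  # stage 2: zero-inflated Dirichlet proportions and multinomial counts
  k <- length(config$taxon_names)
  alpha <- config$dirichlet_concentration
  gam <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)),
                nrow = n, ncol = k)
  zmask <- matrix(stats::runif(n * k) < rep(config$zero_inflation, each = n),
                  nrow = n, ncol = k)
  gam[zmask] <- 0
  # a fully-zeroed sample keeps its most concentrated taxon
  dead <- which(rowSums(gam) == 0)
  for (i in dead) gam[i, which.max(alpha)] <- 1
  true_rel <- gam / rowSums(gam)
  lib <- sample(seq(config$library_size_range[1],
                    config$library_size_range[2]), n, replace = TRUE)
  counts <- t(vapply(seq_len(n), function(i) {
    drop(stats::rmultinom(1, lib[i], true_rel[i, ]))
  }, numeric(k)))
  dimnames(counts) <- list(ids, config$taxon_names)
  dimnames(true_rel) <- list(ids, config$taxon_names)

  # stage 3: micro-balance on true relative abundances
  rel_tab <- abundance_table(true_rel, ids, config$taxon_names,
                             is_relative = TRUE)
  bspec <- default_balance_spec()
  balance <- compute_balance(rel_tab, bspec)

  # stage 4: outcome from the logistic model
  beta <- config$outcome_coefficients
  lin <- beta["age"] * age + beta["bmi"] * bmi +
    beta["prior_gdm"] * prior_gdm + beta["fpg"] * fpg +
    beta["micro_balance"] * balance
  b0 <- beta["intercept"]
  if (is.na(b0)) {
    b0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + lin)) - config$target_prevalence,
      interval = c(-60, 60), tol = 1e-10)$root
  }
  p_true <- stats::plogis(b0 + lin)
  gdm <- stats::rbinom(n, 1, p_true)

  # stage 5: OGTT post-load glucose with outcome shift
  pg1h <- rtrunc_norm(n, 8.0, 1.5, 2) + config$ogtt_effect * gdm
  pg2h <- rtrunc_norm(n, 6.8, 1.5, 2) + 0.8 * config$ogtt_effect * gdm

  # stage 6: weights and preterm flag
  weight_20w <- rtrunc_norm(n, 69, 10, 40)
  weight_25w <- weight_20w + stats::rnorm(n, 2.2, 1.4)
  preterm <- stats::rbinom(n, 1, 0.06)

  clinical <- data.frame(
    sample_id = ids, age = age, bmi = bmi, prior_gdm = prior_gdm,
    fpg = fpg, pg1h = pg1h, pg2h = pg2h,
    weight_20w = weight_20w, weight_25w = weight_25w,
    gdm = gdm, preterm = preterm,
    stringsAsFactors = FALSE
  )
  truth <- list(
    coefficients = c(intercept = unname(b0),
                     beta[c("age", "bmi", "prior_gdm", "fpg",
                            "micro_balance")]),
    probabilities = stats::setNames(p_true, ids),
    true_relative = true_rel,
    balance = balance,
    seed = config$seed,
    config = config
  )
  structure(list(
    clinical = clinical,
    abundances = abundance_table(counts, ids, config$taxon_names,
                                 is_relative = FALSE),
    truth = truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, events = %d, %d taxa, seed = %d\n",
              nrow(x$clinical), sum(x$clinical$gdm),
              length(x$abundances$taxa), x$truth$seed))
  invisible(x)
}

clinical_columns <- c("sample_id", "age", "bmi", "prior_gdm", "fpg",
                      "pg1h", "pg2h", "weight_20w", "weight_25w",
                      "gdm", "preterm")

fmt_full <- function(x) {
  if (is.numeric(x) && !all(x == round(x))) sprintf("%.17g", x)
  else as.character(x)
}

#' Write a cohort to disk
#'
#' Writes the clinical table as CSV (fixed column order:
#' `sample_id,age,bmi,prior_gdm,fpg,pg1h,pg2h,weight_20w,weight_25w,gdm,preterm`),
#' the abundance table as TSV (first column `sample_id`, then one
#' column per taxon lineage), and the generating truth as JSON.
#' Numeric values are written to full precision so a read-back
#' round-trips exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths
#'   (`clinical`, `abundance`, `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.csv"),
             abundance = file.path(dir, "abundance.tsv"),
             truth = file.path(dir, "truth.json"))
  cl <- cohort$clinical[clinical_columns]
  cl_chr <- as.data.frame(lapply(cl, fmt_full), stringsAsFactors = FALSE)
  names(cl_chr) <- clinical_columns
  utils::write.table(cl_chr, paths["clinical"], sep = ",",
                     row.names = FALSE, quote = FALSE)
  ab <- cohort$abundances
  ab_df <- data.frame(sample_id = ab$sample_ids,
                      apply(ab$values, 2, fmt_full),
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(ab_df) <- c("sample_id", ab$taxa)
  utils::write.table(ab_df, paths["abundance"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    coefficients = as.list(truth$coefficients),
    seed = truth$seed,
    probabilities = as.list(truth$probabilities),
    balance = as.list(truth$balance),
    config = list(
      n_participants = truth$config$n_participants,
      target_prevalence = truth$config$target_prevalence,
      library_size_range = truth$config$library_size_range,
      ogtt_effect = truth$config$ogtt_effect,
      prior_gdm_prevalence = truth$config$prior_gdm_prevalence
    )
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

read_table_checked <- function(path, sep, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("malformed %s file '%s': line %d has %d fields, expected %d",
                 what, path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]. Validates the clinical header, the
#' uniqueness of sample identifiers, and the sample correspondence
#' between the clinical and abundance tables. Malformed files are
#' reported with the offending line; a missing outcome column is
#' reported by name.
#'
#' @param dir Directory holding `clinical.csv`, `abundance.tsv` and
#'   optionally `truth.json`.
#' @return A `synthetic_cohort` (with `truth = NULL` when no truth file
#'   is present).
#' @export
read_cohort <- function(dir) {
  cl <- read_table_checked(file.path(dir, "clinical.csv"), ",", "clinical CSV")
  missing_cols <- setdiff(clinical_columns, names(cl))
  if (length(missing_cols)) {
    stop("clinical CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cl$sample_id)) {
    stop("clinical CSV has duplicated sample id: ",
         cl$sample_id[duplicated(cl$sample_id)][1], call. = FALSE)
  }
  ab <- read_table_checked(file.path(dir, "abundance.tsv"), "\t",
                           "abundance TSV")
  if (names(ab)[1] != "sample_id") {
    stop("abundance TSV must start with a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(ab$sample_id)) {
    stop("abundance TSV has duplicated sample id: ",
         ab$sample_id[duplicated(ab$sample_id)][1], call. = FALSE)
  }
  if (!setequal(ab$sample_id, cl$sample_id)) {
    stop("clinical and abundance tables cover different samples",
         call. = FALSE)
  }
  vals <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ab$sample_id
  vals <- vals[cl$sample_id, , drop = FALSE]
  is_rel <- max(abs(rowSums(vals) - 1)) <= 1e-9
  tab <- abundance_table(vals, cl$sample_id, colnames(vals),
                         is_relative = is_rel)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(coefficients = unlist(tj$coefficients),
         probabilities = unlist(tj$probabilities),
         balance = unlist(tj$balance),
         seed = tj$seed, config = tj$config)
  } else NULL
  structure(list(clinical = cl, abundances = tab, truth = truth),
            class = "synthetic_cohort")
}
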