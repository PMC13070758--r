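# Two-group comparison statistics and the two-proportion sample-size
# calculation. Standard tests are delegated to base stats; the
# module's surface mirrors what trial tables report.

#' Two-sample t-test
#'
#' Welch (default) or pooled-variance Student t-test, two-sided. Two
#' groups with zero variance and equal means return p = 1 by
#' convention.
#'
#' @param xs,ys Numeric samples, each of length >= 2.
#' @param var_equal Pooled-variance Student test when `TRUE`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(xs, ys, var_equal = FALSE) {
  if (length(xs) < 2 || length(ys) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::sd(xs) == 0 && stats::sd(ys) == 0) {
    if (mean(xs) == mean(ys)) {
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(xs, ys, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact when the combined sample is small and
#' tie-free, otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param xs,ys Numeric samples.
#' @param exact_max Use the exact distribution when `n1 + n2` is at most
#'   this and there are no ties (default 12).
#' @return List with `U` (statistic for `xs`), `p_value`.
#' @export
mann_whitney <- function(xs, ys, exact_max = 12) {
  if (!length(xs) || !length(ys)) stop("empty sample", call. = FALSE)
  no_ties <- !anyDuplicated(c(xs, ys))
  exact <- no_ties && (length(xs) + length(ys)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(xs, ys, exact = exact,
                                            correct = !exact))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}

check_table2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  matrix(cells, nrow = 2, byrow = TRUE)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with continuity correction on the 2x2 table
#' `rbind(c(a, b), c(c, d))` (rows = groups, columns = outcome
#' yes/no). The correction is conservative: its p-value is always at
#' least the uncorrected one.
#'
#' @param a,b,c,d Cell counts.
#' @return List with `statistic`, `p_value`.
#' @export
#' @examples
#' chi2_yates(6, 44, 0, 48) # p ~ 0.0398
chi2_yates <- function(a, b, c, d) {
  tab <- check_table2x2(a, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal; use fisher_exact instead", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Uncorrected Pearson chi-square for a 2x2 table
#'
#' @inheritParams chi2_yates
#' @return List with `statistic`, `p_value`.
#' @export
chi2_pearson <- function(a, b, c, d) {
  tab <- check_table2x2(a, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal; use fisher_exact instead", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger
#' than that of the observed table.
#'
#' @inheritParams chi2_yates
#' @return List with `p_value`.
#' @export
fisher_exact <- function(a, b, c, d) {
  tab <- check_table2x2(a, b, c, d)
  list(p_value = stats::fisher.test(tab)$p.value)
}

#' Sample size for comparing two independent proportions
#'
#' Pooled-variance normal-approximation formula:
#' `n/group = (z_{a/2} * sqrt(2*pbar*qbar) + z_beta *
#' sqrt(p1*q1 + p2*q2))^2 / (p1 - p2)^2`. The unrounded per-group size
#' is always returned; the rounded totals follow the chosen convention:
#' `"ceiling"` (conservative: per-group ceiling, doubled, attrition
#' inflation rounded up) or `"nearest"` (per-group and final totals
#' rounded to the nearest integer, as trial protocols often do).
#'
#' @param p1,p2 Anticipated proportions in (0, 1), unequal.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param attrition Anticipated attrition fraction in `[0, 1)`
#'   (default 0).
#' @param rounding Rounding convention, `"ceiling"` or `"nearest"`.
#' @return List with `n_per_group` (unrounded), `n_per_group_rounded`,
#'   `n_total`, `n_total_with_attrition`.
#' @export
#' @examples
#' two_proportion_sample_size(0.35, 0.12, attrition = 0.05,
#'                            rounding = "nearest")
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.80,
                                       attrition = 0,
                                       rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  for (v in c(p1, p2, alpha, power)) {
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("p1, p2, alpha and power must lie in (0, 1)", call. = FALSE)
    }
  }
  if (p1 == p2) stop("p1 and p2 must differ", call. = FALSE)
  if (attrition < 0 || attrition >= 1) {
    stop("attrition must be in [0, 1)", call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  rnd <- if (rounding == "ceiling") ceiling else round
  n_grp <- rnd(n)
  total <- 2 * n_grp
  list(n_per_group = n,
       n_per_group_rounded = n_grp,
       n_total = total,
       n_total_with_attrition = rnd(total * (1 + attrition)))
}
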