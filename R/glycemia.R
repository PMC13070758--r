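# OGTT-derived glycemic indices, IADPSG classification, HOMA-IR and
# gestational weight-gain categories.

#' OGTT record
#'
#' Bundle the three plasma-glucose measurements of a 75-g oral glucose
#' tolerance test (OGTT) taken at 0, 1 and 2 hours.
#'
#' @param fpg Fasting plasma glucose (mmol/L).
#' @param pg1h 1-hour plasma glucose (mmol/L).
#' @param pg2h 2-hour plasma glucose (mmol/L).
#'
#' @return An object of class `ogtt_record`: a list with elements
#'   `fpg`, `pg1h`, `pg2h` and the fixed time grid `times = c(0, 1, 2)`
#'   (hours). Vector inputs of equal length are allowed and propagate
#'   through all index functions.
#' @export
#' @examples
#' ogtt_record(4.49, 8.88, 7.32)
ogtt_record <- function(fpg, pg1h, pg2h) {
  n <- length(fpg)
  if (length(pg1h) != n || length(pg2h) != n) {
    stop("fpg, pg1h and pg2h must have equal length", call. = FALSE)
  }
  for (nm in c("fpg", "pg1h", "pg2h")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be finite and positive", nm), call. = FALSE)
    }
  }
  structure(
    list(fpg = as.numeric(fpg), pg1h = as.numeric(pg1h),
         pg2h = as.numeric(pg2h), times = c(0, 1, 2)),
    class = "ogtt_record"
  )
}

as_ogtt <- function(record) {
  if (inherits(record, "ogtt_record")) return(record)
  if (is.numeric(record) && length(record) == 3) {
    return(ogtt_record(record[1], record[2], record[3]))
  }
  stop("expected an ogtt_record or a numeric triplet (fpg, pg1h, pg2h)",
       call. = FALSE)
}

#' Whole-OGTT glucose area under the curve
#'
#' Trapezoidal area under the glucose-time curve over the 0-2 h grid,
#' i.e. `0.5*fpg + pg1h + 0.5*pg2h`, in mmol*h/L. Because the trapezoid
#' is linear in the glucose values, the mean of per-subject AUCs equals
#' the AUC of the group-mean glucose values.
#'
#' @param record An [ogtt_record()] or a numeric triplet
#'   `(fpg, pg1h, pg2h)`.
#' @return Numeric AUC in mmol*h/L (vectorised over records).
#' @seealso [ogtt_iauc()], [ogtt_deltas()]
#' @export
#' @examples
#' ogtt_auc(ogtt_record(4.49, 8.88, 7.32)) # 14.785
ogtt_auc <- function(record) {
  r <- as_ogtt(record)
  0.5 * r$fpg + r$pg1h + 0.5 * r$pg2h
}

#' Incremental OGTT glucose area under the curve
#'
#' Net incremental area above the fasting baseline over 0-2 h:
#' `ogtt_auc(record) - 2*fpg`. Negative segments are not truncated, so
#' the value can be negative when post-load glucose falls below fasting;
#' this net definition keeps the identity `iAUC = AUC - 2*FPG` exact.
#'
#' @inheritParams ogtt_auc
#' @return Numeric incremental AUC in mmol*h/L.
#' @export
#' @examples
#' ogtt_iauc(ogtt_record(4.49, 8.88, 7.32)) # 5.805
ogtt_iauc <- function(record) {
  r <- as_ogtt(record)
  ogtt_auc(r) - 2 * r$fpg
}

#' Pairwise OGTT glucose excursions
#'
#' @inheritParams ogtt_auc
#' @return A data.frame with columns `d1h_fpg` (1hPG - FPG), `d2h_fpg`
#'   (2hPG - FPG) and `d1h_2h` (1hPG - 2hPG), all in mmol/L.
#' @export
ogtt_deltas <- function(record) {
  r <- as_ogtt(record)
  data.frame(d1h_fpg = r$pg1h - r$fpg,
             d2h_fpg = r$pg2h - r$fpg,
             d1h_2h  = r$pg1h - r$pg2h)
}

#' IADPSG gestational diabetes classification
#'
#' A 75-g OGTT is classified as gestational diabetes mellitus when any
#' of the IADPSG thresholds is met (inclusive): fasting glucose >= 5.1,
#' 1-hour glucose >= 10.0, or 2-hour glucose >= 8.5 mmol/L.
#'
#' Raising any glucose value can never flip a positive classification
#' back to negative (monotonicity).
#'
#' @inheritParams ogtt_auc
#' @return Logical GDM flag (vectorised over records).
#' @export
#' @examples
#' classify_gdm(ogtt_record(5.1, 6.0, 6.0))  # TRUE (fasting boundary)
#' classify_gdm(ogtt_record(5.0, 9.9, 8.4))  # FALSE
classify_gdm <- function(record) {
  r <- as_ogtt(record)
  r$fpg >= 5.1 | r$pg1h >= 10.0 | r$pg2h >= 8.5
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' Standard formulation with glucose in mmol/L and insulin in uU/mL:
#' `fpg * fasting_insulin / 22.5`.
#'
#' @param fpg Fasting plasma glucose (mmol/L), positive.
#' @param fasting_insulin Fasting serum insulin (uU/mL), positive.
#' @return Numeric HOMA-IR index.
#' @export
#' @examples
#' homa_ir(4.5, 10) # 2
homa_ir <- function(fpg, fasting_insulin) {
  if (!is.numeric(fpg) || !is.numeric(fasting_insulin) ||
      any(!is.finite(fpg)) || any(!is.finite(fasting_insulin)) ||
      any(fpg <= 0) || any(fasting_insulin <= 0)) {
    stop("fpg and fasting_insulin must be finite and positive",
         call. = FALSE)
  }
  fpg * fasting_insulin / 22.5
}

# IOM gestational weight-gain ranges (kg) by pre-pregnancy BMI class.
# Overweight ends at 29.9 and obese starts at 30; values in [29.9, 30)
# fall in the overweight class.
.iom_ranges <- list(
  underweight = c(12.5, 18),
  normal      = c(11.5, 16),
  overweight  = c(7, 11.5),
  obese       = c(5, 9)
)

iom_bmi_class <- function(pre_bmi) {
  if (pre_bmi < 18.5) "underweight"
  else if (pre_bmi < 25) "normal"
  else if (pre_bmi < 30) "overweight"
  else "obese"
}

#' IOM gestational weight-gain category
#'
#' Classify total gestational weight gain against the Institute of
#' Medicine recommended ranges for the pre-pregnancy BMI class:
#' 12.5-18 kg (underweight, BMI < 18.5), 11.5-16 kg (normal weight),
#' 7-11.5 kg (overweight), 5-9 kg (obese, BMI >= 30). Range bounds are
#' inclusive; gain below the range is "inadequate", above "excessive".
#'
#' @param pre_bmi Pre-pregnancy BMI (kg/m^2), positive.
#' @param total_gain Total gestational weight gain (kg).
#' @return Character scalar: `"inadequate"`, `"adequate"` or
#'   `"excessive"` (vectorised over inputs).
#' @export
#' @examples
#' iom_gwg_category(22.0, 13.0) # adequate
#' iom_gwg_category(31.0, 9.5)  # excessive
iom_gwg_category <- function(pre_bmi, total_gain) {
  if (!is.numeric(pre_bmi) || any(!is.finite(pre_bmi)) || any(pre_bmi <= 0)) {
    stop("pre_bmi must be finite and positive", call. = FALSE)
  }
  if (!is.numeric(total_gain) || any(!is.finite(total_gain))) {
    stop("total_gain must be finite", call. = FALSE)
  }
  n <- max(length(pre_bmi), length(total_gain))
  pre_bmi <- rep_len(pre_bmi, n)
  total_gain <- rep_len(total_gain, n)
  vapply(seq_len(n), function(i) {
    rng <- .iom_ranges[[iom_bmi_class(pre_bmi[i])]]
    if (total_gain[i] < rng[1]) "inadequate"
    else if (total_gain[i] > rng[2]) "excessive"
    else "adequate"
  }, character(1))
}
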