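# Cohort I/O: delimited-text reading with record validation, writing,
# cross-densitometer correction.

canonical_columns <- function() {
  c("id", "sex", "age", "weight", "height", "bmi", "ck", "hscrp", "ldh",
    "albumin", "ast", "lbm_dxa")
}

#' Validate subject records
#'
#' Checks every row of a cohort table against the record invariants: sex must
#' be male/female (no imputation), age and a positive weight must be present,
#' at least one of height (> 0, metres) and BMI (> 0) must be given, and any
#' biochemistry present must be non-negative. A stored BMI that disagrees with
#' `weight/height^2` by more than 0.1 kg/m^2 is reported as a warning (the
#' stored value still takes precedence for prediction).
#'
#' @param cohort data frame with canonical columns (see [read_cohort()]).
#' @return list with `valid` (logical per row) and `report` (data frame with
#'   `row`, `field`, `message`, `severity`; severity `"error"` marks the
#'   record invalid, `"warning"` does not).
#' @export
validate_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  rows <- integer(); fields <- character(); msgs <- character()
  sev <- character()
  note <- function(i, field, msg, severity = "error") {
    rows <<- c(rows, i); fields <<- c(fields, field)
    msgs <<- c(msgs, msg); sev <<- c(sev, severity)
  }
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else rep(NA, n)
  sex_raw <- col("sex")
  sex_ok <- tolower(trimws(as.character(sex_raw))) %in%
    c("m", "male", "f", "female", "0", "1")
  age <- suppressWarnings(as.numeric(col("age")))
  weight <- suppressWarnings(as.numeric(col("weight")))
  height <- suppressWarnings(as.numeric(col("height")))
  bmi <- suppressWarnings(as.numeric(col("bmi")))
  for (i in seq_len(n)) {
    if (!isTRUE(sex_ok[i])) note(i, "sex", "sex must be male or female")
    if (is.na(age[i])) note(i, "age", "age is missing")
    if (is.na(weight[i]) || weight[i] <= 0) {
      note(i, "weight", "weight must be present and positive")
    }
    h_ok <- !is.na(height[i]) && height[i] > 0
    b_ok <- !is.na(bmi[i]) && bmi[i] > 0
    if (!is.na(height[i]) && height[i] <= 0) {
      note(i, "height", "height must be positive when present")
    }
    if (!is.na(bmi[i]) && bmi[i] <= 0) {
      note(i, "bmi", "bmi must be positive when present")
    }
    if (!h_ok && !b_ok) note(i, "height/bmi", "need height or bmi")
    if (h_ok && b_ok && !is.na(weight[i]) && weight[i] > 0) {
      if (abs(bmi[i] - weight[i] / height[i]^2) > 0.1) {
        note(i, "bmi",
             "stored bmi differs from weight/height^2 by > 0.1 kg/m^2",
             "warning")
      }
    }
    for (an in c("ck", "hscrp", "ldh", "albumin", "ast")) {
      v <- suppressWarnings(as.numeric(col(an)[i]))
      if (!is.na(v) && v < 0) {
        note(i, an, sprintf("%s must be >= 0 when present", an))
      }
    }
  }
  report <- data.frame(row = rows, field = fields, message = msgs,
                       severity = sev, stringsAsFactors = FALSE)
  valid <- !(seq_len(n) %in% rows[sev == "error"])
  list(valid = valid, report = report)
}

#' Read a cohort file
#'
#' Reads a comma-separated cohort table (header row required, decimal point,
#' UTF-8) into validated subject records. Canonical columns are `id`, `sex`,
#' `age` (years), `weight` (kg), `height` (m), `bmi` (kg/m^2), `ck` (U/L),
#' `hscrp` (mg/L), `ldh` (U/L), `albumin` (g/L), `ast` (U/L) and `lbm_dxa`
#' (kg); `column_map` renames nonstandard headers onto these. BMI is
#' back-filled from weight and height when absent. Rows violating record
#' invariants are excluded from the returned cohort and listed, with row
#' numbers, in the attached validation report.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical name ->
#'   file header, e.g. `c(weight = "wt_kg")`.
#' @return data frame of valid records with attribute `"validation"` (the
#'   report of [validate_cohort()]).
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop_lbmpe(sprintf("cohort file not found: %s", path),
               "lbmpe_format_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop_lbmpe(sprintf("cannot parse '%s' as CSV: %s", path,
                         conditionMessage(e)),
                 "lbmpe_format_error")
    }
  )
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop_lbmpe(sprintf("mapped column '%s' (for '%s') not in file",
                           src, canon),
                   "lbmpe_schema_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!all(c("sex", "age", "weight") %in% names(raw))) {
    stop_lbmpe("mandatory columns sex, age, weight not all present",
               "lbmpe_schema_error")
  }
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))
  v <- validate_cohort(raw)
  cohort <- raw[v$valid, , drop = FALSE]
  rownames(cohort) <- NULL
  if (nrow(cohort)) {
    cohort$sex <- normalize_sex(cohort$sex)
    cohort <- prepare_subjects(cohort)
  }
  attr(cohort, "validation") <- v$report
  cohort
}

#' Write a cohort file
#'
#' @param cohort data frame of subject records.
#' @param path output path; comma-separated, header row, UTF-8.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(canonical_columns(), names(cohort))
  extra <- setdiff(names(cohort), cols)
  utils::write.csv(cohort[c(cols, extra)], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-densitometer linear correction
#'
#' Reference LBM measured on one densitometer can be converted to another
#' machine's equivalent with a user-supplied linear transform
#' `slope * lbm + intercept` (manufacturers' calibrations differ, so the
#' coefficients must come from a cross-calibration study; the default is the
#' identity).
#'
#' @param slope dimensionless, must be positive.
#' @param intercept kg.
#' @param source_label,target_label free-text machine labels.
#' @return a `machine_correction`.
#' @export
machine_correction <- function(slope = 1, intercept = 0,
                               source_label = "source",
                               target_label = "target") {
  assert_scalar_number(slope, "slope")
  assert_scalar_number(intercept, "intercept")
  if (slope <= 0) {
    stop_lbmpe("correction slope must be positive", "lbmpe_domain_error")
  }
  structure(list(slope = slope, intercept = intercept,
                 source_label = source_label, target_label = target_label),
            class = "machine_correction")
}

#' @export
print.machine_correction <- function(x, ...) {
  cat(sprintf("<machine_correction> %s -> %s: lbm' = %g * lbm %+g\n",
              x$source_label, x$target_label, x$slope, x$intercept))
  invisible(x)
}

#' @rdname machine_correction
#' @param lbm numeric vector of LBM values, kg.
#' @param correction a `machine_correction`.
#' @export
apply_machine_correction <- function(lbm, correction) {
  if (!inherits(correction, "machine_correction")) {
    stop_lbmpe("`correction` must be a machine_correction",
               "lbmpe_domain_error")
  }
  correction$slope * lbm + correction$intercept
}

#' @rdname machine_correction
#' @export
invert_machine_correction <- function(correction) {
  machine_correction(1 / correction$slope,
                     -correction$intercept / correction$slope,
                     source_label = correction$target_label,
                     target_label = correction$source_label)
}

#' @rdname machine_correction
#' @param cohort data frame with an `lbm_dxa` column.
#' @export
correct_cohort <- function(cohort, correction) {
  if (!"lbm_dxa" %in% names(cohort)) {
    stop_lbmpe("cohort carries no lbm_dxa column", "lbmpe_schema_error")
  }
  cohort$lbm_dxa <- apply_machine_correction(cohort$lbm_dxa, correction)
  attr(cohort, "machine_correction") <- correction
  cohort
}
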