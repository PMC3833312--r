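# Sex / age / BMI stratification and stratified agreement reports.

interval_labels <- function(breaks, unit_gap = FALSE) {
  k <- length(breaks) - 1L
  labs <- character(k)
  for (i in seq_len(k)) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    labs[i] <- if (!is.finite(hi)) {
      sprintf(">=%g", lo)
    } else if (lo <= 0 || !is.finite(lo)) {
      sprintf("<%g", hi)
    } else if (unit_gap) {
      sprintf("%g-%g", lo, hi - 1)  # integer-year style, e.g. 50-64
    } else {
      sprintf("%g-<%g", lo, hi)
    }
  }
  labs
}

#' Stratification scheme for cohort reports
#'
#' Bins are half-open `[lower, upper)`: a BMI of exactly 27 falls in
#' `"27-<30"`, an age of exactly 80 in `">=80"`. The defaults reproduce the
#' groupings used in population validation tables: BMI `<22`, `22-<27`,
#' `27-<30`, `>=30` kg/m^2 and age `50-64`, `65-79`, `>=80` years (continuous
#' ages are assigned by the half-open convention, so 64.5 belongs to `50-64`).
#'
#' @param bmi_breaks increasing break points (kg/m^2), first may be 0/-Inf,
#'   last Inf.
#' @param age_breaks increasing break points (years).
#' @param by_sex stratify by sex as well?
#' @param bmi_labels,age_labels optional labels; defaults derived from the
#'   breaks.
#' @return a `stratification_scheme`.
#' @export
stratification_scheme <- function(bmi_breaks = c(0, 22, 27, 30, Inf),
                                  age_breaks = c(50, 65, 80, Inf),
                                  by_sex = TRUE,
                                  bmi_labels = NULL, age_labels = NULL) {
  for (br in list(bmi = bmi_breaks, age = age_breaks)) {
    if (!is.null(br) && (length(br) < 2L || is.unsorted(br, strictly = TRUE))) {
      stop_lbmpe("breaks must be strictly increasing with length >= 2",
                 "lbmpe_domain_error")
    }
  }
  structure(
    list(bmi_breaks = bmi_breaks,
         bmi_labels = bmi_labels %||%
           (if (is.null(bmi_breaks)) NULL else interval_labels(bmi_breaks)),
         age_breaks = age_breaks,
         age_labels = age_labels %||%
           (if (is.null(age_breaks)) NULL
            else interval_labels(age_breaks, unit_gap = TRUE)),
         by_sex = isTRUE(by_sex)),
    class = "stratification_scheme"
  )
}

#' @export
print.stratification_scheme <- function(x, ...) {
  cat("<stratification_scheme>\n")
  if (x$by_sex) cat("  sex: men | women\n")
  if (!is.null(x$age_breaks)) {
    cat("  age (years):", paste(x$age_labels, collapse = " | "), "\n")
  }
  if (!is.null(x$bmi_breaks)) {
    cat("  BMI (kg/m^2):", paste(x$bmi_labels, collapse = " | "), "\n")
  }
  invisible(x)
}

assign_bin <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks, rightmost.closed = FALSE, left.open = FALSE)
  out <- rep(NA_character_, length(x))
  inside <- !is.na(x) & idx >= 1L & idx <= length(labels) &
    x < breaks[length(breaks)]
  out[inside] <- labels[idx[inside]]
  out
}

#' Partition a cohort into strata
#'
#' Each stratification dimension (sex, age, BMI) partitions the cohort
#' independently — every record lands in exactly one stratum per dimension, as
#' in per-gender / per-age-group / per-BMI-group validation tables. Records
#' missing a dimension's field, or falling outside its declared range, are
#' listed as unassignable for that dimension and excluded with a warning.
#'
#' @param cohort data frame of subject records.
#' @param scheme a [stratification_scheme()].
#' @return a `cohort_strata`: named list of dimensions (`sex`, `age`, `bmi`,
#'   as configured), each a named list of sub-cohorts, with an `"unassigned"`
#'   attribute giving per-dimension row indices left out.
#' @export
stratify <- function(cohort, scheme = stratification_scheme()) {
  cohort <- as.data.frame(cohort)
  dims <- list()
  unassigned <- list()
  n <- nrow(cohort)
  if (scheme$by_sex) {
    if (!"sex" %in% names(cohort)) {
      stop_lbmpe("cohort carries no sex column", "lbmpe_schema_error")
    }
    s <- normalize_sex(cohort$sex)
    dims$sex <- list(men = cohort[s == "male", , drop = FALSE],
                     women = cohort[s == "female", , drop = FALSE])
    unassigned$sex <- which(is.na(s))
  }
  bin_dim <- function(field, breaks, labels) {
    if (!field %in% names(cohort)) {
      stop_lbmpe(sprintf("cohort carries no %s column", field),
                 "lbmpe_schema_error")
    }
    lab <- assign_bin(cohort[[field]], breaks, labels)
    out <- lapply(labels, function(L) cohort[!is.na(lab) & lab == L, ,
                                             drop = FALSE])
    names(out) <- labels
    list(strata = out, unassigned = which(is.na(lab)))
  }
  if (!is.null(scheme$age_breaks)) {
    b <- bin_dim("age", scheme$age_breaks, scheme$age_labels)
    dims$age <- b$strata
    unassigned$age <- b$unassigned
  }
  if (!is.null(scheme$bmi_breaks)) {
    b <- bin_dim("bmi", scheme$bmi_breaks, scheme$bmi_labels)
    dims$bmi <- b$strata
    unassigned$bmi <- b$unassigned
  }
  dropped <- sum(lengths(unassigned))
  if (dropped > 0) {
    warn_lbmpe(
      sprintf("%d record-assignment(s) unassignable (missing or out-of-range stratification fields)",
              dropped),
      "lbmpe_unassignable_records"
    )
  }
  structure(dims, unassigned = unassigned, n = n, class = "cohort_strata")
}

#' @export
print.cohort_strata <- function(x, ...) {
  cat(sprintf("<cohort_strata> %d records\n", attr(x, "n")))
  for (dim in names(x)) {
    sizes <- vapply(x[[dim]], nrow, 0L)
    cat(sprintf("  %s: %s\n", dim,
                paste(sprintf("%s (n=%d)", names(sizes), sizes),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Stratified agreement report
#'
#' Computes the full agreement battery ([evaluate_agreement()]) for every
#' equation in every stratum of the scheme, plus the total cohort, and
#' flattens the results to one data frame shaped like a stratified validation
#' table. Empty strata yield a row with `n = 0` and `NA` statistics.
#'
#' @param cohort data frame carrying `lbm_dxa` and the predictors required by
#'   every listed equation.
#' @param equations equation names or [lbm_equation] objects.
#' @param scheme a [stratification_scheme()].
#' @param orientation Bland-Altman difference orientation (see
#'   [bland_altman()]).
#' @return data frame with columns `dimension`, `stratum`, `equation`, `n`,
#'   and the flattened agreement statistics.
#' @export
stratified_report <- function(cohort, equations = "pe1",
                              scheme = stratification_scheme(),
                              orientation = "ref_minus_pred") {
  if (!"lbm_dxa" %in% names(cohort)) {
    stop_lbmpe("cohort carries no lbm_dxa reference column",
               "lbmpe_schema_error")
  }
  eqs <- resolve_equations(equations)
  strata <- c(list(total = list(total = as.data.frame(cohort))),
              suppressWarnings(unclass(stratify(cohort, scheme))))
  empty_row <- function(dim, lab, eq, n) {
    out <- data.frame(dimension = dim, stratum = lab, equation = eq, n = n)
    for (cn in c("mean_ref", "sd_ref", "mean_pred", "sd_pred", "me", "me_lo",
                 "me_hi", "me_p", "pearson_r", "ccc", "ccc_lo", "ccc_hi",
                 "cb", "loa_lo", "loa_hi", "loa_pct_lo", "loa_pct_hi",
                 "rmse", "rmse_lo", "rmse_hi")) {
      out[[cn]] <- NA_real_
    }
    out
  }
  rows <- list()
  for (dim in names(strata)) {
    for (lab in names(strata[[dim]])) {
      sub <- strata[[dim]][[lab]]
      for (eq in eqs) {
        if (nrow(sub) < 3L) {
          rows[[length(rows) + 1L]] <- empty_row(dim, lab, eq$name, nrow(sub))
          next
        }
        pred <- as.numeric(eval_equation(eq, prepare_subjects(sub)))
        res <- evaluate_agreement(pred, sub$lbm_dxa, label = eq$name,
                                  orientation = orientation)
        df <- as.data.frame(res)
        df$label <- NULL
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(dimension = dim, stratum = lab, equation = eq$name),
          df
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a stratified report as aligned text
#'
#' @param report output of [stratified_report()].
#' @return character vector of lines, invisibly; also printed.
#' @export
render_report <- function(report) {
  fmt <- function(x, d = 2) ifelse(is.na(x), "", fmt_num(x, d))
  tab <- data.frame(
    stratum = sprintf("%s/%s", report$dimension, report$stratum),
    equation = report$equation,
    n = report$n,
    `mean (SD)` = sprintf("%s (%s)", fmt(report$mean_pred),
                          fmt(report$sd_pred)),
    `ME (95%CI)` = sprintf("%s (%s, %s)", fmt(report$me), fmt(report$me_lo),
                           fmt(report$me_hi)),
    p = ifelse(is.na(report$me_p), "",
               ifelse(report$me_p < 0.001, "<0.001", fmt(report$me_p, 3))),
    R = fmt(report$pearson_r, 3),
    `ccc (95%CI) [Cb]` = sprintf("%s (%s, %s) [%s]", fmt(report$ccc, 3),
                                 fmt(report$ccc_lo, 3), fmt(report$ccc_hi, 3),
                                 fmt(report$cb, 3)),
    `95% LoA` = sprintf("%s, %s (%s to %s%%)", fmt(report$loa_lo),
                        fmt(report$loa_hi), fmt(report$loa_pct_lo, 1),
                        fmt(report$loa_pct_hi, 1)),
    `RMSE (95%CI)` = sprintf("%s (%s, %s)", fmt(report$rmse),
                             fmt(report$rmse_lo), fmt(report$rmse_hi)),
    check.names = FALSE
  )
  lines <- utils::capture.output(print(tab, row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
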