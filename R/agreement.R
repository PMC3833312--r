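# Method-comparison battery: mean error (Sheiner-Beal bias), RMSE, Lin's
# concordance correlation, Bland-Altman limits of agreement.

check_pairs <- function(pred, ref, min_n = 2L, drop_missing = FALSE) {
  if (length(pred) != length(ref)) {
    stop_lbmpe(sprintf("pred (n=%d) and ref (n=%d) must have equal length",
                       length(pred), length(ref)),
               "lbmpe_shape_error")
  }
  keep <- !(is.na(pred) | is.na(ref))
  if (!all(keep)) {
    if (!drop_missing) {
      stop_lbmpe(
        sprintf("%d pair(s) contain missing values; set drop_missing = TRUE to delete them pairwise",
                sum(!keep)),
        "lbmpe_missing_value_error"
      )
    }
    pred <- pred[keep]
    ref <- ref[keep]
  }
  if (length(pred) < min_n) {
    stop_lbmpe(sprintf("need at least %d complete pairs, have %d",
                       min_n, length(pred)),
               "lbmpe_insufficient_data_error")
  }
  list(pred = as.numeric(pred), ref = as.numeric(ref))
}

#' Mean error (bias) of a predictor against a reference
#'
#' The mean error is `mean(pred - ref)` — positive when the predictor
#' over-estimates the reference. Its 95% confidence interval uses the normal
#' quantile 1.96 on the standard error of the differences; the interval
#' containing zero indicates an unbiased model. The p-value is the two-sided
#' paired t-test of the differences against zero.
#'
#' @param pred predicted values, kg.
#' @param ref reference (e.g. DXA) values, kg, same length.
#' @param drop_missing drop incomplete pairs instead of erroring.
#' @return list with `me`, `ci` (length-2), `p`, `sd_diff`, `n`.
#' @export
mean_error <- function(pred, ref, drop_missing = FALSE) {
  v <- check_pairs(pred, ref, 2L, drop_missing)
  d <- v$pred - v$ref
  n <- length(d)
  me <- mean(d)
  sd_d <- stats::sd(d)
  half <- 1.96 * sd_d / sqrt(n)
  p <- if (sd_d == 0) {
    if (me == 0) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  list(me = me, ci = c(me - half, me + half), p = p, sd_diff = sd_d, n = n)
}

#' Root-mean-square error with confidence interval
#'
#' Sheiner-Beal precision: `sqrt(mean((pred - ref)^2))`. The confidence
#' interval is obtained on the mean-squared-error scale
#' (`mse +/- 1.96 * se(squared errors)`) and square-rooted, with the lower
#' bound floored at zero.
#'
#' @inheritParams mean_error
#' @return list with `rmse`, `ci`, `n`.
#' @export
rmse_sheiner_beal <- function(pred, ref, drop_missing = FALSE) {
  v <- check_pairs(pred, ref, 2L, drop_missing)
  d2 <- (v$pred - v$ref)^2
  n <- length(d2)
  mse <- mean(d2)
  half <- 1.96 * stats::sd(d2) / sqrt(n)
  ci <- sqrt(pmax(0, c(mse - half, mse + half)))
  list(rmse = sqrt(mse), ci = ci, n = n)
}

#' Lin's concordance correlation coefficient
#'
#' Measures deviation of paired data from the line of identity. With
#' population (1/n) moments,
#' `ccc = 2 * cov(pred, ref) / (var(pred) + var(ref) + (mean(pred) - mean(ref))^2)`.
#' The coefficient factors exactly as `ccc = r * cb` where `r` is the Pearson
#' correlation and `cb` (the bias-correction factor, in (0, 1]) penalises
#' location and scale shift. The confidence interval applies the Fisher
#' z-transformation with Lin's (1989) asymptotic standard error.
#'
#' @inheritParams mean_error
#' @param conf confidence level for the interval.
#' @return list with `ccc`, `ci`, `pearson_r`, `cb`, `n`.
#' @export
concordance <- function(pred, ref, drop_missing = FALSE, conf = 0.95) {
  v <- check_pairs(pred, ref, 3L, drop_missing)
  x <- v$pred
  y <- v$ref
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 || sy2 == 0) {
    stop_lbmpe("concordance is undefined when either vector has zero variance",
               "lbmpe_degenerate_input_error")
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  cb <- 2 * sqrt(sx2 * sy2) / (sx2 + sy2 + (mx - my)^2)
  if (abs(ccc) >= 1) {
    # exact identity: the interval degenerates
    return(list(ccc = ccc, ci = c(ccc, ccc), pearson_r = r, cb = cb, n = n))
  }
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  z <- atanh(ccc)
  se_z2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(z + c(-1, 1) * q * sqrt(max(0, se_z2)))
  list(ccc = ccc, ci = ci, pearson_r = r, cb = cb, n = n)
}

#' Bland-Altman 95% limits of agreement
#'
#' Differences are taken as reference minus prediction by default (the
#' orientation used in published validation tables; note this is opposite in
#' sign to [mean_error()], which reports predicted minus reference). Limits
#' are `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation.
#' Percentage limits divide by the mean of the paired averages
#' `(pred + ref)/2`; this denominator is an approximation, as percentage
#' limits have no unique convention.
#'
#' @inheritParams mean_error
#' @param orientation `"ref_minus_pred"` (default) or `"pred_minus_ref"`.
#' @return list with `loa` (length-2), `loa_pct`, `mean_diff`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pred, ref,
                         orientation = c("ref_minus_pred", "pred_minus_ref"),
                         drop_missing = FALSE) {
  orientation <- match.arg(orientation)
  v <- check_pairs(pred, ref, 2L, drop_missing)
  d <- switch(orientation,
              ref_minus_pred = v$ref - v$pred,
              pred_minus_ref = v$pred - v$ref)
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  denom <- mean((v$pred + v$ref) / 2)
  list(loa = loa, loa_pct = 100 * loa / denom, mean_diff = m, sd_diff = s,
       n = length(d))
}

#' Full agreement battery for one predictor against a reference
#'
#' Composes [mean_error()], [rmse_sheiner_beal()], [concordance()] and
#' [bland_altman()] into one validation-table row.
#'
#' @inheritParams bland_altman
#' @param label name for the predictor column (used in printing).
#' @return an `agreement_result`: list with `n`, `mean_ref`, `sd_ref`,
#'   `mean_pred`, `sd_pred`, `me`, `me_ci`, `me_p`, `pearson_r`, `ccc`,
#'   `ccc_ci`, `cb`, `loa`, `loa_pct`, `rmse`, `rmse_ci`, `orientation`,
#'   `label`. Cross-field identities hold exactly: `ccc = pearson_r * cb`,
#'   `rmse^2 = me^2 + population variance of the errors`, and the midpoint of
#'   `loa` is the mean difference under the chosen orientation.
#' @export
evaluate_agreement <- function(pred, ref, label = "prediction",
                               orientation = c("ref_minus_pred",
                                               "pred_minus_ref"),
                               drop_missing = FALSE) {
  orientation <- match.arg(orientation)
  v <- check_pairs(pred, ref, 3L, drop_missing)
  me <- mean_error(v$pred, v$ref)
  cc <- concordance(v$pred, v$ref)
  ba <- bland_altman(v$pred, v$ref, orientation)
  rm <- rmse_sheiner_beal(v$pred, v$ref)
  structure(
    list(n = length(v$pred),
         mean_ref = mean(v$ref), sd_ref = stats::sd(v$ref),
         mean_pred = mean(v$pred), sd_pred = stats::sd(v$pred),
         me = me$me, me_ci = me$ci, me_p = me$p,
         pearson_r = cc$pearson_r, ccc = cc$ccc, ccc_ci = cc$ci, cb = cc$cb,
         loa = ba$loa, loa_pct = ba$loa_pct,
         rmse = rm$rmse, rmse_ci = rm$ci,
         orientation = orientation, label = label),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s vs reference (n = %d)\n", x$label, x$n))
  cat(sprintf("  mean (SD): ref %s (%s), pred %s (%s) kg\n",
              fmt_num(x$mean_ref, 2), fmt_num(x$sd_ref, 2),
              fmt_num(x$mean_pred, 2), fmt_num(x$sd_pred, 2)))
  cat(sprintf("  ME (pred - ref): %s (%s, %s) kg, p = %s\n",
              fmt_num(x$me, 2), fmt_num(x$me_ci[1], 2),
              fmt_num(x$me_ci[2], 2), format.pval(x$me_p, digits = 3)))
  cat(sprintf("  R = %s, ccc = %s (%s, %s) [Cb = %s]\n",
              fmt_num(x$pearson_r, 3), fmt_num(x$ccc, 3),
              fmt_num(x$ccc_ci[1], 3), fmt_num(x$ccc_ci[2], 3),
              fmt_num(x$cb, 3)))
  cat(sprintf("  95%% LoA (%s): %s, %s kg (%s to %s%%)\n",
              x$orientation, fmt_num(x$loa[1], 2), fmt_num(x$loa[2], 2),
              fmt_num(x$loa_pct[1], 1), fmt_num(x$loa_pct[2], 1)))
  cat(sprintf("  RMSE: %s (%s, %s) kg\n", fmt_num(x$rmse, 2),
              fmt_num(x$rmse_ci[1], 2), fmt_num(x$rmse_ci[2], 2)))
  invisible(x)
}

#' Flatten agreement results to a one-row data frame
#'
#' @param x an `agreement_result`.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return one-row data frame mirroring the validation-table columns.
#' @export
as.data.frame.agreement_result <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    label = x$label, n = x$n,
    mean_ref = x$mean_ref, sd_ref = x$sd_ref,
    mean_pred = x$mean_pred, sd_pred = x$sd_pred,
    me = x$me, me_lo = x$me_ci[1], me_hi = x$me_ci[2], me_p = x$me_p,
    pearson_r = x$pearson_r,
    ccc = x$ccc, ccc_lo = x$ccc_ci[1], ccc_hi = x$ccc_ci[2], cb = x$cb,
    loa_lo = x$loa[1], loa_hi = x$loa[2],
    loa_pct_lo = x$loa_pct[1], loa_pct_hi = x$loa_pct[2],
    rmse = x$rmse, rmse_lo = x$rmse_ci[1], rmse_hi = x$rmse_ci[2],
    stringsAsFactors = FALSE
  )
}

#' Format an agreement result as a report row
#'
#' Renders the standard validation-table layout: Mean (SD) | Mean error
#' (95% CI) | p | R | ccc (95% CI) [Cb] | 95% limits of agreement |
#' RMSE (95% CI).
#'
#' @param x an `agreement_result`.
#' @return character vector of formatted cells.
#' @export
format_agreement_row <- function(x) {
  c(`Mean (SD), kg` = sprintf("%s (%s)", fmt_num(x$mean_pred, 2),
                              fmt_num(x$sd_pred, 2)),
    `Mean error (95%CI), kg` = sprintf("%s (%s, %s)", fmt_num(x$me, 2),
                                       fmt_num(x$me_ci[1], 2),
                                       fmt_num(x$me_ci[2], 2)),
    `P` = format.pval(x$me_p, digits = 3),
    `R` = fmt_num(x$pearson_r, 3),
    `ccc (95% CI) [Cb]` = sprintf("%s (%s, %s) [%s]", fmt_num(x$ccc, 3),
                                  fmt_num(x$ccc_ci[1], 3),
                                  fmt_num(x$ccc_ci[2], 3), fmt_num(x$cb, 3)),
    `95% limits of agreement` = sprintf("%s, %s (%s to %s%%)",
                                        fmt_num(x$loa[1], 2),
                                        fmt_num(x$loa[2], 2),
                                        fmt_num(x$loa_pct[1], 1),
                                        fmt_num(x$loa_pct[2], 1)),
    `RMSE (95% CI), kg` = sprintf("%s (%s, %s)", fmt_num(x$rmse, 2),
                                  fmt_num(x$rmse_ci[1], 2),
                                  fmt_num(x$rmse_ci[2], 2)))
}
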