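# Equation development: OLS fitting and exhaustive best-subset search ranked
# by adjusted R-squared.

# Convert a predictor table to a numeric design data.frame (sex -> 0/1 male
# indicator), preserving column names.
design_frame <- function(predictors) {
  predictors <- as.data.frame(predictors)
  for (nm in names(predictors)) {
    if (nm == "sex" && !is.numeric(predictors[[nm]])) {
      predictors[[nm]] <- sex_indicator(predictors[[nm]])
    }
    if (!is.numeric(predictors[[nm]])) {
      stop_lbmpe(sprintf("predictor '%s' is not numeric", nm),
                 "lbmpe_domain_error")
    }
  }
  predictors
}

#' Ordinary least squares fit with SEE and adjusted R-squared
#'
#' Fits `y ~ predictors` by least squares and reports the quantities used to
#' rank candidate prediction equations: the coefficient of determination
#' `R2 = 1 - SSE/SST` (in percent), its adjusted version
#' `1 - (1 - R2) (n - 1)/(n - p - 1)`, and the standard error of the estimate
#' `SEE = sqrt(SSE / (n - p - 1))` in kg.
#'
#' @param y response vector (reference LBM, kg).
#' @param predictors data frame of candidate predictors; a character `sex`
#'   column is encoded as a male = 1, female = 0 indicator.
#' @return an `ols_fit`: list with `coefficients` (including `(Intercept)`),
#'   `r2` and `adjusted_r2` (percent), `see` (kg), `n_obs`, `p` and
#'   `predictors`.
#' @export
fit_ols <- function(y, predictors) {
  X <- design_frame(predictors)
  n <- length(y)
  p <- ncol(X)
  if (p < 1L) {
    stop_lbmpe("at least one predictor is required", "lbmpe_domain_error")
  }
  if (nrow(X) != n) {
    stop_lbmpe("response and predictors have different numbers of rows",
               "lbmpe_shape_error")
  }
  if (anyNA(y) || anyNA(X)) {
    stop_lbmpe("missing values in response or predictors", "lbmpe_missing_value_error")
  }
  if (n <= p + 1L) {
    stop_lbmpe(sprintf("need more than p + 1 = %d observations, have %d",
                       p + 1L, n),
               "lbmpe_insufficient_data_error")
  }
  df <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop_lbmpe(
      sprintf("design is rank deficient; collinear column(s): %s",
              paste(names(coefs)[is.na(coefs)], collapse = ", ")),
      "lbmpe_collinearity_error"
    )
  }
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(
    list(coefficients = coefs,
         r2 = 100 * r2, adjusted_r2 = 100 * adj,
         see = sqrt(sse / (n - p - 1)),
         n_obs = n, p = p, predictors = names(X)),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %d obs, %d predictor(s): %s\n", x$n_obs, x$p,
              paste(x$predictors, collapse = ", ")))
  print(round(x$coefficients, 6))
  cat(sprintf("  R2 = %s%%  adj R2 = %s%%  SEE = %s kg\n",
              fmt_num(x$r2, 2), fmt_num(x$adjusted_r2, 2), fmt_num(x$see, 3)))
  invisible(x)
}

subset_key <- function(predictors) paste(sort(predictors), collapse = ",")

#' Exhaustive best-subset regression
#'
#' Enumerates every subset of the candidate predictors of each size
#' `1..max_size`, fits each by OLS, and ranks the fits within each size by
#' adjusted R-squared (descending). Ties are broken deterministically by the
#' lexicographic order of the sorted predictor names. Rank-deficient subsets
#' are skipped with a warning and recorded, never fatal. No stepwise
#' shortcuts are taken: with k candidates, all `choose(k, size)` subsets per
#' size are fitted.
#'
#' @param y response vector (reference LBM, kg).
#' @param candidates data frame of candidate predictors (see [fit_ols()]).
#' @param max_size largest subset size to consider; must not exceed the number
#'   of candidates.
#' @param top_k number of top-ranked candidate equations retained per size.
#' @return a `best_subsets` object: list with `sizes` (one entry per subset
#'   size, each a ranked list of fits carrying `predictors`, `coefficients`,
#'   `r2`, `adjusted_r2`, `see`), `skipped` (character vector of skipped
#'   subsets), `n_obs`, `candidates`.
#' @export
best_subsets <- function(y, candidates, max_size = 6L, top_k = 6L) {
  X <- design_frame(candidates)
  k <- ncol(X)
  if (k < 1L) {
    stop_lbmpe("candidate set must be nonempty", "lbmpe_domain_error")
  }
  if (max_size > k || max_size < 1L) {
    stop_lbmpe(sprintf("max_size must be in 1..%d", k), "lbmpe_domain_error")
  }
  skipped <- character()
  sizes <- vector("list", max_size)
  for (size in seq_len(max_size)) {
    combos <- utils::combn(names(X), size, simplify = FALSE)
    fits <- list()
    for (combo in combos) {
      fit <- tryCatch(fit_ols(y, X[combo]),
                      lbmpe_collinearity_error = function(e) e)
      if (inherits(fit, "condition")) {
        skipped <- c(skipped, subset_key(combo))
        next
      }
      fits[[length(fits) + 1L]] <- list(
        predictors = combo,
        coefficients = fit$coefficients,
        r2 = fit$r2, adjusted_r2 = fit$adjusted_r2, see = fit$see
      )
    }
    if (length(fits)) {
      adj <- vapply(fits, `[[`, 0, "adjusted_r2")
      keys <- vapply(fits, function(f) subset_key(f$predictors), "")
      ord <- order(-adj, keys)
      fits <- fits[ord][seq_len(min(top_k, length(fits)))]
    }
    sizes[[size]] <- fits
  }
  if (length(skipped)) {
    warn_lbmpe(sprintf("skipped %d rank-deficient subset(s): %s",
                       length(skipped), paste(skipped, collapse = "; ")),
               "lbmpe_skipped_subsets")
  }
  structure(
    list(sizes = sizes, skipped = skipped, n_obs = length(y),
         candidates = names(X), top_k = top_k),
    class = "best_subsets"
  )
}

#' @export
print.best_subsets <- function(x, ...) {
  cat(sprintf("<best_subsets> %d obs, candidates: %s\n", x$n_obs,
              paste(x$candidates, collapse = ", ")))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 5)
  if (length(x$skipped)) {
    cat("skipped (rank deficient):", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tabulate a best-subsets search
#'
#' @param x a `best_subsets` object.
#' @param row.names,optional,... S3 compatibility; unused.
#' @return data frame with columns `size`, `rank`, `predictors`, `r2`,
#'   `adjusted_r2`, `see`.
#' @export
as.data.frame.best_subsets <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  rows <- list()
  for (size in seq_along(x$sizes)) {
    fits <- x$sizes[[size]]
    for (rank in seq_along(fits)) {
      f <- fits[[rank]]
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, rank = rank,
        predictors = paste(f$predictors, collapse = "+"),
        r2 = f$r2, adjusted_r2 = f$adjusted_r2, see = f$see,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Materialise a best-subsets candidate as a prediction equation
#'
#' Registers nothing; simply converts the fitted coefficients of the candidate
#' at the requested size and rank into a linear [lbm_equation] (a fitted `sex`
#' indicator becomes a male sex offset) carrying SEE, R-squared and the number
#' of training observations as metadata.
#'
#' @param result a `best_subsets` object.
#' @param size subset size.
#' @param rank rank within that size (1 = best adjusted R-squared).
#' @param name name for the new equation.
#' @return a [lbm_equation].
#' @export
select_equation <- function(result, size, rank = 1L,
                            name = sprintf("fit_size%d_rank%d", size, rank)) {
  if (!inherits(result, "best_subsets")) {
    stop_lbmpe("`result` must come from best_subsets()", "lbmpe_domain_error")
  }
  if (size < 1L || size > length(result$sizes) ||
      rank < 1L || rank > length(result$sizes[[size]])) {
    stop_lbmpe(sprintf("no candidate at size %d, rank %d", size, rank),
               "lbmpe_lookup_error")
  }
  f <- result$sizes[[size]][[rank]]
  coefs <- f$coefficients
  intercept <- unname(coefs[["(Intercept)"]])
  slopes <- coefs[setdiff(names(coefs), "(Intercept)")]
  sex_offset <- NULL
  if ("sex" %in% names(slopes)) {
    sex_offset <- c(male = unname(slopes[["sex"]]), female = 0)
    slopes <- slopes[setdiff(names(slopes), "sex")]
  }
  lbm_equation(
    name = name, form = "linear", intercept = intercept,
    coefficients = slopes, sex_offset = sex_offset, output = "lbm",
    metadata = list(see = f$see, r2 = f$r2, adjusted_r2 = f$adjusted_r2,
                    n_obs = result$n_obs,
                    source = sprintf("best-subset OLS fit (size %d, rank %d)",
                                     size, rank))
  )
}
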