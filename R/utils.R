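# Internal helpers: classed errors, seed hygiene, truncated-normal sampling.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lbmpe <- function(message, class, ...) {
  stop(structure(
    class = c(class, "lbmpe_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warn_lbmpe <- function(message, class) {
  warning(structure(
    class = c(class, "lbmpe_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_lbmpe(sprintf("`%s` must be a single finite number", name),
               "lbmpe_domain_error")
  }
  invisible(x)
}

# Normalise a sex vector to "male"/"female"; anything else is rejected.
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  s[s %in% c("m", "male", "1")] <- "male"
  s[s %in% c("f", "female", "0")] <- "female"
  bad <- !(s %in% c("male", "female")) & !is.na(s)
  if (any(bad)) {
    stop_lbmpe(
      sprintf("sex must be 'male' or 'female'; got: %s",
              paste(unique(sex[bad]), collapse = ", ")),
      "lbmpe_domain_error"
    )
  }
  s
}

sex_indicator <- function(sex) as.numeric(normalize_sex(sex) == "male")

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_lbmpe("seed must be a single integer", "lbmpe_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Inverse-CDF sampler for a normal truncated to [lower, upper].
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop_lbmpe("sd must be >= 0", "lbmpe_config_error")
  if (lower >= upper) {
    stop_lbmpe("truncation bounds must satisfy lower < upper",
               "lbmpe_config_error")
  }
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_lbmpe("degenerate marginal (sd = 0) lies outside its truncation bounds",
                 "lbmpe_config_error")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    stop_lbmpe(
      sprintf("infeasible truncation: [%g, %g] carries ~zero mass for Normal(%g, %g)",
              lower, upper, mean, sd),
      "lbmpe_config_error"
    )
  }
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

fmt_num <- function(x, digits = 3) formatC(x, format = "f", digits = digits)
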