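#' Body mass index
#'
#' BMI is weight divided by height squared.
#'
#' @param weight body weight in kilograms; must be positive.
#' @param height standing height in metres; must be positive.
#' @return BMI in kg/m^2, vectorised over its inputs.
#' @examples
#' compute_bmi(81, 1.80)
#' @export
compute_bmi <- function(weight, height) {
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop_lbmpe("`weight` must be positive and finite", "lbmpe_domain_error")
  }
  if (!is.numeric(height) || any(!is.finite(height)) || any(height <= 0)) {
    stop_lbmpe("`height` must be positive and finite", "lbmpe_domain_error")
  }
  weight / height^2
}

#' Construct a prediction equation
#'
#' A `lbm_equation` bundles a named estimator of lean body mass (LBM) or
#' fat-free mass (FFM) with its coefficients, required predictors, units and
#' provenance metadata. Three functional forms are supported:
#'
#' * `"linear"` — `intercept + sum(coefficients * predictors) + sex_offset[sex]`,
#'   the form of the developed equations PE1-PE4.
#' * `"janmahasatian_rational"` — the rational FFM form
#'   `num * weight / (d0 + d1 * BMI)` with sex-specific denominators.
#' * `"bodyfat_to_ffm"` — a linear body-fat-mass (kg) model subtracted from
#'   weight (Heitmann form; the weight coefficient is sex-specific).
#' * `"bodyfat_pct_to_ffm"` — a linear body-fat-percentage model converted as
#'   `weight * (1 - pct/100)` (Deurenberg form).
#'
#' @param name short identifier, e.g. `"pe1"`.
#' @param form one of the forms above.
#' @param intercept intercept in kg (linear) or percent (body-fat-percent form).
#' @param coefficients named numeric vector mapping predictor name to
#'   coefficient (canonical predictor names: `weight`, `bmi`, `age`, `ck`,
#'   `hscrp`, `ldh`, `albumin`, `ast`, `height`).
#' @param sex_offset named numeric vector `c(male = , female = )` added to the
#'   linear predictor, or `NULL`.
#' @param params form-specific parameter list for the non-linear forms.
#' @param output `"lbm"` or `"ffm"`; the two are closely related but not
#'   identical (membrane lipids are in LBM, bone in neither), so the label is
#'   carried rather than converted.
#' @param metadata free-form provenance list; conventional entries are `see`
#'   (residual standard error of the estimate, kg), `r2` (percent) and
#'   `source`.
#' @return an object of class `lbm_equation`.
#' @seealso [builtin_equations()], [predict.lbm_equation()]
#' @export
lbm_equation <- function(name,
                         form = c("linear", "janmahasatian_rational",
                                  "bodyfat_to_ffm", "bodyfat_pct_to_ffm"),
                         intercept = 0,
                         coefficients = numeric(),
                         sex_offset = NULL,
                         params = list(),
                         output = c("lbm", "ffm"),
                         metadata = list()) {
  form <- match.arg(form)
  output <- match.arg(output)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_lbmpe("equation `name` must be a non-empty string", "lbmpe_domain_error")
  }
  if (form == "linear") {
    if (length(coefficients) && is.null(names(coefficients))) {
      stop_lbmpe("`coefficients` must be a named numeric vector",
                 "lbmpe_domain_error")
    }
    if (!is.null(sex_offset) &&
        !all(c("male", "female") %in% names(sex_offset))) {
      stop_lbmpe("`sex_offset` must name both 'male' and 'female'",
                 "lbmpe_domain_error")
    }
  }
  required <- switch(form,
    linear = c(names(coefficients), if (!is.null(sex_offset)) "sex"),
    janmahasatian_rational = c("sex", "weight", "bmi"),
    bodyfat_to_ffm = c("sex", "weight", "bmi", "age"),
    bodyfat_pct_to_ffm = c("sex", "weight", "bmi", "age")
  )
  structure(
    list(name = name, form = form, intercept = intercept,
         coefficients = coefficients, sex_offset = sex_offset,
         params = params, required_predictors = unique(required),
         output = output, metadata = metadata),
    class = "lbm_equation"
  )
}

#' @export
print.lbm_equation <- function(x, ...) {
  cat(sprintf("<lbm_equation> %s  [%s -> %s]\n", x$name, x$form,
              toupper(x$output)))
  if (x$form == "linear") {
    terms <- character()
    if (length(x$coefficients)) {
      terms <- sprintf("%+g %s", x$coefficients, names(x$coefficients))
    }
    if (!is.null(x$sex_offset)) {
      terms <- c(terms, sprintf("%+g (if male)", x$sex_offset[["male"]]))
    }
    cat("  ", fmt_num(x$intercept, 6), " ", paste(terms, collapse = " "),
        "\n", sep = "")
  }
  cat("  requires:", paste(x$required_predictors, collapse = ", "), "\n")
  if (length(x$metadata)) {
    md <- x$metadata
    if (!is.null(md$see)) cat(sprintf("  SEE = %s kg", fmt_num(md$see, 2)))
    if (!is.null(md$r2)) cat(sprintf("  R2 = %s%%", fmt_num(md$r2, 1)))
    cat("\n")
    if (!is.null(md$source)) cat("  source:", md$source, "\n")
  }
  invisible(x)
}

# ---- built-in coefficient sets -------------------------------------------

.lbmpe_builtins <- function() {
  list(
    pe1 = lbm_equation(
      "pe1", "linear",
      intercept = 22.932326,
      coefficients = c(weight = 0.684668, bmi = -1.137156, age = -0.009213),
      sex_offset = c(male = 9.940015, female = 0),
      output = "lbm",
      metadata = list(see = 3.61, r2 = 90.7,
                      source = "anthropometric LBM equation developed in the CASA cohort (full-precision coefficients)")
    ),
    pe2 = lbm_equation(
      "pe2", "linear",
      intercept = 22.06,
      coefficients = c(weight = 0.67, bmi = -1.11, ck = 0.01),
      sex_offset = c(male = 9.76, female = 0),
      output = "lbm",
      metadata = list(see = 3.56, r2 = 91.0,
                      source = "LBM equation with creatine kinase, CASA cohort")
    ),
    pe3 = lbm_equation(
      "pe3", "linear",
      intercept = 21.19,
      coefficients = c(weight = 0.67, bmi = -1.04, hscrp = -0.56, ck = 0.01),
      sex_offset = c(male = 9.51, female = 0),
      output = "lbm",
      metadata = list(see = 3.47, r2 = 91.4,
                      source = "LBM equation with CK and hsCRP, CASA cohort")
    ),
    pe4 = lbm_equation(
      "pe4", "linear",
      intercept = 23.17,
      coefficients = c(weight = 0.64, bmi = -0.91, ck = 0.02, hscrp = -0.58,
                       ldh = -0.02),
      sex_offset = c(male = 9.45, female = 0),
      output = "lbm",
      metadata = list(see = 3.38, r2 = 91.9,
                      source = "LBM equation with CK, hsCRP and LDH, CASA cohort")
    ),
    heitmann = lbm_equation(
      "heitmann", "bodyfat_to_ffm",
      params = list(
        intercept = -30.180,
        bmi = 0.988, age = 0.094,
        weight_male = 0.242, weight_female = 0.344
      ),
      output = "ffm",
      metadata = list(source = "Heitmann body-fat (kg) equation; FFM = weight - fat")
    ),
    janmahasatian = lbm_equation(
      "janmahasatian", "janmahasatian_rational",
      params = list(
        numerator = 9270,
        male = c(d0 = 6680, d1 = 216),
        female = c(d0 = 8780, d1 = 244)
      ),
      output = "ffm",
      metadata = list(source = "Janmahasatian rational FFM equation")
    ),
    deurenberg = lbm_equation(
      "deurenberg", "bodyfat_pct_to_ffm",
      params = list(intercept = -5.4, bmi = 1.2, age = 0.23,
                    sex_offset = c(male = -10.8, female = 0)),
      output = "ffm",
      metadata = list(source = "Deurenberg body-fat percent equation; FFM = weight * (1 - pct/100)")
    )
  )
}

.lbmpe_registry <- new.env(parent = emptyenv())

registry_state <- function() {
  if (!exists("equations", envir = .lbmpe_registry)) {
    assign("equations", .lbmpe_builtins(), envir = .lbmpe_registry)
  }
  get("equations", envir = .lbmpe_registry)
}

#' Built-in prediction equations
#'
#' Returns the registry of equations shipped with the package: the four
#' developed LBM equations (`pe1`-`pe4`; `pe1` carries its full-precision
#' coefficients, `pe2`-`pe4` the published two-decimal coefficients) and the
#' Heitmann, Janmahasatian and Deurenberg fat-free-mass comparators.
#'
#' @return named list of [lbm_equation] objects.
#' @export
builtin_equations <- function() .lbmpe_builtins()

#' Look up a registered equation by name
#'
#' @param name equation name (case-insensitive), e.g. `"pe1"` or
#'   `"deurenberg"`.
#' @return a [lbm_equation].
#' @export
get_equation <- function(name) {
  reg <- registry_state()
  key <- tolower(name)
  if (!key %in% names(reg)) {
    stop_lbmpe(
      sprintf("unknown equation '%s'; registered: %s", name,
              paste(names(reg), collapse = ", ")),
      "lbmpe_lookup_error"
    )
  }
  reg[[key]]
}

#' Register a custom equation
#'
#' Adds (or replaces) an equation in the session registry so that it can be
#' addressed by name in [predict_lbm()], [run_predict()] and friends.
#'
#' @param equation a [lbm_equation].
#' @return the equation, invisibly.
#' @export
register_equation <- function(equation) {
  if (!inherits(equation, "lbm_equation")) {
    stop_lbmpe("`equation` must be an lbm_equation", "lbmpe_domain_error")
  }
  reg <- registry_state()
  reg[[tolower(equation$name)]] <- equation
  assign("equations", reg, envir = .lbmpe_registry)
  invisible(equation)
}

#' @rdname get_equation
#' @export
list_equations <- function() names(registry_state())

# ---- equation file round trip --------------------------------------------

#' Read / write equation coefficient files
#'
#' Equations are serialised as human-readable JSON (one object per equation:
#' name, form, intercept, coefficients, sex offsets, parameters, output label,
#' metadata). Files written by [write_equation_file()] — including those
#' produced by [run_develop()] — load back with [read_equation_file()].
#'
#' @param equations a list of [lbm_equation] objects (or a single one).
#' @param path file path.
#' @return `read_equation_file()` returns a named list of equations;
#'   `write_equation_file()` returns `path` invisibly.
#' @export
write_equation_file <- function(equations, path) {
  if (inherits(equations, "lbm_equation")) equations <- list(equations)
  payload <- lapply(equations, function(eq) {
    # named numeric vectors must become objects, not bare arrays
    params <- lapply(eq$params, function(x) {
      if (is.numeric(x) && length(x) > 1L) as.list(x) else x
    })
    list(name = eq$name, form = eq$form, intercept = eq$intercept,
         coefficients = as.list(eq$coefficients),
         sex_offset = if (is.null(eq$sex_offset)) NULL else as.list(eq$sex_offset),
         params = params, output = eq$output, metadata = eq$metadata)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_equation_file
#' @export
read_equation_file <- function(path) {
  if (!file.exists(path)) {
    stop_lbmpe(sprintf("equation file not found: %s", path),
               "lbmpe_schema_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  eqs <- lapply(payload, function(p) {
    lbm_equation(
      name = p$name, form = p$form,
      intercept = p$intercept %||% 0,
      coefficients = unlist(p$coefficients) %||% numeric(),
      sex_offset = if (is.null(p$sex_offset)) NULL else unlist(p$sex_offset),
      params = lapply(p$params %||% list(), function(x)
        if (is.list(x)) unlist(x) else x),
      output = p$output %||% "lbm",
      metadata = p$metadata %||% list()
    )
  })
  names(eqs) <- vapply(eqs, `[[`, "", "name")
  eqs
}

# ---- prediction -----------------------------------------------------------

# Coerce a subject (named list / one-row df) or cohort df to a data.frame and
# back-fill BMI from weight/height, warning when a stored BMI disagrees with
# weight/height^2 by more than 0.1 kg/m^2 (the stored value wins).
prepare_subjects <- function(data) {
  if (is.null(dim(data))) data <- as.data.frame(data, stringsAsFactors = FALSE)
  data <- as.data.frame(data)
  if (!nrow(data)) return(data)
  if ("sex" %in% names(data)) data$sex <- normalize_sex(data$sex)
  has_height <- "height" %in% names(data)
  if (!"bmi" %in% names(data)) data$bmi <- NA_real_
  if (has_height && "weight" %in% names(data)) {
    computable <- !is.na(data$weight) & !is.na(data$height) & data$height > 0
    fill <- is.na(data$bmi) & computable
    if (any(fill)) {
      data$bmi[fill] <- compute_bmi(data$weight[fill], data$height[fill])
    }
    both <- !is.na(data$bmi) & computable & !fill
    if (any(both)) {
      disc <- abs(data$bmi[both] -
                    data$weight[both] / data$height[both]^2)
      if (any(disc > 0.1)) {
        warn_lbmpe(
          sprintf("%d record(s) have stored BMI differing from weight/height^2 by > 0.1 kg/m^2; stored BMI used",
                  sum(disc > 0.1)),
          "lbmpe_bmi_inconsistency"
        )
      }
    }
  }
  data
}

missing_fields <- function(data, required) {
  n <- nrow(data)
  miss <- vapply(required, function(f) {
    if (!f %in% names(data)) rep(TRUE, n) else is.na(data[[f]])
  }, logical(n))
  miss <- matrix(miss, nrow = n,
                 dimnames = list(NULL, required))
  out <- character(n)
  bad <- which(rowSums(miss) > 0)
  for (i in bad) out[i] <- paste(required[miss[i, ]], collapse = ",")
  out
}

eval_equation <- function(eq, data) {
  n <- nrow(data)
  if (!n) return(numeric(0))
  miss <- missing_fields(data, eq$required_predictors)
  if (any(nzchar(miss))) {
    ids <- if ("id" %in% names(data)) data$id else seq_len(n)
    bad <- which(nzchar(miss))
    stop_lbmpe(
      sprintf("equation '%s' is missing required predictor(s) for %d record(s): %s",
              eq$name, length(bad),
              paste(sprintf("[%s: %s]", ids[bad], miss[bad]), collapse = " ")),
      "lbmpe_missing_field_error"
    )
  }
  flags <- rep(FALSE, n)
  value <- switch(eq$form,
    linear = {
      v <- rep(eq$intercept, n)
      for (p in names(eq$coefficients)) v <- v + eq$coefficients[[p]] * data[[p]]
      if (!is.null(eq$sex_offset)) v <- v + unname(eq$sex_offset[data$sex])
      v
    },
    janmahasatian_rational = {
      p <- eq$params
      d <- t(vapply(data$sex, function(s) p[[s]], c(d0 = 0, d1 = 0)))
      p$numerator * data$weight / (d[, "d0"] + d[, "d1"] * data$bmi)
    },
    bodyfat_to_ffm = {
      p <- eq$params
      wcoef <- ifelse(data$sex == "male", p$weight_male, p$weight_female)
      fat <- p$intercept + p$bmi * data$bmi + wcoef * data$weight +
        p$age * data$age
      data$weight - fat
    },
    bodyfat_pct_to_ffm = {
      p <- eq$params
      pct <- p$intercept + p$bmi * data$bmi + p$age * data$age +
        unname(p$sex_offset[data$sex])
      if (any(pct < 0 | pct > 100)) flags[pct < 0 | pct > 100] <- TRUE
      data$weight * (1 - pct / 100)
    }
  )
  # extrapolation outside (0, weight) is reported, never clamped
  if ("weight" %in% names(data)) {
    implausible <- value <= 0 | value >= data$weight
    flags <- flags | implausible
  }
  if (any(flags)) {
    warn_lbmpe(
      sprintf("equation '%s': %d prediction(s) flagged as implausible (outside (0, weight) or body-fat%% outside [0, 100])",
              eq$name, sum(flags)),
      "lbmpe_implausible_prediction"
    )
    attr(value, "flags") <- flags
  }
  value
}

#' Predict LBM/FFM for subjects
#'
#' @param object a [lbm_equation].
#' @param newdata a data frame (or single named list) of subjects with the
#'   canonical columns `sex`, `age`, `weight` and either `bmi` or `height`,
#'   plus any biochemistry the equation requires (`ck` U/L, `hscrp` mg/L,
#'   `ldh` U/L).
#' @param ... unused.
#' @return numeric vector of predictions in kg, aligned to the rows of
#'   `newdata`. Implausible predictions (outside `(0, weight)`, or a body-fat
#'   percentage outside `[0, 100]`) trigger a warning and are marked in a
#'   logical `"flags"` attribute; values are never clamped.
#' @export
predict.lbm_equation <- function(object, newdata, ...) {
  eval_equation(object, prepare_subjects(newdata))
}

#' Developed LBM equations PE1-PE4
#'
#' `predict_pe1()` evaluates the anthropometric equation
#' `LBM = 22.932326 + 0.684668 weight - 1.137156 BMI - 0.009213 age +
#' 9.940015 (if male)` (full-precision coefficients; SEE 3.61 kg).
#' `predict_pe2()`-`predict_pe4()` add creatine kinase, hsCRP and LDH terms
#' with the published two-decimal coefficients.
#'
#' @param subjects data frame of subjects (see [predict.lbm_equation()]).
#' @return predicted LBM in kg.
#' @examples
#' predict_pe1(data.frame(sex = "male", age = 60, weight = 80, bmi = 24.7))
#' @export
predict_pe1 <- function(subjects) predict(get_equation("pe1"), subjects)

#' @rdname predict_pe1
#' @export
predict_pe2 <- function(subjects) predict(get_equation("pe2"), subjects)

#' @rdname predict_pe1
#' @export
predict_pe3 <- function(subjects) predict(get_equation("pe3"), subjects)

#' @rdname predict_pe1
#' @export
predict_pe4 <- function(subjects) predict(get_equation("pe4"), subjects)

#' Heitmann fat-free mass
#'
#' Body fat (kg) from BMI, weight and age with a sex-specific weight
#' coefficient; FFM is weight minus fat mass. `heitmann_bodyfat()` exposes the
#' intermediate fat mass, so `heitmann_bodyfat(x) + heitmann_ffm(x)` always
#' equals weight.
#'
#' @inheritParams predict_pe1
#' @return kg.
#' @export
heitmann_ffm <- function(subjects) {
  predict(get_equation("heitmann"), subjects)
}

#' @rdname heitmann_ffm
#' @export
heitmann_bodyfat <- function(subjects) {
  data <- prepare_subjects(subjects)
  ffm <- eval_equation(get_equation("heitmann"), data)
  data$weight - as.numeric(ffm)
}

#' Janmahasatian fat-free mass
#'
#' Rational-form FFM: `9270 * weight / (6680 + 216 * BMI)` for men and
#' `9270 * weight / (8780 + 244 * BMI)` for women.
#'
#' @inheritParams predict_pe1
#' @return kg.
#' @export
janmahasatian_ffm <- function(subjects) {
  predict(get_equation("janmahasatian"), subjects)
}

#' Deurenberg fat-free mass
#'
#' Body fat percent `1.2 BMI + 0.23 age - 10.8 (if male) - 5.4`; FFM is
#' `weight * (1 - pct/100)`. Percentages outside `[0, 100]` (the equation
#' extrapolates freely) are flagged with a warning, not clamped.
#'
#' @inheritParams predict_pe1
#' @return kg (`deurenberg_ffm`) or percent (`deurenberg_bodyfat_pct`).
#' @export
deurenberg_ffm <- function(subjects) {
  predict(get_equation("deurenberg"), subjects)
}

#' @rdname deurenberg_ffm
#' @export
deurenberg_bodyfat_pct <- function(subjects) {
  data <- prepare_subjects(subjects)
  p <- get_equation("deurenberg")$params
  p$intercept + p$bmi * data$bmi + p$age * data$age +
    unname(p$sex_offset[data$sex])
}

#' Batch prediction over a cohort
#'
#' Evaluates one equation on every record. Records that do not satisfy the
#' equation's required predictors are reported by id in a single aggregated
#' error — nothing is silently dropped.
#'
#' @param cohort data frame of subjects.
#' @param equation a [lbm_equation] or the name of a registered equation.
#' @return numeric vector aligned to `cohort` rows.
#' @export
predict_batch <- function(cohort, equation) {
  if (is.character(equation)) equation <- get_equation(equation)
  predict(equation, cohort)
}

#' Evaluate several equations on a cohort
#'
#' @param cohort data frame of subjects.
#' @param equations character vector of registered equation names, or a list
#'   of [lbm_equation] objects.
#' @return data frame with one prediction column per equation (named after the
#'   equation), aligned to `cohort` rows.
#' @export
predict_lbm <- function(cohort, equations = c("pe1", "pe2", "pe3", "pe4")) {
  eqs <- resolve_equations(equations)
  data <- prepare_subjects(cohort)
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (eq in eqs) out[[eq$name]] <- as.numeric(eval_equation(eq, data))
  out
}

resolve_equations <- function(equations) {
  if (inherits(equations, "lbm_equation")) return(list(equations))
  if (is.character(equations)) return(lapply(equations, get_equation))
  if (is.list(equations) &&
      all(vapply(equations, inherits, TRUE, "lbm_equation"))) {
    return(equations)
  }
  stop_lbmpe("`equations` must be equation names or lbm_equation objects",
             "lbmpe_lookup_error")
}
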