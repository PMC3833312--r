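test_that("BMI is weight over height squared, with domain checks", {
  expect_equal(compute_bmi(81, 1.8), 25.0)
  expect_equal(compute_bmi(70, 1.0), 70.0)
  expect_equal(compute_bmi(72.5, 1.63), 27.29, tolerance = 0.0002)
  expect_error(compute_bmi(-5, 1.7), "weight", class = "lbmpe_domain_error")
  expect_error(compute_bmi(70, 0), "height", class = "lbmpe_domain_error")
})

test_that("pe1 reproduces its full-precision linear form", {
  s <- data.frame(sex = "male", age = 60, weight = 80, bmi = 24.7)
  expect_equal(predict_pe1(s), 59.0052478, tolerance = 1e-7)
  # sex offset is exactly the male coefficient
  f <- transform(s, sex = "female")
  expect_equal(predict_pe1(s) - predict_pe1(f), 9.940015)
  # linear in age with slope -0.009213
  older <- transform(s, age = 70)
  expect_equal(predict_pe1(older) - predict_pe1(s), -0.09213, tolerance = 1e-10)
  # bmi back-filled from height when absent
  h <- data.frame(sex = "male", age = 60, weight = 80, height = 1.8)
  expect_equal(predict_pe1(h),
               predict_pe1(data.frame(sex = "male", age = 60, weight = 80,
                                      bmi = 80 / 1.8^2)))
})

test_that("pe2-pe4 use the published biochemistry coefficients", {
  s <- data.frame(sex = "male", age = 60, weight = 80, bmi = 24.7,
                  ck = 114.3, hscrp = 2, ldh = 175)
  expect_equal(predict_pe2(s), 22.06 + 0.67 * 80 - 1.11 * 24.7 + 9.76 +
                 0.01 * 114.3)
  expect_equal(predict_pe2(s), 59.146, tolerance = 1e-10)
  # zero-covariate reductions
  z <- transform(s, hscrp = 0)
  expect_equal(predict_pe3(z),
               21.19 + 0.67 * 80 - 1.04 * 24.7 + 9.51 + 0.01 * 114.3)
  z4 <- transform(s, ck = 0, hscrp = 0, ldh = 0)
  expect_equal(predict_pe4(z4), 23.17 + 0.64 * 80 - 0.91 * 24.7 + 9.45)
  # missing analytes are named in the error
  expect_error(predict_pe2(data.frame(sex = "male", weight = 80, bmi = 24.7)),
               "ck", class = "lbmpe_missing_field_error")
  expect_error(predict_pe4(transform(s, ldh = NA)), "ldh",
               class = "lbmpe_missing_field_error")
})

test_that("Heitmann body fat and FFM partition weight exactly", {
  s <- data.frame(sex = "male", age = 60, weight = 80, bmi = 24.7)
  expect_equal(heitmann_bodyfat(s), 19.2236, tolerance = 1e-10)
  expect_equal(heitmann_ffm(s), 60.7764, tolerance = 1e-10)
  # female fat exceeds male fat by exactly 0.102 * weight
  f <- transform(s, sex = "female")
  expect_equal(heitmann_bodyfat(f) - heitmann_bodyfat(s), 0.102 * 80,
               tolerance = 1e-10)
  subj <- random_subjects(50, seed = 401)
  expect_equal(heitmann_bodyfat(subj) + heitmann_ffm(subj), subj$weight,
               tolerance = 1e-12)
})

test_that("Janmahasatian FFM matches its rational form and is monotone", {
  expect_equal(janmahasatian_ffm(data.frame(sex = "male", weight = 70,
                                            bmi = 25)),
               648900 / 12080, tolerance = 1e-12)
  # numerator proportional to weight: FFM -> 0 with weight
  tiny <- janmahasatian_ffm(data.frame(sex = "female", weight = 1e-6,
                                       bmi = 25))
  expect_lt(tiny, 1e-6)
  w <- seq(40, 150, by = 5)
  ffm_w <- janmahasatian_ffm(data.frame(sex = "male", weight = w, bmi = 28))
  expect_true(all(diff(ffm_w) > 0))
  b <- seq(18, 40, by = 1)
  ffm_b <- suppressWarnings(
    janmahasatian_ffm(data.frame(sex = "female", weight = 70, bmi = b))
  )
  expect_true(all(diff(ffm_b) < 0))
})

test_that("Deurenberg body fat percent converts to FFM and flags extrapolation", {
  s <- data.frame(sex = "male", age = 60, weight = 75, bmi = 25)
  expect_equal(deurenberg_bodyfat_pct(s), 27.6, tolerance = 1e-10)
  expect_equal(deurenberg_ffm(s), 54.3, tolerance = 1e-10)
  f <- transform(s, sex = "female")
  expect_equal(deurenberg_bodyfat_pct(s) - deurenberg_bodyfat_pct(f), -10.8)
  # absurd extrapolation (young lean man: fat% = -5.6) produces a warning
  # flag, not an error or clamping
  silly <- data.frame(sex = "male", age = 20, weight = 70, bmi = 5)
  expect_equal(deurenberg_bodyfat_pct(silly), -5.6, tolerance = 1e-10)
  expect_warning(v <- deurenberg_ffm(silly),
                 class = "lbmpe_implausible_prediction")
  expect_true(any(attr(v, "flags")))
  expect_gt(as.numeric(v), 70)  # unclamped: FFM exceeds weight
})

test_that("batch predictions equal scalar loops and aggregate failures by id", {
  empty <- data.frame(sex = character(), age = numeric(), weight = numeric(),
                      bmi = numeric())
  expect_length(predict_batch(empty, "pe1"), 0)
  one <- data.frame(sex = "female", age = 44, weight = 62, bmi = 23)
  expect_equal(predict_batch(one, "pe1"), predict_pe1(one))
  subj <- random_subjects(100, seed = 402)
  for (eq in c("pe1", "pe3", "heitmann", "janmahasatian", "deurenberg")) {
    batch <- suppressWarnings(predict_batch(subj, eq))
    scalar <- vapply(seq_len(nrow(subj)), function(i) {
      suppressWarnings(as.numeric(predict_batch(subj[i, , drop = FALSE], eq)))
    }, 0)
    expect_equal(as.numeric(batch), scalar, tolerance = 1e-12, label = eq)
  }
  # all offending ids reported in one error
  bad <- random_subjects(6, seed = 403)
  bad$ck[c(2, 5)] <- NA
  err <- tryCatch(predict_batch(bad, "pe2"), error = function(e) e)
  expect_s3_class(err, "lbmpe_missing_field_error")
  expect_match(conditionMessage(err), "R002")
  expect_match(conditionMessage(err), "R005")
})

test_that("developed equations are affine in the predictors", {
  a <- data.frame(sex = "male", age = 30, weight = 60, bmi = 21, ck = 80,
                  hscrp = 1, ldh = 150)
  b <- data.frame(sex = "male", age = 80, weight = 110, bmi = 33, ck = 250,
                  hscrp = 6, ldh = 280)
  for (t in c(0.25, 0.5, 0.8)) {
    mix <- a
    for (cn in c("age", "weight", "bmi", "ck", "hscrp", "ldh")) {
      mix[[cn]] <- t * a[[cn]] + (1 - t) * b[[cn]]
    }
    for (fn in list(predict_pe1, predict_pe2, predict_pe3, predict_pe4)) {
      expect_equal(fn(mix), t * fn(a) + (1 - t) * fn(b), tolerance = 1e-10)
    }
  }
})

test_that("estimators stay inside (0, weight) on the physiological box", {
  grid <- expand.grid(sex = c("male", "female"), age = c(18, 54, 90),
                      bmi = c(18, 29, 40), weight = c(40, 95, 150),
                      stringsAsFactors = FALSE)
  grid$ck <- 114.3; grid$hscrp <- 2; grid$ldh <- 175
  for (eq in c("pe1", "pe2", "pe3", "pe4", "janmahasatian", "deurenberg")) {
    v <- as.numeric(predict_batch(grid, eq))
    expect_true(all(v > 0 & v < grid$weight), label = eq)
  }
  # Heitmann genuinely extrapolates to negative fat mass for a young lean
  # light man (18 y, BMI 18, 40 kg): the package must flag it, not hide it
  expect_warning(hf <- heitmann_ffm(grid),
                 class = "lbmpe_implausible_prediction")
  flagged <- attr(hf, "flags")
  corner <- grid$sex == "male" & grid$age == 18 & grid$bmi == 18 &
    grid$weight == 40
  expect_equal(which(flagged), which(corner))
  expect_true(all(hf[!flagged] > 0 & hf[!flagged] < grid$weight[!flagged]))
})

test_that("a stored BMI inconsistent with weight/height^2 warns but wins", {
  s <- data.frame(sex = "male", age = 50, weight = 80, height = 1.8, bmi = 27)
  expect_warning(v <- predict_pe1(s), class = "lbmpe_bmi_inconsistency")
  expect_equal(v, predict_pe1(data.frame(sex = "male", age = 50, weight = 80,
                                         bmi = 27)))
})

test_that("equation registry round-trips through the JSON config format", {
  path <- withr::local_tempfile(fileext = ".json")
  write_equation_file(builtin_equations(), path)
  eqs <- read_equation_file(path)
  expect_setequal(names(eqs), names(builtin_equations()))
  subj <- random_subjects(20, seed = 404)
  for (nm in names(eqs)) {
    expect_equal(
      suppressWarnings(as.numeric(predict(eqs[[nm]], subj))),
      suppressWarnings(as.numeric(predict(get_equation(nm), subj))),
      tolerance = 1e-12, label = nm
    )
  }
  # custom registration
  custom <- lbm_equation("halfweight", "linear", intercept = 0,
                         coefficients = c(weight = 0.5))
  register_equation(custom)
  expect_equal(as.numeric(predict_batch(subj, "halfweight")),
               0.5 * subj$weight)
  expect_error(get_equation("nope"), class = "lbmpe_lookup_error")
})
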