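make_cohort_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("well-formed files read into validated records", {
  df <- data.frame(id = c("a", "b", "c"), sex = c("male", "female", "male"),
                   age = c(60, 45, 72), weight = c(80, 62, 75),
                   height = c(1.80, 1.65, 1.72), lbm_dxa = c(58, 41, 52))
  path <- make_cohort_file(df)
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort), 3)
  expect_equal(nrow(attr(cohort, "validation")), 0)
  # bmi back-filled from weight/height^2; spot-check the first row by hand
  expect_equal(cohort$bmi[1], 80 / 1.8^2, tolerance = 1e-9)
})

test_that("invalid rows are rejected and reported with row and field", {
  df <- data.frame(id = c("ok", "badw", "badsex"),
                   sex = c("female", "male", "unknown"),
                   age = c(50, 60, 70), weight = c(70, -5, 80),
                   bmi = c(24, 25, 26))
  path <- make_cohort_file(df)
  cohort <- read_cohort(path)
  expect_equal(cohort$id, "ok")
  rep <- attr(cohort, "validation")
  expect_true(any(rep$row == 2 & rep$field == "weight"))
  expect_true(any(rep$row == 3 & rep$field == "sex"))
  # schema errors for missing mandatory columns
  path2 <- make_cohort_file(data.frame(sex = "male", weight = 80))
  expect_error(read_cohort(path2), class = "lbmpe_schema_error")
  expect_error(read_cohort("/nonexistent/file.csv"),
               class = "lbmpe_format_error")
})

test_that("column maps decouple file headers from canonical names", {
  df <- data.frame(subj = "x", gender = "female", years = 44, wt = 61,
                   ht = 1.66)
  path <- make_cohort_file(df)
  cohort <- read_cohort(path, column_map = c(id = "subj", sex = "gender",
                                             age = "years", weight = "wt",
                                             height = "ht"))
  expect_equal(cohort$weight, 61)
  expect_error(read_cohort(path, column_map = c(weight = "missing_col")),
               class = "lbmpe_schema_error")
})

test_that("write -> read round-trips records field for field", {
  cohort <- generate_cohort(cohort_preset("VC", seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  for (cn in c("id", "sex", "age", "weight", "bmi", "ck", "hscrp", "ldh",
               "albumin", "ast", "lbm_dxa")) {
    expect_equal(back[[cn]], cohort[[cn]], tolerance = 1e-9, label = cn)
  }
})

test_that("machine corrections apply, invert and validate", {
  corr <- machine_correction(1.02, -0.5, "Norland XR36", "Lunar PRODIGY")
  expect_equal(apply_machine_correction(50, corr), 50.5)
  expect_equal(apply_machine_correction(c(40, 60), machine_correction()),
               c(40, 60))
  inv <- invert_machine_correction(corr)
  lbm <- c(35.2, 48.9, 61.4)
  expect_equal(apply_machine_correction(apply_machine_correction(lbm, corr),
                                        inv),
               lbm, tolerance = 1e-12)
  expect_error(machine_correction(0), class = "lbmpe_domain_error")
  expect_error(machine_correction(-1.1), class = "lbmpe_domain_error")
  co <- data.frame(lbm_dxa = c(50, 51))
  expect_equal(correct_cohort(co, corr)$lbm_dxa, c(50.5, 51.52))
})

test_that("stratification uses half-open bins with the printed boundary rules", {
  co <- data.frame(
    id = 1:7, sex = c("male", "female", "male", "female", "male", "female",
                      "male"),
    age = c(50, 64.999, 65, 79.5, 80, 95, 55),
    bmi = c(21.99, 22, 26.9, 27, 29.99, 30, 41),
    weight = 70, lbm_dxa = 50
  )
  strata <- stratify(co, stratification_scheme())
  expect_equal(sort(strata$age[["50-64"]]$id), c(1, 2, 7))
  expect_equal(sort(strata$age[["65-79"]]$id), c(3, 4))
  expect_equal(sort(strata$age[[">=80"]]$id), c(5, 6))
  expect_equal(strata$bmi[["<22"]]$id, 1)
  expect_equal(sort(strata$bmi[["22-<27"]]$id), c(2, 3))
  expect_equal(sort(strata$bmi[["27-<30"]]$id), c(4, 5))
  expect_equal(sort(strata$bmi[[">=30"]]$id), c(6, 7))
  expect_equal(nrow(strata$sex$men) + nrow(strata$sex$women), 7)
  # partition: each dimension's sizes sum to the assignable total
  for (dim in names(strata)) {
    expect_equal(sum(vapply(strata[[dim]], nrow, 0L)), 7, label = dim)
  }
})

test_that("records outside the declared ranges are unassignable, with warning", {
  co <- data.frame(id = 1:3, sex = "male", age = c(30, 55, NA), bmi = 25,
                   weight = 70)
  expect_warning(strata <- stratify(co),
                 class = "lbmpe_unassignable_records")
  expect_equal(sum(vapply(strata$age, nrow, 0L)), 1)
  expect_equal(attr(strata, "unassigned")$age, c(1, 3))
})

test_that("stratified reports compose evaluate_agreement per stratum", {
  cohort <- generate_cohort(cohort_preset("NWAHS-FAMAS", n = 400, seed = 32))
  # single-stratum scheme reduces to a direct evaluate_agreement call
  flat <- stratified_report(cohort, "pe1",
                            stratification_scheme(bmi_breaks = NULL,
                                                  age_breaks = NULL,
                                                  by_sex = FALSE))
  expect_equal(nrow(flat), 1)
  direct <- evaluate_agreement(
    suppressWarnings(predict_pe1(cohort)), cohort$lbm_dxa)
  expect_equal(flat$me, direct$me)
  expect_equal(flat$ccc, direct$ccc)
  expect_equal(flat$rmse, direct$rmse)
  # full scheme: row counts agree with stratify()
  rep <- suppressWarnings(stratified_report(cohort, c("pe1", "deurenberg")))
  strata <- suppressWarnings(stratify(cohort))
  for (dim in names(strata)) {
    for (lab in names(strata[[dim]])) {
      got <- rep$n[rep$dimension == dim & rep$stratum == lab &
                     rep$equation == "pe1"]
      expect_equal(got, nrow(strata[[dim]][[lab]]),
                   label = paste(dim, lab))
    }
  }
})

test_that("per-sex mean error recovers sex-specific injected bias", {
  cohort <- generate_cohort(cohort_preset("NWAHS-FAMAS", n = 20000,
                                          seed = 33))
  # inject +1.5 kg reference shift for men, -0.8 for women: predictions then
  # under/over-estimate by exactly those amounts on average
  shift <- ifelse(cohort$sex == "male", 1.5, -0.8)
  cohort$lbm_dxa <- cohort$lbm_dxa + shift
  rep <- suppressWarnings(
    stratified_report(cohort, "pe1",
                      stratification_scheme(bmi_breaks = NULL,
                                            age_breaks = NULL))
  )
  noise_se <- 3.61 / sqrt(8000)
  me_men <- rep$me[rep$stratum == "men"]
  me_women <- rep$me[rep$stratum == "women"]
  expect_lt(abs(me_men - (-1.5)), 4 * noise_se)
  expect_lt(abs(me_women - 0.8), 4 * noise_se)
})

test_that("empty strata emit n = 0 rows with blank statistics", {
  cohort <- generate_cohort(cohort_preset("CASA", n = 60, seed = 34))
  cohort$sex <- "female"
  rep <- suppressWarnings(
    stratified_report(cohort, "pe1",
                      stratification_scheme(bmi_breaks = NULL,
                                            age_breaks = NULL))
  )
  men <- rep[rep$stratum == "men", ]
  expect_equal(men$n, 0)
  expect_true(is.na(men$me))
  women <- rep[rep$stratum == "women", ]
  expect_equal(women$n, 60)
})
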