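# ABPM summarisation, exclusion flow, derived covariates.

test_that("ABPM summaries are the mean and n-1 SD with invariance properties", {
  r <- data.frame(sbp = c(110, 120, 130), dbp = c(70, 75, 80))
  s <- summarize_abpm(r)
  expect_equal(unname(s["sbp_24h_mean"]), 120)
  expect_equal(unname(s["sbp_24h_sd"]), 10)
  flat <- data.frame(sbp = rep(118, 20), dbp = rep(76, 20))
  expect_equal(unname(summarize_abpm(flat)["sbp_24h_sd"]), 0)
  expect_error(summarize_abpm(data.frame(sbp = 120, dbp = 80)), "insufficient-data")
  # order invariance of the mean; shift invariance of the SD
  perm <- r[c(3, 1, 2), ]
  expect_equal(summarize_abpm(perm)["sbp_24h_mean"], s["sbp_24h_mean"])
  shifted <- r; shifted$sbp <- shifted$sbp + 7
  expect_equal(summarize_abpm(shifted)["sbp_24h_sd"], s["sbp_24h_sd"])
  # weighted mean on an uneven grid differs from the plain mean
  r$timestamp_minutes <- c(0, 30, 600)
  expect_false(summarize_abpm(r, weighted = TRUE)["sbp_24h_mean"] ==
                 summarize_abpm(r)["sbp_24h_mean"])
})

test_that("exclusion flow counts each participant once, in rule order", {
  df <- data.frame(med = c(rep(TRUE, 2), rep(FALSE, 8)),
                   bmi = c(25, NA, NA, rep(24, 7)))
  flow <- apply_exclusions(df, list(
    med = function(d) d$med,
    missing = function(d) is.na(d$bmi)))
  expect_equal(flow$n_eligible, 7)
  expect_equal(unname(flow$ledger), c(2L, 1L))
  # participant 2 is on medication AND has missing BMI: counted under 'med'
  expect_equal(flow$n_input, flow$n_eligible + sum(flow$ledger))
  expect_error(apply_exclusions(df, list(function(d) d$med)), "must be named")
  expect_error(apply_exclusions(df, list(bad = "not a function")), "predicate")
})

test_that("flow conservation holds for arbitrary rule sets", {
  set.seed(31)
  for (rep in 1:5) {
    df <- data.frame(a = runif(50) < 0.3, b = runif(50) < 0.2, c = runif(50) < 0.4)
    flow <- apply_exclusions(df, list(r1 = function(d) d$a,
                                      r2 = function(d) d$b,
                                      r3 = function(d) d$c))
    expect_equal(flow$n_input, flow$n_eligible + sum(flow$ledger))
  }
})

test_that("energy plausibility bounds are sex-specific and strict", {
  expect_true(energy_plausibility_filter("female", 450))
  expect_false(energy_plausibility_filter("male", 5500))
  expect_true(energy_plausibility_filter("male", 6001))
  expect_false(energy_plausibility_filter("male", 6000))
  expect_true(energy_plausibility_filter("female", 5001))
  expect_false(energy_plausibility_filter("female", 500))
})

test_that("fiber density is g per 1000 kcal with a positive-energy domain", {
  expect_equal(fiber_per_1000kcal(30, 2000), 15)
  expect_equal(fiber_per_1000kcal(0, 2000), 0)
  expect_error(fiber_per_1000kcal(30, 0), "domain error")
})

test_that("sodium estimate matches the hand-evaluated spot-urine equations", {
  # independent hand evaluation for a 57-year-old 80 kg, 175 cm male with
  # spot Na 55.3 mmol/L and spot creatinine 11.3 mmol/L
  prcr <- -12.63 * 57 + 15.12 * 80 + 7.39 * 175 - 79.9       # mg/day
  xna <- 55.3 / (11.3 * 11.312 * 10) * prcr
  expected_mg <- 16.3 * sqrt(xna) * 22.99
  got <- kawasaki_sodium("male", 57, 80, 175, 55.3, 11.3)
  expect_equal(got$sodium_mg_day, expected_mg, tolerance = 1e-12)
  expect_equal(got$log_sodium, log(expected_mg))
  # the estimate should land in a physiologic range (grams per day)
  expect_gt(got$sodium_mg_day, 1000)
  expect_lt(got$sodium_mg_day, 10000)

  # sqrt scaling in spot sodium; monotone decreasing in creatinine
  base <- kawasaki_sodium("female", 55, 65, 163, 50, 10)$sodium_mg_day
  expect_equal(kawasaki_sodium("female", 55, 65, 163, 100, 10)$sodium_mg_day,
               base * sqrt(2))
  expect_lt(kawasaki_sodium("female", 55, 65, 163, 50, 14)$sodium_mg_day, base)
  expect_error(kawasaki_sodium("male", 57, 80, 175, 55, 0), "domain error")
  expect_error(kawasaki_sodium("male", 57, -80, 175, 55, 10), "domain error")
})

test_that("PPI flag is an and/or rule over named drug metabolites", {
  m <- data.frame(omeprazole = c(1.2, NA, NA), pantoprazole = c(NA, NA, 0.4))
  expect_equal(ppi_flag(m), c(TRUE, FALSE, TRUE))
  expect_error(ppi_flag(m[, 1, drop = FALSE]), "absent")
})

test_that("complete-case selection reports missing columns and rows", {
  df <- data.frame(a = c(1, NA, 3), b = c(1, 2, 3))
  expect_equal(complete_cases_for(df, c("a", "b")), c(TRUE, FALSE, TRUE))
  expect_error(complete_cases_for(df, "zz"), "absent")
})
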