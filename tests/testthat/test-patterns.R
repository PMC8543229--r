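test_that("Kaplan-Meier estimates equal the hand-computed product limit", {
  cohort <- data.frame(
    person_id = sprintf("P%d", 1:10),
    sex = "male", age_group = "18-29",
    time = c(2, 3, 5, 5, rep(10, 6)),
    event = c(1, 0, 1, 1, rep(0, 6)))
  km <- km_estimate(cohort, strata = character(0))
  expect_equal(km_surv_at(km, "all", 2), 0.9)
  expect_equal(km_surv_at(km, "all", 5), 0.675)   # (1-1/10)(1-2/8)
  expect_equal(km_surv_at(km, "all", 1), 1)
  # survival is non-increasing and bounded
  ev <- km[km$n_event > 0, ]
  expect_true(all(diff(ev$surv[order(ev$time)]) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("KM degenerate cases: no events and all events", {
  none <- data.frame(time = c(5, 8, 10), event = c(0, 0, 0))
  km0 <- km_estimate(none, strata = character(0))
  expect_equal(km_surv_at(km0, "all", 100), 1)
  all_ev <- data.frame(time = c(1, 1, 1), event = c(1, 1, 1))
  km1 <- km_estimate(all_ev, strata = character(0))
  expect_equal(km_surv_at(km1, "all", 1), 0)
})

test_that("without censoring 1 - S(t) is the empirical CDF", {
  set.seed(12)
  t <- sample(1:50, 40, replace = TRUE)
  cohort <- data.frame(time = t, event = 1)
  km <- km_estimate(cohort, strata = character(0))
  for (tt in c(5, 17, 33, 50)) {
    expect_equal(1 - km_surv_at(km, "all", tt), mean(t <= tt))
  }
})

test_that("KM agrees with the direct product-limit oracle per stratum", {
  set.seed(3)
  cohort <- data.frame(
    sex = sample(c("male", "female"), 60, TRUE),
    age_group = "6-12",
    time = sample(1:100, 60, TRUE),
    event = rbinom(60, 1, 0.7))
  km <- km_estimate(cohort, strata = "sex")
  for (s in c("male", "female")) {
    sub <- cohort[cohort$sex == s, ]
    oracle <- oracle_km(sub$time, sub$event)
    for (tt in c(10, 40, 80)) {
      expect_equal(km_surv_at(km, s, tt), oracle_km_at(oracle, tt))
    }
  }
})

test_that("incident users require a clean wash-out and minimum age", {
  d <- function(x) as.Date(x)
  recs <- make_records(
    # incident: first-ever dispensation inside 2013
    make_record(record_id = "R1", person_id = "PA",
                dispensation_date = d("2013-03-01")),
    # excluded: dispensation 100 days before the window entry
    make_record(record_id = "R2", person_id = "PB",
                dispensation_date = d("2012-11-21")),
    make_record(record_id = "R3", person_id = "PB",
                dispensation_date = d("2013-03-01")),
    # excluded: under age
    make_record(record_id = "R4", person_id = "PC", age = 5L,
                dispensation_date = d("2013-05-01")),
    # incident: prior use beyond the wash-out window
    make_record(record_id = "R5", person_id = "PD",
                dispensation_date = d("2011-06-01")),
    make_record(record_id = "R6", person_id = "PD",
                dispensation_date = d("2013-06-01")))
  strata <- rbind(
    make_stratum(person_id = "PA", period_start = "2013-03-01",
                 period_end = "2013-07-01"),
    make_stratum(person_id = "PB", period_start = "2013-03-01",
                 period_end = "2013-05-01", period_id = 2L),
    make_stratum(person_id = "PC", period_start = "2013-05-01",
                 period_end = "2013-06-01", period_id = 3L),
    make_stratum(person_id = "PD", period_start = "2011-06-01",
                 period_end = "2011-07-13", period_id = 4L),
    make_stratum(person_id = "PD", period_start = "2013-06-01",
                 period_end = "2014-03-01", period_id = 5L))
  cohort <- find_incident_users(recs, strata, year = 2013)
  expect_setequal(cohort$person_id, c("PA", "PD"))
  pa <- cohort[cohort$person_id == "PA", ]
  expect_equal(pa$event, 1L)
  expect_equal(pa$time, as.numeric(d("2013-07-01") - d("2013-03-01")))
  # PD's episode crosses the administrative censoring date
  pd <- cohort[cohort$person_id == "PD", ]
  expect_equal(pd$event, 0L)
  expect_equal(pd$time, as.numeric(d("2013-12-31") - d("2013-06-01")))
})

test_that("wash-out is causal: later dispensations cannot change incident status", {
  recs <- make_records(
    make_record(record_id = "R1", person_id = "PA",
                dispensation_date = as.Date("2013-03-01")),
    make_record(record_id = "R2", person_id = "PA",
                dispensation_date = as.Date("2013-11-01")))
  strata <- make_stratum(person_id = "PA", period_start = "2013-03-01",
                         period_end = "2013-12-15")
  with_future <- find_incident_users(recs, strata, year = 2013)
  without <- find_incident_users(recs[1, ], strata, year = 2013)
  expect_equal(with_future$index_date, without$index_date)
  expect_equal(nrow(with_future), 1)
})

test_that("single-prescription users are dropped in the sensitivity cohort", {
  cohort <- data.frame(person_id = c("PA", "PB"),
                       n_dispensations = c(1L, 2L))
  class(cohort) <- c("incident_cohort", "data.frame")
  out <- single_prescription_sensitivity(cohort)
  expect_equal(out$person_id, "PB")
  expect_equal(nrow(single_prescription_sensitivity(cohort[0, ])), 0)
})

test_that("dose categories partition at 30 and 60 mg", {
  expect_equal(as.character(dose_category(c(0, 30, 31, 45, 60, 61, 200))),
               c("low", "low", "medium", "medium", "medium", "high", "high"))
  expect_false(anyNA(dose_category(seq(0, 150, by = 0.5))))
  expect_error(dose_category(-1), ">= 0")
})

test_that("person dose takes the longest period's duration-weighted mean", {
  one <- make_stratum(period_start = "2013-01-01", period_end = "2013-04-11",
                      dose_mg_per_day = 36)
  expect_equal(person_dose(one, "N06BA04"), 36)
  # longest of two periods wins
  two <- rbind(
    make_stratum(period_id = 1L, period_start = "2013-01-01",
                 period_end = "2013-01-31", dose_mg_per_day = 20),
    make_stratum(period_id = 2L, period_start = "2013-03-01",
                 period_end = "2013-09-17", dose_mg_per_day = 54))
  expect_equal(person_dose(two, "N06BA04"), 54)
  # strata weighted by duration: 60 d @ 20 + 40 d @ 40 -> 28
  strat <- rbind(
    make_stratum(period_id = 1L, period_start = "2013-01-01",
                 period_end = "2013-04-11",
                 stratum_start = "2013-01-01", stratum_end = "2013-03-02",
                 dose_mg_per_day = 20),
    make_stratum(period_id = 1L, period_start = "2013-01-01",
                 period_end = "2013-04-11",
                 stratum_start = "2013-03-02", stratum_end = "2013-04-11",
                 dose_mg_per_day = 40))
  expect_equal(person_dose(strat, "N06BA04"), 28)
  expect_error(person_dose(one, "N06BA09"), "no treatment period")
})
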