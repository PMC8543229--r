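test_that("expected length is the exact pills/dosage quotient", {
  expect_equal(expected_length(30, 1), 30)
  expect_equal(expected_length(100, 3), 100 / 3)
  expect_equal(expected_length(15, 0.5), 30)
  expect_error(expected_length(30, 0), "> 0")
})

test_that("clamping clips to 1-90 days and updates the dosage", {
  out <- clamp_length(200, 200)              # 200 pills at 1/day
  expect_equal(out$days, 90)
  expect_equal(out$pills_per_day, 200 / 90)
  out2 <- clamp_length(0.2, 2)               # 2 pills at 10/day
  expect_equal(out2$days, 1)
  expect_equal(out2$pills_per_day, 2)
  out3 <- clamp_length(30, 30)
  expect_equal(out3$days, 30)
  expect_equal(out3$pills_per_day, 1)        # unchanged inside range
})

test_that("adherence extension multiplies by 7/5 and refuses contraction", {
  expect_equal(apply_adherence(30), 42)
  expect_equal(apply_adherence(90), 126)
  expect_equal(apply_adherence(13, coefficient = 1), 13)
  expect_error(apply_adherence(10, coefficient = 0.8), ">= 1")
})

test_that("titrated supplies walk the stated schedule", {
  out <- titrated_length(c(1, 2), c(7, NA), 35)
  expect_equal(out$days, 21)                 # 7 + (35-7)/2
  expect_equal(out$profile$days, c(7, 14))
  expect_equal(out$profile$pills_per_day, c(1, 2))
  # pills exhausted inside the first interval
  short <- titrated_length(c(1, 2), c(7, NA), 5)
  expect_equal(short$days, 5)
  expect_equal(nrow(short$profile), 1)
  # single segment behaves like a regular supply
  one <- titrated_length(2, NA, 60)
  expect_equal(one$days, 30)
  # no usable schedule -> flagged flat dose at the maintenance dosage
  flagged <- titrated_length(c(1, 2), c(NA, NA), 30)
  expect_true(isTRUE(attr(flagged, "flagged")))
  expect_equal(flagged$days, 15)
})

test_that("a single dispensation yields one period of its extended length", {
  rec <- make_record(record_id = "R1", n_packages = 1, package_size = 30)
  rec$pills_per_day <- 1
  sup <- build_supplies(rec)
  expect_equal(sup$expected_days, 30)
  expect_equal(sup$clamped_days, 30)
  expect_equal(sup$extended_days, 42)
  per <- join_periods(sup)
  expect_equal(nrow(per), 1)
  expect_equal(as.numeric(per$period_end - per$period_start), 42)
  expect_equal(per$dose_mg_per_day, 18)
})

test_that("stockpiled refills join; late refills open a new period", {
  d0 <- as.Date("2013-01-01")
  mk <- function(id, date) {
    r <- make_record(record_id = id, dispensation_date = date)
    r$pills_per_day <- 1
    r
  }
  # refill on day 30 while 12 days of supply remain -> one 84-day period
  sup <- build_supplies(rbind(mk("R1", d0), mk("R2", d0 + 30)))
  per <- join_periods(sup)
  info <- unique(per[c("period_id", "period_start", "period_end",
                       "n_dispensations")])
  expect_equal(nrow(info), 1)
  expect_equal(as.numeric(info$period_end - info$period_start), 84)
  expect_equal(info$n_dispensations, 2L)
  # refill on day 60, after the 42-day supply lapsed -> two periods
  sup2 <- build_supplies(rbind(mk("R1", d0), mk("R2", d0 + 60)))
  per2 <- join_periods(sup2)
  info2 <- unique(per2[c("period_id", "period_start", "period_end")])
  expect_equal(nrow(info2), 2)
  expect_equal(as.numeric(info2$period_start), as.numeric(c(d0, d0 + 60)))
  expect_equal(as.numeric(info2$period_end - info2$period_start), c(42, 42))
})

test_that("different medications are independent streams", {
  d0 <- as.Date("2013-01-01")
  r1 <- make_record(record_id = "R1", dispensation_date = d0)
  r2 <- make_record(record_id = "R2", dispensation_date = d0 + 10,
                    atc = "N06BA09", article_number = "A20040",
                    strength_mg = 40, package_size = 28)
  r1$pills_per_day <- 1; r2$pills_per_day <- 1
  per <- join_periods(build_supplies(rbind(r1, r2)))
  expect_equal(sort(unique(per$atc)), c("N06BA04", "N06BA09"))
  expect_equal(nrow(unique(per[c("atc", "period_id")])), 2)
})

test_that("dose strata follow mg/day changes and tile each period", {
  d0 <- as.Date("2013-01-01")
  mk <- function(id, date, ppd) {
    r <- make_record(record_id = id, dispensation_date = date)
    r$pills_per_day <- ppd
    r
  }
  # dose change at the second dispensation: 1/day then 2/day
  sup <- build_supplies(rbind(mk("R1", d0, 1), mk("R2", d0 + 30, 2)))
  per <- join_periods(sup)
  expect_equal(nrow(per), 2)
  expect_equal(per$dose_mg_per_day, c(18, 36))
  expect_equal(per$stratum_start[2], per$stratum_end[1])     # contiguous
  expect_equal(per$stratum_start[1], per$period_start[1])
  expect_equal(per$stratum_end[2], per$period_end[2])
  # equal doses merge into a single stratum
  sup2 <- build_supplies(rbind(mk("R1", d0, 1), mk("R2", d0 + 30, 1)))
  expect_equal(nrow(join_periods(sup2)), 1)
})

test_that("weight-form dose is pills/day times strength", {
  expect_equal(dose_mg(2, 10), 20)
  expect_equal(dose_mg(0.5, 36), 18)
  expect_error(dose_mg(1, 0), "strength")
})

test_that("pills are conserved through clamping", {
  set.seed(31)
  for (i in 1:50) {
    pills <- sample(c(28, 30, 56, 60, 98, 100, 200), 1)
    ppd <- sample(dosage_codec()$pills, 1)
    rec <- make_record(record_id = "R1", package_size = pills)
    rec$pills_per_day <- ppd
    sup <- build_supplies(rec)
    expect_equal(sup$clamped_days * sup$pills_per_day, sup$pills_total)
  }
})

test_that("period boundaries match the day-walk oracle on random histories", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    d0 <- as.Date("2012-06-01") + sample(0:200, 1)
    dates <- d0 + cumsum(c(0, sample(5:80, n - 1, replace = TRUE)))
    recs <- do.call(rbind, lapply(seq_len(n), function(j) {
      r <- make_record(record_id = sprintf("R%d", j),
                       dispensation_date = dates[j],
                       package_size = sample(c(28, 30, 100), 1))
      r$pills_per_day <- sample(c(0.5, 1, 2, 3, 4), 1)
      r
    }))
    sup <- build_supplies(recs)
    per <- join_periods(sup)
    info <- unique(per[c("period_start", "period_end")])
    oracle <- oracle_daywalk(sup$dispensation_date,
                             vapply(sup$profile, function(p)
                               max(1, round(sum(p$days))), numeric(1)))
    expect_equal(as.numeric(info$period_start), as.numeric(oracle$start))
    expect_equal(as.numeric(info$period_end), as.numeric(oracle$end))
  }
})

test_that("periods have no look-ahead: truncating the future preserves the past", {
  cfg <- synth_config(n_persons = 30, seed = 13)
  reg <- generate_register(cfg)
  recs <- filter_indication(filter_returned(reg$records))$kept
  recs$pills_per_day <- reg$gold$true_pills_per_day[
    match(recs$record_id, reg$gold$record_id)]
  cutoff <- as.Date("2012-06-01")
  full <- join_periods(build_supplies(recs))
  trunc <- join_periods(build_supplies(
    recs[recs$dispensation_date <= cutoff, , drop = FALSE]))
  f <- full[full$period_end <= cutoff, ]
  t <- trunc[trunc$period_end <= cutoff, ]
  ord <- function(x) {
    x <- x[order(x$person_id, x$atc, x$stratum_start), ]
    rownames(x) <- NULL
    x[c("person_id", "atc", "period_start", "period_end",
        "stratum_start", "stratum_end", "dose_mg_per_day")]
  }
  expect_equal(ord(t), ord(f))
})
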