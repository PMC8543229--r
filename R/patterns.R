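#' Age bands used in the usage-pattern analyses
#'
#' Children 6-12, adolescents 13-17, young adults 18-29, middle-aged
#' adults 30-49 and older adults 50+ (the "above 50" band is read as
#' ages >= 50, matching the 30-49 band below it).
#'
#' @param age Numeric ages in years.
#' @return Factor of age-band labels.
#' @export
age_group <- function(age) {
  .age_band(age)
}

# Merge one person's treatment periods (possibly several medications,
# assumed consumed simultaneously) into person-level episodes: union of
# [start, end) intervals, joining overlapping or touching intervals.
.person_episodes <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  es <- starts[1]; ee <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ee) {
      ee <- max(ee, ends[i])
    } else {
      out_s <- c(out_s, es); out_e <- c(out_e, ee)
      es <- starts[i]; ee <- ends[i]
    }
  }
  data.frame(start = as.Date(c(out_s, es), origin = "1970-01-01"),
             end = as.Date(c(out_e, ee), origin = "1970-01-01"))
}

#' Identify incident medication users with a wash-out window
#'
#' An incident user's index date is the first dispensation inside the
#' calendar window with no dispensation of any study medication in the
#' preceding `washout_days`.  Users are followed from index until their
#' continuous treatment episode (person-level union of treatment
#' periods across medications) ends, or administrative censoring at the
#' window end.  Incident status is causal: dispensations after the
#' index date never affect it.
#'
#' @param records Filtered prescription records (study medications).
#' @param periods Period-strata table from [join_periods()].
#' @param year Calendar year of the window (index dates and censoring).
#' @param washout_days Wash-out length (default 365).
#' @param min_age Minimum age at index (default 6).
#' @return A data.frame (class `incident_cohort`): `person_id`,
#'   `index_date`, `sex`, `age`, `age_group`, `time` (days),
#'   `event` (1 = discontinued before censoring), `n_dispensations`
#'   (study dispensations from index to window end).
#' @export
find_incident_users <- function(records, periods, year = 2013,
                                washout_days = 365, min_age = 6) {
  win_start <- as.Date(sprintf("%d-01-01", year))
  win_end <- as.Date(sprintf("%d-12-31", year))
  out <- list()
  per_info <- unique(periods[c("person_id", "period_id", "period_start",
                               "period_end")])
  for (pid in unique(records$person_id)) {
    rec <- records[records$person_id == pid, , drop = FALSE]
    dates <- sort(rec$dispensation_date)
    in_win <- dates[dates >= win_start & dates <= win_end]
    if (length(in_win) == 0) next
    index <- in_win[1]
    prior <- dates[dates < index & dates >= index - washout_days]
    if (length(prior)) next
    age <- rec$age[rec$dispensation_date == index][1]
    if (age < min_age) next
    pp <- per_info[per_info$person_id == pid, , drop = FALSE]
    if (nrow(pp) == 0) next
    ep <- .person_episodes(pp$period_start, pp$period_end)
    hit <- which(ep$start <= index & ep$end > index)
    if (length(hit) == 0) next
    disc <- ep$end[hit[1]]
    event <- as.integer(disc <= win_end)
    time <- as.numeric((if (event == 1) disc else win_end) - index)
    out[[length(out) + 1L]] <- data.frame(
      person_id = pid, index_date = index,
      sex = rec$sex[1], age = age,
      age_group = as.character(age_group(age)),
      time = time, event = event,
      n_dispensations = sum(rec$dispensation_date >= index &
                              rec$dispensation_date <= win_end),
      stringsAsFactors = FALSE)
  }
  cohort <- if (length(out)) do.call(rbind, out) else
    data.frame(person_id = character(0), index_date = as.Date(character(0)),
               sex = character(0), age = numeric(0), age_group = character(0),
               time = numeric(0), event = integer(0),
               n_dispensations = integer(0))
  rownames(cohort) <- NULL
  class(cohort) <- c("incident_cohort", "data.frame")
  cohort
}

#' Sensitivity cohort without single-prescription users
#'
#' @param cohort An [find_incident_users()] cohort.
#' @return The subcohort of users with at least two study dispensations.
#' @export
single_prescription_sensitivity <- function(cohort) {
  out <- cohort[cohort$n_dispensations >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier discontinuation curves by stratum
#'
#' Product-limit estimate of remaining on treatment, per stratum
#' (default sex x age group).  Fitted with [survival::survfit()]; ties
#' are handled by simultaneous multiplication at each distinct event
#' time.  Empty strata are omitted.
#'
#' @param cohort An incident cohort with `time` and `event` columns.
#' @param strata Character vector of stratifying columns (possibly
#'   empty for a single pooled curve).
#' @return A data.frame of class `km_curves`: `stratum`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(cohort, strata = c("sex", "age_group")) {
  stopifnot(nrow(cohort) >= 1)
  df <- as.data.frame(cohort)
  df$.stratum <- if (length(strata)) {
    interaction(df[strata], sep = "/", drop = TRUE)
  } else factor("all")
  fit <- survival::survfit(survival::Surv(time, event) ~ .stratum,
                           data = df)
  sm <- summary(fit, censored = TRUE)
  strat <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^\\.stratum=", "", as.character(sm$strata))
  out <- data.frame(stratum = strat, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    surv = sm$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curves", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: survival at the largest tabulated time not
#' exceeding `t` (1 before the first).
#'
#' @param km A `km_curves` table.
#' @param stratum Stratum label (use `"all"` for pooled fits).
#' @param t Time(s), same unit as the fit (days).
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(km, stratum, t) {
  cur <- km[km$stratum == stratum & km$n_event > 0, , drop = FALSE]
  cur <- cur[order(cur$time), , drop = FALSE]
  vapply(t, function(tt) {
    i <- which(cur$time <= tt)
    if (length(i) == 0) 1 else cur$surv[max(i)]
  }, numeric(1))
}

#' Categorise a prescribed daily dose (weight form)
#'
#' Low 0-30 mg/day, medium 31-60 (i.e. above 30 up to 60), high above
#' 60; the three categories partition the nonnegative axis.
#'
#' @param mg_per_day Nonnegative mg/day values.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
dose_category <- function(mg_per_day) {
  if (any(mg_per_day < 0, na.rm = TRUE)) stop("mg_per_day must be >= 0")
  cut(mg_per_day, breaks = c(-Inf, 30, 60, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' Representative daily dose of one person for one medication
#'
#' The duration-weighted mean mg/day over the strata of the person's
#' longest treatment period of that medication (ties broken toward the
#' earliest period).
#'
#' @param period_strata Period-strata rows of one person.
#' @param atc Medication ATC code.
#' @return mg/day (scalar).
#' @export
person_dose <- function(period_strata, atc) {
  ps <- period_strata[period_strata$atc == atc, , drop = FALSE]
  if (nrow(ps) == 0) stop("person has no treatment period for ", atc)
  info <- unique(ps[c("period_id", "period_start", "period_end")])
  info$dur <- as.numeric(info$period_end - info$period_start)
  info <- info[order(-info$dur, info$period_start, info$period_id), ]
  best <- info$period_id[1]
  st <- ps[ps$period_id == best, , drop = FALSE]
  days <- as.numeric(st$stratum_end - st$stratum_start)
  sum(days * st$dose_mg_per_day) / sum(days)
}

#' Dose-category distribution of medication users by sex and age group
#'
#' For each user of the medication in the calendar year (any
#' dispensation, age >= `min_age`), takes the person-level dose
#' ([person_dose()]), categorises it and tabulates proportions by sex
#' and age group.
#'
#' @param records Filtered prescription records.
#' @param periods Period-strata table.
#' @param atc Medication ATC (default methylphenidate, N06BA04).
#' @param year Calendar year.
#' @param min_age Minimum age (default 6).
#' @return A data.frame: `sex`, `age_group`, `n`, `low`, `medium`,
#'   `high` (proportions), plus per-person doses as attribute
#'   `person_doses`.
#' @export
dose_categories_by_group <- function(records, periods, atc = "N06BA04",
                                     year = 2013, min_age = 6) {
  win_start <- as.Date(sprintf("%d-01-01", year))
  win_end <- as.Date(sprintf("%d-12-31", year))
  rec <- records[records$atc == atc &
                   records$dispensation_date >= win_start &
                   records$dispensation_date <= win_end &
                   records$age >= min_age, , drop = FALSE]
  persons <- unique(rec$person_id)
  persons <- persons[persons %in% periods$person_id[periods$atc == atc]]
  if (length(persons) == 0)
    return(data.frame(sex = character(0), age_group = character(0),
                      n = integer(0), low = numeric(0), medium = numeric(0),
                      high = numeric(0)))
  doses <- vapply(persons, function(pid) {
    person_dose(periods[periods$person_id == pid, , drop = FALSE], atc)
  }, numeric(1))
  meta <- rec[!duplicated(rec$person_id), c("person_id", "sex", "age")]
  meta <- meta[match(persons, meta$person_id), ]
  df <- data.frame(person_id = persons, sex = meta$sex,
                   age_group = as.character(age_group(meta$age)),
                   mg_per_day = doses,
                   category = as.character(dose_category(doses)),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, paste(df$sex, df$age_group)),
    function(g) {
      data.frame(sex = g$sex[1], age_group = g$age_group[1], n = nrow(g),
                 low = mean(g$category == "low"),
                 medium = mean(g$category == "medium"),
                 high = mean(g$category == "high"),
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  attr(agg, "person_doses") <- df
  agg
}
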