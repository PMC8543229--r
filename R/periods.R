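#' Expected treatment length of a dispensation
#'
#' Number of pills in the dispensed package(s) divided by the daily
#' dosage; real-valued.
#'
#' @param pills_total Total pills dispensed (`n_packages * package_size`).
#' @param pills_per_day Daily dosage in pills (> 0).
#' @return Length in days.
#' @export
expected_length <- function(pills_total, pills_per_day) {
  if (any(pills_per_day <= 0)) stop("pills_per_day must be > 0")
  pills_total / pills_per_day
}

#' Clamp an expected length to the reimbursable range
#'
#' Expected lengths are clipped to `[min_days, max_days]` (default 1 and
#' 90 days — at most a three-month supply is reimbursed at a time).
#' When clipping fires, the daily dosage is updated to
#' `pills_total / clamped length` so that the dispensed pills are
#' conserved.
#'
#' @param expected Expected days (> 0), vectorised.
#' @param pills_total Total pills dispensed.
#' @param min_days,max_days Clamp bounds.
#' @return A list with `days` (clamped) and `pills_per_day` (updated
#'   where clamped, otherwise `pills_total / expected`, i.e. unchanged).
#' @export
clamp_length <- function(expected, pills_total, min_days = 1, max_days = 90) {
  stopifnot(all(expected > 0))
  days <- pmin(pmax(expected, min_days), max_days)
  list(days = days, pills_per_day = pills_total / days)
}

#' Extend a supply length for non-perfect adherence
#'
#' Supplies are stretched by an adherence coefficient, by default 7/5:
#' medication assumed taken on weekdays and sometimes omitted on
#' weekends, so 5 days of pills last about 7 calendar days.
#'
#' @param clamped Clamped supply days.
#' @param coefficient Adherence coefficient (>= 1; extension only).
#' @return Extended days.
#' @export
apply_adherence <- function(clamped, coefficient = 7 / 5) {
  if (coefficient < 1)
    stop("adherence coefficient must be >= 1 (extension, not contraction)")
  clamped * coefficient
}

#' Supply length and dose profile of a titrated dispensation
#'
#' Walks the titration segments in order, consuming
#' `stated_duration * dosage` pills per segment; pills remaining after
#' the last stated duration are consumed at the final segment's dosage.
#' If the pills run out mid-walk the supply ends on the exhaustion day.
#'
#' @param doses Pills/day per segment, in reading order.
#' @param durations Stated duration (days) per segment; the final
#'   segment's may be `NA` (open-ended maintenance dose).
#' @param pills_total Total pills dispensed.
#' @return A list with `days` (total supply length) and `profile`
#'   (data.frame `days`, `pills_per_day` per traversed segment).  When
#'   at most one segment has a usable dose the dispensation is treated
#'   as regular at that dose and the result carries
#'   `attr(, "flagged") = TRUE`.
#' @export
titrated_length <- function(doses, durations, pills_total) {
  stopifnot(length(doses) == length(durations), length(doses) >= 1)
  if (length(doses) == 1) {
    days <- expected_length(pills_total, doses)
    return(list(days = days,
                profile = data.frame(days = days, pills_per_day = doses)))
  }
  known <- !is.na(durations)
  if (sum(known) == 0 || (all(!known[-length(known)]))) {
    # cannot walk the schedule: fall back to the final dose, flagged
    d <- doses[length(doses)]
    days <- expected_length(pills_total, d)
    out <- list(days = days,
                profile = data.frame(days = days, pills_per_day = d))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  remaining <- pills_total
  prof_days <- numeric(0)
  prof_dose <- numeric(0)
  n <- length(doses)
  for (k in seq_len(n)) {
    dk <- doses[k]
    if (k < n && !is.na(durations[k])) {
      need <- durations[k] * dk
      if (remaining <= need) {           # exhausted mid-segment
        prof_days <- c(prof_days, remaining / dk)
        prof_dose <- c(prof_dose, dk)
        remaining <- 0
        break
      }
      prof_days <- c(prof_days, durations[k])
      prof_dose <- c(prof_dose, dk)
      remaining <- remaining - need
    } else {                             # final (or open) segment
      prof_days <- c(prof_days, remaining / dk)
      prof_dose <- c(prof_dose, dk)
      remaining <- 0
      break
    }
  }
  list(days = sum(prof_days),
       profile = data.frame(days = prof_days, pills_per_day = prof_dose))
}

#' Build per-dispensation supplies
#'
#' Applies expected-length, clamping and adherence extension to each
#' resolved dispensation and returns a date-sorted supply table per
#' person and ATC.  Titrated dispensations contribute their per-segment
#' dose profile; clamping a titrated supply scales segment durations
#' proportionally (and doses inversely, conserving pills), and the
#' adherence extension scales each segment by the coefficient.
#'
#' @param records Resolved prescription records with `record_id` and
#'   `pills_per_day` columns (plus the register fields).
#' @param profiles Optional named list (by `record_id`) of titration
#'   profiles (data.frames `days`, `pills_per_day`) for titrated
#'   dispensations.
#' @param coefficient Adherence coefficient (default 7/5).
#' @param min_days,max_days Clamp bounds (default 1, 90).
#' @return A data.frame sorted by person, ATC, date with columns
#'   `record_id`, `person_id`, `atc`, `dispensation_date`,
#'   `strength_mg`, `pills_total`, `pills_per_day`, `expected_days`,
#'   `clamped_days`, `extended_days`, plus a `profile` list-column of
#'   extended per-segment profiles.
#' @export
build_supplies <- function(records, profiles = NULL, coefficient = 7 / 5,
                           min_days = 1, max_days = 90) {
  if (nrow(records) == 0) {
    return(records[integer(0), , drop = FALSE])
  }
  stopifnot(!anyNA(records$pills_per_day))
  pills_total <- records$n_packages * records$package_size
  out <- data.frame(
    record_id = records$record_id,
    person_id = records$person_id,
    atc = records$atc,
    dispensation_date = records$dispensation_date,
    strength_mg = records$strength_mg,
    pills_total = pills_total,
    stringsAsFactors = FALSE
  )
  prof_list <- vector("list", nrow(records))
  expected <- numeric(nrow(records))
  clamped <- numeric(nrow(records))
  dose <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    prof <- profiles[[as.character(records$record_id[i])]]
    if (is.null(prof)) {
      e <- expected_length(pills_total[i], records$pills_per_day[i])
      cl <- clamp_length(e, pills_total[i], min_days, max_days)
      expected[i] <- e
      clamped[i] <- cl$days
      dose[i] <- cl$pills_per_day
      prof_list[[i]] <- data.frame(days = cl$days * coefficient,
                                   pills_per_day = cl$pills_per_day)
    } else {
      e <- sum(prof$days)
      cl_days <- min(max(e, min_days), max_days)
      f <- cl_days / e
      expected[i] <- e
      clamped[i] <- cl_days
      dose[i] <- pills_total[i] / cl_days
      prof_list[[i]] <- data.frame(
        days = prof$days * f * coefficient,
        pills_per_day = prof$pills_per_day / f)
    }
  }
  out$pills_per_day <- dose
  out$expected_days <- expected
  out$clamped_days <- clamped
  out$extended_days <- clamped * coefficient
  out$profile <- prof_list
  ord <- order(out$person_id, out$atc, out$dispensation_date, out$record_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Round segment boundaries of one dispensation's profile so whole-day
# strata tile the dispensation's whole-day length exactly.
.integer_profile <- function(profile) {
  total <- max(1, round(sum(profile$days)))
  cum <- round(cumsum(profile$days) / sum(profile$days) * total)
  days <- diff(c(0, cum))
  keep <- days > 0
  data.frame(days = days[keep], pills_per_day = profile$pills_per_day[keep])
}

#' Join dispensation supplies into continuous treatment periods
#'
#' Within one person and medication, a running supply-end date is
#' maintained: a dispensation dated on or before the running end is a
#' stockpiling instance — its supply is appended starting at the
#' running end; a dispensation dated after the running end opens a new
#' period.  This one running-end rule implements both the stockpiling
#' join and the supply-reaches-next-dispensation join.  Supplies of
#' different medications are independent streams and may overlap
#' (assumed consumed simultaneously).  Each period is stratified by
#' changes in the weight-form dose (mg/day = pills/day x strength);
#' adjacent equal-dose strata are merged.  Supply lengths are rounded
#' to whole days (minimum 1) when laid onto the calendar; interval ends
#' are exclusive.
#'
#' @param supplies Supply table from [build_supplies()].
#' @return A data.frame with one row per dose stratum: `person_id`,
#'   `atc`, `period_id`, `period_start`, `period_end`, `stratum_start`,
#'   `stratum_end`, `pills_per_day`, `dose_mg_per_day`,
#'   `n_dispensations`.
#' @export
join_periods <- function(supplies) {
  empty <- data.frame(
    person_id = character(0), atc = character(0), period_id = integer(0),
    period_start = as.Date(character(0)), period_end = as.Date(character(0)),
    stratum_start = as.Date(character(0)), stratum_end = as.Date(character(0)),
    pills_per_day = numeric(0), dose_mg_per_day = numeric(0),
    n_dispensations = integer(0), stringsAsFactors = FALSE)
  if (is.null(supplies) || nrow(supplies) == 0) return(empty)
  res <- list()
  pid <- 0L
  for (key in split(seq_len(nrow(supplies)),
                    paste(supplies$person_id, supplies$atc, sep = "\r"))) {
    idx <- key[order(supplies$dispensation_date[key])]
    run_end <- NULL
    cur <- NULL       # accumulating period: list(start, end, strata, n)
    flush <- function() {
      if (is.null(cur)) return()
      pid <<- pid + 1L
      st <- cur$strata
      # merge adjacent strata with equal mg/day
      keep <- c(TRUE, abs(diff(st$mg)) > 1e-9)
      grp <- cumsum(keep)
      days <- as.vector(tapply(st$days, grp, sum))
      mg <- st$mg[keep]
      ppd <- st$ppd[keep]
      ends <- cur$start + cumsum(days)
      starts <- c(cur$start, ends[-length(ends)])
      res[[length(res) + 1L]] <<- data.frame(
        person_id = cur$person, atc = cur$atc, period_id = pid,
        period_start = cur$start, period_end = ends[length(ends)],
        stratum_start = starts, stratum_end = ends,
        pills_per_day = ppd, dose_mg_per_day = mg,
        n_dispensations = cur$n, stringsAsFactors = FALSE)
    }
    for (i in idx) {
      prof <- .integer_profile(supplies$profile[[i]])
      mg <- prof$pills_per_day * supplies$strength_mg[i]
      d <- supplies$dispensation_date[i]
      if (is.null(run_end) || d > run_end) {
        flush()
        cur <- list(person = supplies$person_id[i], atc = supplies$atc[i],
                    start = d, n = 0L,
                    strata = data.frame(days = numeric(0), ppd = numeric(0),
                                        mg = numeric(0)))
        run_end <- d
      }
      cur$strata <- rbind(cur$strata,
                          data.frame(days = prof$days,
                                     ppd = prof$pills_per_day, mg = mg))
      cur$n <- cur$n + 1L
      run_end <- run_end + sum(prof$days)
    }
    flush()
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Weight-form daily dose
#'
#' @param pills_per_day Pills per day.
#' @param strength_mg mg of active substance per pill (> 0).
#' @return mg/day.
#' @export
dose_mg <- function(pills_per_day, strength_mg) {
  stopifnot(all(strength_mg > 0))
  pills_per_day * strength_mg
}
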