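#' Read a prescription-register extract
#'
#' Reads a flat CSV extract with one row per dispensation and validates
#' each row against the register schema.  Required columns: `person_id`,
#' `age`, `sex`, `atc`, `article_number`, `dispensation_date`,
#' `n_packages`, `package_size`, `strength_mg`, `specialty`, `county`,
#' `free_text`, `returned`.  Dates must be ISO-8601 (`YYYY-MM-DD`).
#' Invalid rows are reported, never silently dropped: the returned data
#' frame carries a `row_errors` attribute with one row per rejected input
#' row, so `nrow(records) + nrow(row_errors)` equals the number of data
#' rows in the file.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @return A data.frame of validated records, in input order, with
#'   attribute `row_errors` (data.frame with columns `row`, `message`).
#'   Empty `free_text` is preserved as the empty string.
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("person_id", "age", "sex", "atc", "article_number",
                "dispensation_date", "n_packages", "package_size",
                "strength_mg", "specialty", "county", "free_text", "returned")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  validate_prescriptions(raw[required])
}

# Coerce and validate a character data.frame of register rows.
# Returns validated records with a row_errors attribute.
validate_prescriptions <- function(raw) {
  n <- nrow(raw)
  msg <- character(n)
  note <- function(idx, m) {
    idx <- which(idx)
    msg[idx] <<- ifelse(msg[idx] == "", m, paste(msg[idx], m, sep = "; "))
  }
  age <- suppressWarnings(as.integer(raw$age))
  note(is.na(age) | age < 0, "age must be an integer >= 0")
  sex <- tolower(raw$sex)
  note(!sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  date <- as.Date(raw$dispensation_date, format = "%Y-%m-%d")
  note(is.na(date), "dispensation_date not an ISO-8601 date")
  n_packages <- suppressWarnings(as.integer(raw$n_packages))
  note(is.na(n_packages) | n_packages < 1, "n_packages must be a count >= 1")
  package_size <- suppressWarnings(as.integer(raw$package_size))
  note(is.na(package_size) | package_size < 1,
       "package_size must be a count >= 1")
  strength <- suppressWarnings(as.numeric(raw$strength_mg))
  note(is.na(strength) | strength <= 0, "strength_mg must be > 0")
  returned <- toupper(raw$returned) %in% c("TRUE", "T", "1", "YES")
  bad_ret <- !toupper(raw$returned) %in%
    c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")
  note(bad_ret, "returned must be a logical flag")

  ok <- msg == ""
  rec <- data.frame(
    person_id = raw$person_id, age = age, sex = sex, atc = raw$atc,
    article_number = raw$article_number, dispensation_date = date,
    n_packages = n_packages, package_size = package_size,
    strength_mg = strength, specialty = raw$specialty, county = raw$county,
    free_text = raw$free_text, returned = returned,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(rec) <- NULL
  errors <- data.frame(row = which(!ok), message = msg[!ok],
                       stringsAsFactors = FALSE)
  if (nrow(errors))
    warning(nrow(errors), " row(s) failed validation; see attr(, 'row_errors')")
  attr(rec, "row_errors") <- errors
  rec
}

#' Write a treatment-period table
#'
#' Writes one CSV row per dose stratum with columns `person_id`, `atc`,
#' `stratum_start`, `stratum_end`, `dose_mg_per_day`, `pills_per_day`,
#' `n_dispensations` (dates ISO-8601, end exclusive).  Re-reading with
#' [read_periods()] yields identical field values.
#'
#' @param periods A period-strata data.frame as produced by
#'   [join_periods()] (or any data.frame with the columns above).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_periods <- function(periods, path) {
  cols <- c("person_id", "atc", "stratum_start", "stratum_end",
            "dose_mg_per_day", "pills_per_day", "n_dispensations")
  out <- if (nrow(periods) == 0) {
    stub <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    stub
  } else {
    missing <- setdiff(cols, names(periods))
    if (length(missing))
      stop("periods table lacks column(s): ", paste(missing, collapse = ", "))
    df <- periods[cols]
    df$stratum_start <- format(as.Date(df$stratum_start), "%Y-%m-%d")
    df$stratum_end <- format(as.Date(df$stratum_end), "%Y-%m-%d")
    df
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a treatment-period table written by [write_periods()]
#'
#' @param path CSV file path.
#' @return A data.frame with typed columns (dates as `Date`).
#' @export
read_periods <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        fileEncoding = "UTF-8")
  if (nrow(df)) {
    df$stratum_start <- as.Date(df$stratum_start)
    df$stratum_end <- as.Date(df$stratum_end)
    df$dose_mg_per_day <- as.numeric(df$dose_mg_per_day)
    df$pills_per_day <- as.numeric(df$pills_per_day)
    df$n_dispensations <- as.integer(df$n_dispensations)
  }
  df
}
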