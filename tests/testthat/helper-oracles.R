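# Independent oracles used by the property tests.  Deliberately share
# no code with the package: the sig parser is regex-based, the period
# oracle advances one calendar day at a time, and the survival oracle
# evaluates the product-limit formula directly.

# ---- sig text oracle ------------------------------------------------------

oracle_noninformative <- function(text) {
  t <- tolower(trimws(sub("\\.$", "", text)))
  t %in% c("enligt ordination", "enligt läkares föreskrift",
           "dosering enligt schema", "enligt överenskommelse",
           "se doseringsanvisning", "")
}

.oracle_num <- function(s) {
  s <- trimws(s)
  if (s %in% c("halv", "½", "0,5", "0.5", "en halv")) return(0.5)
  if (s == "en") return(1)
  if (s == "två") return(2)
  suppressWarnings(as.numeric(s))
}

QTY <- "(en halv|halv|½|0,5|en|två|[0-9]+(?:[.,][0-9]+)?)"
FORM <- "(?:depottablett|tablett|kapsel|kaps|depottabletter|tabletter|kapslar)[a-zåäö]*"

# Parse one (already titration-split) segment to pills/day, or NA.
oracle_parse_segment <- function(seg) {
  t <- tolower(trimws(seg))
  t <- sub("\\.$", "", t)
  t <- sub("^(?:tag|ta)\\s+", "", t)
  # strip stated duration phrases
  t <- sub("\\s+(?:i\\s+[0-9]+\\s+(?:dagar?|veckor?|vecka|månad(?:er)?)|i en vecka|första veckan)\\s*$", "", t)
  # strip add-on clause (minimum-dose convention)
  t <- sub(",?\\s*vid behov ytterligare\\s+[0-9]+\\s*$", "", t)
  # range: minimum taken per day
  m <- regmatches(t, regexec(paste0("^([0-9]+)-([0-9]+)\\s+", FORM), t))[[1]]
  if (length(m)) return(as.numeric(m[2]))
  # split morning/night statement: sum of the two quantities
  pat_split <- paste0("^", QTY, "\\s+", FORM, "\\s+på morgonen och\\s+",
                      QTY, "\\s+", FORM, "\\s+till natten$")
  m <- regmatches(t, regexec(pat_split, t))[[1]]
  if (length(m)) return(.oracle_num(m[2]) + .oracle_num(m[3]))
  # quantity x frequency
  pat_qf <- paste0("^", QTY, "\\s+", FORM, "\\s+(.*)$")
  m <- regmatches(t, regexec(pat_qf, t))[[1]]
  if (!length(m)) return(NA_real_)
  q <- .oracle_num(m[2])
  freq_txt <- m[3]
  f <- if (grepl("^([0-9]+)\\s+gånger", freq_txt)) {
    as.numeric(sub("^([0-9]+)\\s+gånger.*$", "\\1", freq_txt))
  } else if (grepl("^morgon och kväll$", freq_txt)) 2
  else if (freq_txt %in% c("dagligen", "varje dag", "1 gång dagligen",
                           "varje morgon", "till kvällen")) 1
  else NA_real_
  q * f
}

# Full-text oracle: split at connectives, parse each segment; returns
# list(informative, segment_values, final_value).
oracle_parse_sig <- function(text) {
  if (oracle_noninformative(text))
    return(list(informative = FALSE, values = NA_real_, final = NA_real_))
  t <- tolower(text)
  parts <- strsplit(t, ",?\\s*(?:och\\s+)?(?:därefter|sedan)\\s+")[[1]]
  vals <- vapply(parts, oracle_parse_segment, numeric(1), USE.NAMES = FALSE)
  list(informative = TRUE, values = vals, final = vals[length(vals)])
}

# ---- day-walk period oracle ----------------------------------------------

# Brute-force simulator for one person x ATC stream: advance one day at
# a time, add arriving supplies to the stockpile, consume one day of
# supply per day; a period closes on the first day the stockpile is
# empty.  `dates` are dispensation Dates, `days` whole supply days.
oracle_daywalk <- function(dates, days) {
  stopifnot(length(dates) == length(days))
  o <- order(dates)
  dates <- dates[o]; days <- days[o]
  d0 <- min(dates)
  horizon <- as.integer(max(dates) - d0) + sum(days) + 2
  arrive <- tapply(days, as.integer(dates - d0), sum)
  stock <- 0
  open_start <- NA_integer_
  starts <- integer(0); ends <- integer(0)
  for (day in 0:horizon) {
    key <- as.character(day)
    if (!is.na(arrive[key])) stock <- stock + arrive[[key]]
    if (!is.na(open_start) && stock == 0) {
      starts <- c(starts, open_start); ends <- c(ends, day)
      open_start <- NA_integer_
    }
    if (stock > 0) {
      if (is.na(open_start)) open_start <- day
      stock <- stock - 1
    }
  }
  if (!is.na(open_start)) {
    starts <- c(starts, open_start); ends <- c(ends, horizon + 1)
  }
  data.frame(start = d0 + starts, end = d0 + ends)
}

# ---- survival oracle ------------------------------------------------------

# Direct product-limit computation at every distinct event time.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

oracle_km_at <- function(km, t) {
  i <- which(km$time <= t)
  if (length(i) == 0) 1 else km$surv[max(i)]
}
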