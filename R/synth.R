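#' Configuration for the synthetic prescription register
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' an ATC mix of 81.25% methylphenidate and 6.25% each of atomoxetine,
#' amfetamine and dexamfetamine (6500:500:500:500), about 6.5% titrated
#' prescriptions, a dosage-class distribution skewed toward 1-3
#' pills/day, and per-refill discontinuation hazards highest in young
#' adults.  Non-informative texts (10%) carry a true dosage that
#' continues the person's trajectory, so carry-forward imputation is
#' learnable.  `exact_refills = TRUE` (with `adherence_coefficient = 1`
#' and zero hazards/pauses) produces noiseless refill-on-time histories
#' whose true treatment periods the period engine must recover exactly.
#'
#' @param n_persons Number of persons.
#' @param date_start,date_end Initiation window (Date or ISO string).
#' @param class_probs Named probability vector over the 16 dosage
#'   classes.
#' @param fraction_titrated Per-record probability of a titrated sig.
#' @param fraction_noninformative Per-record probability of a
#'   non-informative sig.
#' @param fraction_range,fraction_addon Per-record probabilities of
#'   range ("1-2 tabletter") and add-on ("vid behov ytterligare") sigs.
#' @param refill_gap_mean,refill_gap_sd Refill gap as a fraction of the
#'   extended supply length (normal, truncated to `[0.4, 1.0]`).
#' @param pause_prob Probability that a refill is delayed beyond the
#'   supply (gap factor 1.3-2.5), opening a new treatment period.
#' @param discontinuation_hazard Named per-refill stopping hazards by
#'   age band.
#' @param dose_change_prob Per-refill probability of moving one dosage
#'   class (mostly upward).
#' @param returned_fraction Fraction of extra records flagged as
#'   returned to the pharmacy.
#' @param other_indication_fraction Fraction of persons whose sigs
#'   state a non-ADHD indication (exercises the indication filter).
#' @param adherence_coefficient Coefficient used when laying supplies
#'   on the calendar to drive refill gaps and the true timelines.
#' @param max_dispensations Cap on dispensations per person.
#' @param exact_refills Refill exactly when the supply runs out (used
#'   by the timeline-recovery check).
#' @param seed Integer seed; the same seed reproduces the register
#'   byte-identically.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_persons = 1250L,
                         date_start = "2011-01-01",
                         date_end = "2013-12-31",
                         class_probs = NULL,
                         fraction_titrated = 0.065,
                         fraction_noninformative = 0.10,
                         fraction_range = 0.04,
                         fraction_addon = 0.03,
                         refill_gap_mean = 0.85,
                         refill_gap_sd = 0.12,
                         pause_prob = 0.08,
                         discontinuation_hazard = c("6-12" = 0.05,
                                                    "13-17" = 0.07,
                                                    "18-29" = 0.14,
                                                    "30-49" = 0.08,
                                                    "50+" = 0.09),
                         dose_change_prob = 0.08,
                         returned_fraction = 0.01,
                         other_indication_fraction = 0.01,
                         adherence_coefficient = 7 / 5,
                         max_dispensations = 15L,
                         exact_refills = FALSE,
                         seed = 1L) {
  codec <- dosage_codec()
  if (is.null(class_probs)) {
    class_probs <- c(0.08, 0.30, 0.22, 0.14, 0.08, 0.05, 0.03, 0.02,
                     0.02, 0.01, 0.015, 0.01, 0.008, 0.007, 0.005, 0.005)
    names(class_probs) <- codec$labels
  }
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1")
  frac <- c(fraction_titrated, fraction_noninformative, fraction_range,
            fraction_addon, returned_fraction, other_indication_fraction,
            pause_prob)
  if (any(frac < 0 | frac > 1)) stop("fractions must be in [0, 1]")
  structure(list(
    n_persons = as.integer(n_persons),
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    class_probs = class_probs,
    fraction_titrated = fraction_titrated,
    fraction_noninformative = fraction_noninformative,
    fraction_range = fraction_range, fraction_addon = fraction_addon,
    refill_gap_mean = refill_gap_mean, refill_gap_sd = refill_gap_sd,
    pause_prob = pause_prob,
    discontinuation_hazard = discontinuation_hazard,
    dose_change_prob = dose_change_prob,
    returned_fraction = returned_fraction,
    other_indication_fraction = other_indication_fraction,
    adherence_coefficient = adherence_coefficient,
    max_dispensations = as.integer(max_dispensations),
    exact_refills = exact_refills,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Article catalog of the synthetic register
#'
#' Nordic-article-style package catalog: per ATC, a few articles with
#' strength (mg/pill) and package size (pills).
#'
#' @return A data.frame with `atc`, `article_number`, `strength_mg`,
#'   `package_size`.
#' @export
article_catalog <- function() {
  data.frame(
    atc = c("N06BA04", "N06BA04", "N06BA04", "N06BA04", "N06BA04",
            "N06BA09", "N06BA09", "N06BA09",
            "N06BA01", "N06BA02", "N06BA02"),
    article_number = c("A10010", "A10018", "A10036", "A10054", "A10020",
                       "A20040", "A20060", "A20080",
                       "A30005", "A40005", "A40010"),
    strength_mg = c(10, 18, 36, 54, 20, 40, 60, 80, 5, 5, 10),
    package_size = c(100, 30, 30, 30, 30, 28, 28, 28, 100, 100, 100),
    stringsAsFactors = FALSE
  )
}

# ---- sig grammar ----------------------------------------------------------

.num_token <- function(q, allow_words = TRUE) {
  if (q == 0.5) return(sample(c("halv", "½", "0,5"), 1))
  if (allow_words && q <= 2 && stats::runif(1) < 0.2)
    return(c("en", "två")[q])
  format(q)
}

.form_word <- function(q, base = sample(c("tablett", "kapsel",
                                          "depottablett"), 1)) {
  plural <- !(q == 0.5 || q == 1)
  if (!plural) return(base)
  switch(base,
         tablett = "tabletter",
         kapsel = "kapslar",
         depottablett = "depottabletter")
}

.freq_phrase <- function(f) {
  if (f == 1) sample(c("dagligen", "varje dag", "1 gång dagligen",
                       "varje morgon", "till kvällen"), 1)
  else if (f == 2) sample(c("2 gånger dagligen", "morgon och kväll"), 1)
  else paste(f, "gånger dagligen")
}

.noninformative_pool <- function() {
  c("enligt ordination", "enligt läkares föreskrift",
    "dosering enligt schema", "enligt överenskommelse",
    "se doseringsanvisning", "")
}

# One regular (single-interval) phrase realizing v pills/day.
.regular_phrase <- function(v, form_base) {
  cands <- list(list(kind = "qf", q = v, f = 1))
  if (v %% 2 == 0 && v >= 2)
    cands <- c(cands, list(list(kind = "qf", q = v / 2, f = 2)))
  if (v == 1)
    cands <- c(cands, list(list(kind = "qf", q = 0.5, f = 2)))
  if (v %% 3 == 0 && v >= 3)
    cands <- c(cands, list(list(kind = "qf", q = v / 3, f = 3)))
  if (v >= 2 && v == floor(v))
    cands <- c(cands, list(list(kind = "split", q1 = floor(v / 2),
                                q2 = v - floor(v / 2))))
  pick <- cands[[sample.int(length(cands), 1)]]
  if (pick$kind == "split") {
    paste0(.num_token(pick$q1), " ", .form_word(pick$q1, form_base),
           " på morgonen och ", .num_token(pick$q2), " ",
           .form_word(pick$q2, form_base), " till natten")
  } else {
    q <- pick$q
    num <- .num_token(q)
    lead <- if (num == "halv") "en halv" else num
    paste0(lead, " ", .form_word(q, form_base), " ", .freq_phrase(pick$f))
  }
}

.duration_phrase <- function() {
  opts <- list(c("i 3 dagar", 3), c("i 4 dagar", 4), c("i 5 dagar", 5),
               c("i 10 dagar", 10), c("i 1 vecka", 7), c("i 2 veckor", 14),
               c("första veckan", 7))
  o <- opts[[sample.int(length(opts), 1)]]
  list(text = o[1], days = as.numeric(o[2]))
}

.surface_noise <- function(text) {
  if (!nzchar(text)) return(text)
  if (stats::runif(1) < 0.25)
    text <- paste(sample(c("tag", "ta"), 1), text)
  if (stats::runif(1) < 0.5)
    text <- paste0(toupper(substr(text, 1, 1)), substring(text, 2))
  if (stats::runif(1) < 0.3) text <- paste0(text, ".")
  text
}

#' Generate one synthetic dosing text
#'
#' Draws a Swedish-style sig realizing the requested daily dosage (or a
#' non-informative text), together with its gold label and, for
#' titrated sigs, the per-segment truth.  Uses the current RNG state.
#'
#' @param dosage_class Target dosage class label (ignored for
#'   `kind = "noninformative"`).
#' @param kind One of `"regular"`, `"titrated"`, `"range"`, `"addon"`,
#'   `"noninformative"`.
#' @param codec Dosage codec.
#' @return A list: `text`, `informative`, `dosage_class`,
#'   `pills_per_day` (final/maintenance dose; `NA` for
#'   non-informative), and `segments` (data.frame `segment_index`,
#'   `pills_per_day`, `duration_days`; one row unless titrated).
#' @export
generate_sig <- function(dosage_class,
                         kind = c("regular", "titrated", "range", "addon",
                                  "noninformative"),
                         codec = dosage_codec()) {
  kind <- match.arg(kind)
  if (kind == "noninformative") {
    return(list(text = sample(.noninformative_pool(), 1),
                informative = FALSE, dosage_class = NA_character_,
                pills_per_day = NA_real_,
                segments = data.frame(segment_index = 0L,
                                      pills_per_day = NA_real_,
                                      duration_days = NA_real_)))
  }
  idx <- match(dosage_class, codec$labels)
  if (is.na(idx)) stop("unknown dosage class: ", dosage_class)
  v <- codec$pills[idx]
  form_base <- sample(c("tablett", "kapsel", "depottablett"), 1)
  if (kind == "range" && (v != floor(v) || v > 9)) kind <- "regular"
  if (kind == "addon" && v != floor(v)) kind <- "regular"
  if (kind == "titrated" && idx < 2) kind <- "regular"

  if (kind == "titrated") {
    n_seg <- sample(2:3, 1, prob = c(0.8, 0.2))
    n_seg <- min(n_seg, idx)                # need strictly increasing doses
    lower <- sort(sample(seq_len(idx - 1), n_seg - 1))
    seg_idx <- c(lower, idx)
    seg_v <- codec$pills[seg_idx]
    texts <- character(n_seg)
    durs <- rep(NA_real_, n_seg)
    for (k in seq_len(n_seg)) {
      phr <- .regular_phrase(seg_v[k], form_base)
      if (k < n_seg) {
        d <- .duration_phrase()
        phr <- paste(phr, d$text)
        durs[k] <- d$days
      }
      texts[k] <- phr
    }
    conn <- sample(c(", därefter ", ", sedan ", " och därefter "),
                   n_seg - 1, replace = TRUE)
    text <- texts[1]
    for (k in 2:n_seg) text <- paste0(text, conn[k - 1], texts[k])
    return(list(text = .surface_noise(text), informative = TRUE,
                dosage_class = dosage_class, pills_per_day = v,
                segments = data.frame(segment_index = seq_len(n_seg) - 1L,
                                      pills_per_day = seg_v,
                                      duration_days = durs)))
  }

  text <- if (kind == "range") {
    hi <- v + sample(1:2, 1)
    tail <- sample(c("dagligen", "vid behov"), 1)
    paste0(v, "-", hi, " ", .form_word(hi, form_base), " ", tail)
  } else if (kind == "addon") {
    paste0(.regular_phrase(v, form_base), ", vid behov ytterligare 1")
  } else {
    .regular_phrase(v, form_base)
  }
  list(text = .surface_noise(text), informative = TRUE,
       dosage_class = dosage_class, pills_per_day = v,
       segments = data.frame(segment_index = 0L, pills_per_day = v,
                             duration_days = NA_real_))
}

# Supply days the generator's own rules assign to a dispensation
# (expected -> clamp 1..90 -> adherence -> whole days); titration walks
# the stated schedule.  Kept inline so the truth timelines do not rely
# on the period engine under test.
.gen_supply_days <- function(pills_total, segments, coeff) {
  segs <- segments[!is.na(segments$pills_per_day), , drop = FALSE]
  if (nrow(segs) <= 1) {
    days <- pills_total / segs$pills_per_day[1]
  } else {
    remaining <- pills_total
    days <- 0
    for (k in seq_len(nrow(segs))) {
      dk <- segs$pills_per_day[k]
      dur <- segs$duration_days[k]
      if (k < nrow(segs) && !is.na(dur) && remaining > dur * dk) {
        days <- days + dur
        remaining <- remaining - dur * dk
      } else {
        days <- days + remaining / dk
        remaining <- 0
        break
      }
    }
  }
  days <- min(max(days, 1), 90)
  max(1L, as.integer(round(days * coeff)))
}

.age_band <- function(age) {
  cut(age, breaks = c(6, 13, 18, 30, 50, Inf), right = FALSE,
      labels = c("6-12", "13-17", "18-29", "30-49", "50+"))
}

#' Generate a synthetic prescription register
#'
#' Simulates persons with longitudinal dispensation histories: an
#' initiation date, a dosage trajectory (occasional titration at onset,
#' occasional dose changes), refill gaps drawn around the supply length
#' (some early refills creating stockpiling, some long pauses and
#' terminal discontinuations), Swedish-style sig texts with gold labels,
#' plus injected returned dispensations and non-ADHD-indication texts to
#' exercise the record filters.  The same seed reproduces the register
#' exactly.
#'
#' @param config A [synth_config()].
#' @return An object of class `synthetic_register`: list with
#'   `records` (register rows incl. `record_id`), `gold` (per-record
#'   informativeness, dosage class, true pills/day, flags), `segments`
#'   (per-titration-segment truth), `timelines` (true continuous
#'   treatment periods per person and ATC under the generator's own
#'   supply rules) and `config`.
#' @export
generate_register <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  codec <- dosage_codec()
  catalog <- article_catalog()
  atc_probs <- c(N06BA04 = 0.8125, N06BA09 = 0.0625,
                 N06BA01 = 0.0625, N06BA02 = 0.0625)
  counties <- sprintf("C%02d", 1:20)
  specialties <- sprintf("S%d", 1:6)

  rec_rows <- list(); gold_rows <- list(); seg_rows <- list()
  tl_rows <- list()
  rec_counter <- 0L

  for (p in seq_len(config$n_persons)) {
    person_id <- sprintf("P%05d", p)
    age <- sample(6:64, 1, prob = stats::dexp(seq(0, 1, length.out = 59),
                                              rate = 2.2))
    sex <- sample(c("male", "female"), 1)
    county <- sample(counties, 1)
    specialty <- sample(specialties, 1)
    other_ind <- stats::runif(1) < config$other_indication_fraction
    atc <- sample(names(atc_probs), 1, prob = atc_probs)
    arts <- catalog[catalog$atc == atc, , drop = FALSE]
    art <- arts[sample.int(nrow(arts), 1), ]
    # dosage trajectory starts from the configured class distribution
    cls_idx <- sample(seq_along(codec$labels), 1, prob = config$class_probs)
    hazard <- config$discontinuation_hazard[[as.character(.age_band(age))]]

    date0 <- config$date_start +
      sample.int(as.integer(config$date_end - config$date_start) + 1, 1) - 1
    date <- date0
    run_end <- NULL
    per_start <- NULL
    n_in_period <- 0L
    prs <- list(); pgs <- list(); psegs <- list()
    prets <- list(); pgrets <- list()

    j <- 0L
    repeat {
      j <- j + 1L
      rec_counter <- rec_counter + 1L
      record_id <- sprintf("R%07d", rec_counter)
      v <- codec$pills[cls_idx]
      n_packages <- sample(1:2, 1, prob = c(0.85, 0.15))
      pills_total <- n_packages * art$package_size

      u <- stats::runif(1)
      kind <- if (other_ind) "regular"
        else if (u < config$fraction_noninformative) "noninformative"
        else if (u < config$fraction_noninformative +
                   config$fraction_titrated) "titrated"
        else if (u < config$fraction_noninformative +
                   config$fraction_titrated + config$fraction_range) "range"
        else if (u < config$fraction_noninformative +
                   config$fraction_titrated + config$fraction_range +
                   config$fraction_addon) "addon"
        else "regular"
      sig <- generate_sig(codec$labels[cls_idx], kind)
      text <- sig$text
      if (other_ind)
        text <- paste(text, sample(c("mot narkolepsi",
                                     "mot multipel skleros"), 1))
      # segments with truth doses; non-informative keeps the true dose
      true_segs <- sig$segments
      if (!sig$informative) true_segs$pills_per_day <- v

      prs[[j]] <- data.frame(
        record_id = record_id, person_id = person_id, age = age, sex = sex,
        atc = atc, article_number = art$article_number,
        dispensation_date = date, n_packages = n_packages,
        package_size = art$package_size, strength_mg = art$strength_mg,
        specialty = specialty, county = county, free_text = text,
        returned = FALSE, stringsAsFactors = FALSE)
      pgs[[j]] <- data.frame(
        record_id = record_id, person_id = person_id,
        informative = sig$informative,
        dosage_class = if (sig$informative) sig$dosage_class else NA_character_,
        true_pills_per_day = v, titrated = nrow(true_segs) > 1,
        other_indication = other_ind, stringsAsFactors = FALSE)
      if (nrow(true_segs) > 1) {
        s <- true_segs
        s$record_id <- record_id
        psegs[[length(psegs) + 1L]] <- s[, c("record_id", "segment_index",
                                             "pills_per_day",
                                             "duration_days")]
      }
      # occasional returned duplicate (extra record, not consumed)
      if (stats::runif(1) < config$returned_fraction) {
        rec_counter <- rec_counter + 1L
        ret <- prs[[j]]
        ret$record_id <- sprintf("R%07d", rec_counter)
        ret$returned <- TRUE
        prets[[length(prets) + 1L]] <- ret
        gret <- pgs[[j]]
        gret$record_id <- ret$record_id
        pgrets[[length(pgrets) + 1L]] <- gret
        if (nrow(true_segs) > 1) {
          s <- true_segs
          s$record_id <- ret$record_id
          psegs[[length(psegs) + 1L]] <- s[, c("record_id", "segment_index",
                                               "pills_per_day",
                                               "duration_days")]
        }
      }

      supply <- .gen_supply_days(pills_total, true_segs,
                                 config$adherence_coefficient)
      if (!other_ind) {
        if (is.null(run_end) || date > run_end) {
          if (!is.null(run_end))
            tl_rows[[length(tl_rows) + 1L]] <- data.frame(
              person_id = person_id, atc = atc, start = per_start,
              end = run_end, n_dispensations = n_in_period,
              stringsAsFactors = FALSE)
          per_start <- date
          run_end <- date
          n_in_period <- 0L
        }
        run_end <- run_end + supply
        n_in_period <- n_in_period + 1L
      }

      # stop, pause or refill
      if (other_ind || j >= config$max_dispensations ||
          stats::runif(1) < hazard) break
      gapf <- if (config$exact_refills) 1 else {
        if (stats::runif(1) < config$pause_prob)
          stats::runif(1, 1.3, 2.5)
        else min(1, max(0.4, stats::rnorm(1, config$refill_gap_mean,
                                          config$refill_gap_sd)))
      }
      date <- date + max(1L, as.integer(round(supply * gapf)))
      if (date > config$date_end + 180) break
      if (stats::runif(1) < config$dose_change_prob) {
        step <- sample(c(-1L, 1L), 1, prob = c(0.3, 0.7))
        cls_idx <- min(max(cls_idx + step, 1L), length(codec$labels))
      }
    }
    if (!other_ind && !is.null(run_end))
      tl_rows[[length(tl_rows) + 1L]] <- data.frame(
        person_id = person_id, atc = atc, start = per_start, end = run_end,
        n_dispensations = n_in_period, stringsAsFactors = FALSE)
    rec_rows[[p]] <- do.call(rbind, c(prs, prets))
    gold_rows[[p]] <- do.call(rbind, c(pgs, pgrets))
    if (length(psegs)) seg_rows[[p]] <- do.call(rbind, psegs)
  }

  records <- do.call(rbind, rec_rows)
  gold <- do.call(rbind, gold_rows)
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(record_id = character(0), segment_index = integer(0),
               pills_per_day = numeric(0), duration_days = numeric(0))
  timelines <- if (length(tl_rows)) do.call(rbind, tl_rows) else
    data.frame(person_id = character(0), atc = character(0),
               start = as.Date(character(0)), end = as.Date(character(0)),
               n_dispensations = integer(0))
  rownames(records) <- rownames(gold) <- rownames(segments) <-
    rownames(timelines) <- NULL
  structure(list(records = records, gold = gold, segments = segments,
                 timelines = timelines, config = config),
            class = "synthetic_register")
}

#' Export a synthetic register as CSV fixtures
#'
#' Writes `records.csv`, `gold.csv` and `truth_timelines.csv` (plus
#' `segments.csv` when titrated records exist) to a directory.
#' Re-exporting the same register is byte-identical.
#'
#' @param register A [generate_register()] object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_fixture <- function(register, dir) {
  stopifnot(inherits(register, "synthetic_register"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df <- as.data.frame(lapply(df, function(col) {
      if (inherits(col, "Date")) format(col, "%Y-%m-%d") else col
    }), stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  }
  wr(register$records, "records.csv")
  wr(register$gold, "gold.csv")
  wr(register$timelines, "truth_timelines.csv")
  if (nrow(register$segments)) wr(register$segments, "segments.csv")
  invisible(dir)
}
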