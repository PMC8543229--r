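#' Split records into classification entries
#'
#' Applies titration splitting to every record's free text: regular
#' texts yield one entry, titrated texts one entry per titration
#' interval, each with its stated duration when the segment states one.
#'
#' @param records Prescription records with `record_id` and `free_text`.
#' @param keywords Titration keywords.
#' @return A data.frame: `record_id`, `segment_index`, `segment_text`,
#'   `stated_duration_days`, `needs_review`.
#' @export
split_sig_entries <- function(records, keywords = titration_keywords()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- split_titration(records$free_text[i], keywords)
    data.frame(record_id = records$record_id[i],
               segment_index = s$segment_index,
               segment_text = s$segment_text,
               stated_duration_days = s$stated_duration_days,
               needs_review = isTRUE(attr(s, "needs_review")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attach gold labels to classification entries
#'
#' Record-level gold informativeness propagates to every entry of the
#' record; titrated records additionally get per-segment gold dosage
#' classes from the generator's segment truth.
#'
#' @param entries [split_sig_entries()] output.
#' @param gold Per-record gold table (`record_id`, `informative`,
#'   `dosage_class`).
#' @param segments Per-segment truth (`record_id`, `segment_index`,
#'   `pills_per_day`), possibly empty.
#' @return `entries` with `informative` and `dosage_class` columns.
#' @export
entry_gold_labels <- function(entries, gold, segments = NULL) {
  g <- gold[match(entries$record_id, gold$record_id), ]
  entries$informative <- g$informative
  cls <- g$dosage_class
  if (!is.null(segments) && nrow(segments)) {
    m <- match(paste(entries$record_id, entries$segment_index),
               paste(segments$record_id, segments$segment_index))
    hit <- !is.na(m) & !is.na(segments$pills_per_day[m])
    cls[hit] <- pills_to_class(segments$pills_per_day[m[hit]])
  }
  entries$dosage_class <- ifelse(entries$informative, cls, NA_character_)
  entries
}

# Aggregate entry-level cascade output to record level: a record is
# resolved by the text models iff all of its entries are; its
# record-level dosage is the final (maintenance) segment's.
.aggregate_record_predictions <- function(records, entries, entry_preds) {
  n <- nrow(records)
  preds <- data.frame(record_id = records$record_id,
                      pills_per_day = NA_real_,
                      final_class = NA_character_,
                      source = "unresolved",
                      stringsAsFactors = FALSE)
  grp <- split(seq_len(nrow(entries)), entries$record_id)
  for (rid in names(grp)) {
    idx <- grp[[rid]]
    row <- match(rid, preds$record_id)
    if (is.na(row)) next
    if (all(entry_preds$source[idx] == "nlp2")) {
      last <- idx[which.max(entries$segment_index[idx])]
      preds$pills_per_day[row] <- entry_preds$pills_per_day[last]
      preds$final_class[row] <- entry_preds$final_class[last]
      preds$source[row] <- "nlp2"
    }
  }
  preds
}

# Titration dose profiles for resolved multi-segment records:
# per-segment predicted doses + stated durations walked against the
# dispensed pills.  Returns a named list keyed by record_id.
.build_titration_profiles <- function(records, entries, entry_preds,
                                      record_preds) {
  profiles <- list()
  multi <- unique(entries$record_id[entries$segment_index > 0])
  for (rid in multi) {
    row <- match(rid, records$record_id)
    if (is.na(row)) next
    if (record_preds$source[match(rid, record_preds$record_id)] != "nlp2")
      next                               # imputed records are flat-dosed
    idx <- which(entries$record_id == rid)
    idx <- idx[order(entries$segment_index[idx])]
    tl <- titrated_length(entry_preds$pills_per_day[idx],
                          entries$stated_duration_days[idx],
                          records$n_packages[row] * records$package_size[row])
    profiles[[rid]] <- tl$profile
  }
  profiles
}

#' Run the full synthetic study end-to-end
#'
#' Generates a synthetic register, applies the record filters and
#' titration splitting, trains the two text models on a training corpus
#' of entries (persons disjoint from validation), applies the
#' 0.5-threshold cascade register-wide, trains the fallback forest on
#' the confidently text-resolved records, resolves the remainder by
#' carry-forward then forest, builds continuous treatment periods, and
#' computes validation metrics and usage patterns.
#'
#' @param seed Master seed (drives generator and model seeds).
#' @param synth Generator configuration (default [synth_config()] with
#'   this seed).
#' @param n_train_entries Size of the training corpus in titration-split
#'   entries (default 8000).
#' @param n_validation_records Held-out validation prescriptions from
#'   persons disjoint with training (default 1000).
#' @param hyper Text-model hyperparameters.
#' @param threshold Cascade decision threshold (default 0.5).
#' @param adherence Adherence coefficient (default 7/5).
#' @param clamp Supply clamp bounds in days (default `c(1, 90)`).
#' @param carry_window Carry-forward look-back (default 365 days).
#' @param forest_trees Fallback forest size (default 100).
#' @param year Calendar year for usage-pattern analyses.
#' @param patterns Compute usage-pattern analyses (default TRUE).
#' @return A list with components `register`, `records` (filtered),
#'   `entries`, `models`, `record_preds` (resolved), `supplies`,
#'   `periods`, `validation` (metrics), `patterns` and `audit`.
#' @export
run_synthetic_study <- function(seed = 1L,
                                synth = synth_config(seed = seed),
                                n_train_entries = 8000L,
                                n_validation_records = 1000L,
                                hyper = nlp_hyper(),
                                threshold = 0.5,
                                adherence = 7 / 5,
                                clamp = c(1, 90),
                                carry_window = 365,
                                forest_trees = 100L,
                                year = 2013,
                                patterns = TRUE) {
  register <- generate_register(synth)
  n_input <- nrow(register$records)
  kept1 <- filter_returned(register$records)
  fi <- filter_indication(kept1)
  records <- fi$kept
  entries <- split_sig_entries(records)
  entries <- entry_gold_labels(entries, register$gold, register$segments)

  # person-disjoint train / validation split
  persons <- unique(records$person_id)
  entries_per_person <- table(records$person_id[match(entries$record_id,
                                                      records$record_id)])
  cum <- cumsum(as.integer(entries_per_person[persons]))
  n_train_persons <- which(cum >= n_train_entries)[1]
  if (is.na(n_train_persons)) n_train_persons <- length(persons) - 1L
  train_persons <- persons[seq_len(n_train_persons)]
  rest <- persons[-seq_len(n_train_persons)]
  rec_person <- records$person_id[match(entries$record_id,
                                        records$record_id)]
  train_idx <- which(rec_person %in% train_persons)
  val_records <- records[records$person_id %in% rest, , drop = FALSE]
  if (nrow(val_records) > n_validation_records)
    val_records <- val_records[seq_len(n_validation_records), , drop = FALSE]

  train_entries <- entries[train_idx, , drop = FALSE]
  vocab <- build_vocabulary(normalize_text(train_entries$segment_text))
  nlp1 <- train_nlp1(train_entries$segment_text, train_entries$informative,
                     vocab, hyper, seed)
  inf <- train_entries[train_entries$informative &
                         !is.na(train_entries$dosage_class), , drop = FALSE]
  nlp2 <- train_nlp2(inf$segment_text, inf$dosage_class, vocab, hyper,
                     seed + 1L)

  entry_preds <- classify_entries(entries$segment_text, nlp1, nlp2,
                                  threshold)
  record_preds <- .aggregate_record_predictions(records, entries,
                                                entry_preds)
  confident <- which(record_preds$source == "nlp2" &
                       !records$person_id %in% val_records$person_id)
  forest <- train_forest(make_features(records[confident, , drop = FALSE],
                                       records),
                         record_preds$final_class[confident],
                         seed = seed + 2L, ntree = forest_trees)
  resolved <- resolve_dispensations(records, record_preds, forest,
                                    carry_window)
  profiles <- .build_titration_profiles(records, entries, entry_preds,
                                        record_preds)
  rec_res <- records
  rec_res$pills_per_day <- resolved$pills_per_day
  supplies <- build_supplies(rec_res, profiles, adherence,
                             clamp[1], clamp[2])
  periods <- join_periods(supplies)

  validation <- .validation_metrics(val_records, entries, entry_preds,
                                    record_preds, resolved, register,
                                    threshold)
  pat <- NULL
  if (patterns && nrow(periods)) {
    cohort <- find_incident_users(records, periods, year)
    pat <- list(
      cohort = cohort,
      km = if (nrow(cohort)) km_estimate(cohort) else NULL,
      km_sensitivity = {
        sens <- single_prescription_sensitivity(cohort)
        if (nrow(sens)) km_estimate(sens) else NULL
      },
      dose = dose_categories_by_group(records, periods, "N06BA04", year))
  }
  audit <- list(
    n_input = n_input,
    n_returned_removed = n_input - nrow(kept1),
    n_indication_excluded = nrow(fi$excluded),
    n_records = nrow(records),
    n_entries = nrow(entries),
    n_train_entries = length(train_idx),
    n_validation_records = nrow(val_records),
    source_breakdown = table(resolved$source))
  list(register = register, records = records, entries = entries,
       train_persons = train_persons,
       val_record_ids = val_records$record_id,
       models = list(nlp1 = nlp1, nlp2 = nlp2, forest = forest,
                     vocab = vocab),
       record_preds = resolved, supplies = supplies, periods = periods,
       validation = validation, patterns = pat, audit = audit)
}

# Validation metrics on the held-out records.
.validation_metrics <- function(val_records, entries, entry_preds,
                                record_preds, resolved, register,
                                threshold) {
  vids <- val_records$record_id
  eidx <- which(entries$record_id %in% vids)
  if (length(eidx) == 0) return(NULL)
  e <- entries[eidx, , drop = FALSE]
  p <- entry_preds[eidx, , drop = FALSE]
  probs <- attr(entry_preds, "class_probs")[eidx, , drop = FALSE]

  # stage 1: non-informativeness prediction
  pred_noninf <- p$p_noninformative > threshold
  gold_noninf <- !e$informative
  nlp1_correct <- sum(pred_noninf == gold_noninf)
  nlp1 <- list(
    accuracy = proportion_ci(nlp1_correct, length(eidx), "wald"),
    accuracy_wilson = proportion_ci(nlp1_correct, length(eidx), "wilson"),
    gmeans = weighted_gmeans(confusion_matrix(
      ifelse(gold_noninf, "noninf", "inf"),
      ifelse(pred_noninf, "noninf", "inf"))))

  # stage 2: dosage class among entries with a gold dosage that stage 1
  # passed on
  sel <- which(!gold_noninf & !pred_noninf & !is.na(e$dosage_class))
  nlp2 <- NULL
  if (length(sel)) {
    argmax <- colnames(probs)[max.col(probs[sel, , drop = FALSE],
                                      ties.method = "first")]
    cm <- confusion_matrix(e$dosage_class[sel], argmax,
                           labels = dosage_codec()$labels)
    nlp2 <- list(
      accuracy = proportion_ci(sum(argmax == e$dosage_class[sel]),
                               length(sel), "wald"),
      accuracy_wilson = proportion_ci(sum(argmax == e$dosage_class[sel]),
                                      length(sel), "wilson"),
      gmeans = weighted_gmeans(cm),
      confusion = cm)
  }

  # overall accuracy of the two text models (record level)
  ridx <- match(vids, record_preds$record_id)
  gold <- register$gold[match(vids, register$gold$record_id), ]
  text_pills <- ifelse(record_preds$source[ridx] == "nlp2",
                       record_preds$pills_per_day[ridx], NA_real_)
  gold_pills <- ifelse(gold$informative,
                       class_to_pills(gold$dosage_class), NA_real_)
  overall <- overall_accuracy(text_pills, gold$informative, gold_pills)

  # full cascade against the generator's true dosage
  final_pills <- resolved$pills_per_day[ridx]
  truth <- gold$true_pills_per_day
  cascade <- proportion_ci(
    sum(abs(final_pills - truth) < 1e-9, na.rm = TRUE),
    length(vids), "wald")
  bins <- error_size_bins(final_pills, truth)

  list(n_entries = length(eidx), n_records = length(vids),
       nlp1 = nlp1, nlp2 = nlp2, overall = overall, cascade = cascade,
       error_bins = bins)
}

#' Pipeline configuration
#'
#' All tunable constants of the end-to-end pipeline with their default
#' values: cascade threshold 0.5, adherence coefficient 7/5, supply
#' clamp 1-90 days, carry-forward window 365 days, 100 forest trees.
#'
#' @param seed Master seed.
#' @param ... Overrides for any [run_synthetic_study()] argument.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = seed, n_train_entries = 8000L,
              n_validation_records = 1000L, threshold = 0.5,
              adherence = 7 / 5, clamp = c(1, 90), carry_window = 365,
              forest_trees = 100L, year = 2013)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline and write its artifacts
#'
#' Executes [run_synthetic_study()] under a configuration and writes
#' per-stage artifacts to a run directory: the register fixture,
#' resolved predictions, the period table, validation metrics and usage
#' patterns (JSON), plus a manifest recording versions, seeds and stage
#' counts.  Re-running with the same configuration reproduces the
#' outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @return The study result list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_synthetic_study(
    seed = config$seed,
    synth = if (!is.null(config$synth)) config$synth else
      synth_config(seed = config$seed),
    n_train_entries = config$n_train_entries,
    n_validation_records = config$n_validation_records,
    hyper = if (!is.null(config$hyper)) config$hyper else nlp_hyper(),
    threshold = config$threshold, adherence = config$adherence,
    clamp = config$clamp, carry_window = config$carry_window,
    forest_trees = config$forest_trees, year = config$year)
  export_fixture(res$register, file.path(out_dir, "register"))
  preds <- res$record_preds
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  write_periods(res$periods, file.path(out_dir, "periods.csv"))
  v <- res$validation
  rep_ci <- function(x) if (is.null(x)) NULL else
    list(n = x$n, estimate = x$estimate, lower = x$lower, upper = x$upper,
         method = x$method)
  jsonlite::write_json(list(
    nlp1_accuracy = rep_ci(v$nlp1$accuracy),
    nlp1_gmeans = v$nlp1$gmeans,
    nlp2_accuracy = rep_ci(v$nlp2$accuracy),
    nlp2_gmeans = v$nlp2$gmeans,
    overall_informative = rep_ci(v$overall$informative),
    overall_all = rep_ci(v$overall$all),
    cascade_accuracy = rep_ci(v$cascade)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$patterns)) {
    utils::write.csv(res$patterns$cohort,
                     file.path(out_dir, "incident_cohort.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(res$patterns$km, file.path(out_dir, "km_curves.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(res$patterns$dose,
                     file.path(out_dir, "dose_categories.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sigdose")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "synth")],
    audit = c(res$audit[setdiff(names(res$audit), "source_breakdown")],
              list(source_breakdown = as.list(res$audit$source_breakdown))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Summarise a completed run's flow accounting
#'
#' Per-stage record counts and the share of dispensations resolved by
#' each source; the source breakdown always sums to the number of
#' analysed records (conservation).
#'
#' @param result A [run_synthetic_study()] result.
#' @return A list with stage counts and resolution percentages.
#' @export
audit_report <- function(result) {
  a <- result$audit
  src <- as.list(a$source_breakdown)
  total <- sum(unlist(src))
  if (total != a$n_records)
    stop("incomplete run: resolved records do not match analysed records")
  list(stages = a[c("n_input", "n_returned_removed",
                    "n_indication_excluded", "n_records", "n_entries",
                    "n_train_entries", "n_validation_records")],
       resolution_counts = src,
       resolution_pct = lapply(src, function(x) 100 * x / total))
}
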