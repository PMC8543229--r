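# Shared fixture builders.  All fixtures are constructed in code; the
# suite ships no data files.

make_record <- function(record_id = "R1", person_id = "P1", age = 25L,
                        sex = "male", atc = "N06BA04",
                        article_number = "A10018",
                        dispensation_date = as.Date("2013-03-01"),
                        n_packages = 1L, package_size = 30L,
                        strength_mg = 18, specialty = "S1", county = "C01",
                        free_text = "1 tablett dagligen",
                        returned = FALSE) {
  data.frame(record_id = record_id, person_id = person_id, age = age,
             sex = sex, atc = atc, article_number = article_number,
             dispensation_date = dispensation_date,
             n_packages = n_packages, package_size = package_size,
             strength_mg = strength_mg, specialty = specialty,
             county = county, free_text = free_text, returned = returned,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  do.call(rbind, list(...))
}

# Minimal period-strata row for analyses tests.
make_stratum <- function(person_id = "P1", atc = "N06BA04", period_id = 1L,
                         period_start, period_end,
                         stratum_start = period_start,
                         stratum_end = period_end,
                         pills_per_day = 1, dose_mg_per_day = 18,
                         n_dispensations = 1L) {
  data.frame(person_id = person_id, atc = atc, period_id = period_id,
             period_start = as.Date(period_start),
             period_end = as.Date(period_end),
             stratum_start = as.Date(stratum_start),
             stratum_end = as.Date(stratum_end),
             pills_per_day = pills_per_day,
             dose_mg_per_day = dose_mg_per_day,
             n_dispensations = n_dispensations, stringsAsFactors = FALSE)
}

# A small trained model pair on a compact corpus, cached for the tests
# that need real classifiers (training takes a few seconds).
tiny_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(n_persons = 220, seed = 42,
                        fraction_noninformative = 0.15)
    reg <- generate_register(cfg)
    recs <- filter_indication(filter_returned(reg$records))$kept
    entries <- split_sig_entries(recs)
    entries <- entry_gold_labels(entries, reg$gold, reg$segments)
    vocab <- build_vocabulary(normalize_text(entries$segment_text))
    hyper <- nlp_hyper(epochs = 6)
    nlp1 <- train_nlp1(entries$segment_text, entries$informative, vocab,
                       hyper, seed = 1)
    inf <- entries[entries$informative & !is.na(entries$dosage_class), ]
    nlp2 <- train_nlp2(inf$segment_text, inf$dosage_class, vocab, hyper,
                       seed = 2)
    cache <<- list(register = reg, records = recs, entries = entries,
                   vocab = vocab, hyper = hyper, nlp1 = nlp1, nlp2 = nlp2)
    cache
  }
})
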