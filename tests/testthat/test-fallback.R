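hist_df <- function(atc, dates, pills) {
  data.frame(atc = atc, dispensation_date = as.Date(dates),
             pills_per_day = pills, stringsAsFactors = FALSE)
}

test_that("carry-forward takes the most recent same-drug dosage within a year", {
  idx <- as.Date("2013-06-01")
  expect_equal(carry_forward("N06BA04", idx,
                             hist_df("N06BA04", idx - 100, 2)), 2)
  expect_true(is.na(carry_forward("N06BA04", idx,
                                  hist_df("N06BA04", idx - 400, 2))))
  expect_true(is.na(carry_forward("N06BA04", idx,
                                  hist_df("N06BA09", idx - 100, 2))))
  # most recent of several wins
  h <- hist_df("N06BA04", idx - c(300, 30, 150), c(1, 3, 2))
  expect_equal(carry_forward("N06BA04", idx, h), 3)
  # causality: dosages on/after the index date are invisible
  h2 <- hist_df("N06BA04", c(idx, idx + 10), c(5, 6))
  expect_true(is.na(carry_forward("N06BA04", idx, h2)))
  expect_true(is.na(carry_forward("N06BA04", idx, h2[0, ])))
})

test_that("sequence number counts same-drug dispensations in the prior 183 days", {
  base <- as.Date("2013-06-01")
  recs <- make_records(
    make_record(record_id = "R1", dispensation_date = base - 200),
    make_record(record_id = "R2", dispensation_date = base - 120),
    make_record(record_id = "R3", dispensation_date = base - 60),
    make_record(record_id = "R4", dispensation_date = base - 30,
                atc = "N06BA09"),
    make_record(record_id = "R5", dispensation_date = base))
  f <- make_features(recs[5, ], recs)
  expect_equal(f$sequence_number, 3)  # R2 and R3 count; R1 too old, R4 other drug
  expect_equal(make_features(recs[1, ], recs)$sequence_number, 1)
  expect_equal(ncol(f), 6)
})

test_that("forest prediction equals a brute-force per-tree vote tally", {
  m <- tiny_models()
  g <- m$register$gold
  recs <- m$records
  lab <- g$dosage_class[match(recs$record_id, g$record_id)]
  keep <- !is.na(lab)
  feats <- make_features(recs[keep, ], recs)
  fit <- train_forest(feats, lab[keep], seed = 9)
  new <- feats[seq_len(25), ]
  out <- predict_forest(fit, new)
  # independent tally from the per-tree predictions
  x <- sigdose:::.apply_feature_levels(new, fit$levels)
  per_tree <- predict(fit$fit, x, predict.all = TRUE)$individual
  codec <- dosage_codec()
  manual <- apply(per_tree, 1, function(v) {
    tab <- table(v)
    winners <- names(tab)[tab == max(tab)]
    winners[which.min(match(winners, codec$labels))]  # lower class on ties
  })
  expect_equal(out$class, unname(manual))
  expect_equal(out$pills_per_day, class_to_pills(unname(manual)))
  # determinism
  fit2 <- train_forest(feats, lab[keep], seed = 9)
  expect_equal(predict_forest(fit2, new)$votes, out$votes)
  expect_error(train_forest(feats[0, ], character(0)), "no training")
})

test_that("unseen categories at predict time map to the unknown level", {
  m <- tiny_models()
  g <- m$register$gold
  recs <- m$records
  lab <- g$dosage_class[match(recs$record_id, g$record_id)]
  keep <- !is.na(lab)
  fit <- train_forest(make_features(recs[keep, ], recs), lab[keep], seed = 3)
  odd <- make_features(make_record(county = "C99",
                                   article_number = "UNSEEN"))
  expect_no_error(out <- predict_forest(fit, odd))
  expect_true(out$class %in% dosage_codec()$labels)
})

test_that("the cascade resolves every record, carry-forward before forest", {
  m <- tiny_models()
  recs <- make_records(
    make_record(record_id = "R1", person_id = "PA",
                dispensation_date = as.Date("2013-01-01")),
    make_record(record_id = "R2", person_id = "PA",
                dispensation_date = as.Date("2013-02-15")),
    make_record(record_id = "R3", person_id = "PB",
                dispensation_date = as.Date("2013-03-01")))
  preds <- data.frame(
    record_id = c("R1", "R2", "R3"),
    pills_per_day = c(2, NA, NA),
    final_class = c("2", NA, NA),
    source = c("nlp2", "unresolved", "unresolved"),
    stringsAsFactors = FALSE)
  g <- m$register$gold
  lab <- g$dosage_class[match(m$records$record_id, g$record_id)]
  keep <- !is.na(lab)
  forest <- train_forest(make_features(m$records[keep, ], m$records),
                         lab[keep], seed = 5)
  out <- resolve_dispensations(recs, preds, forest)
  expect_false(anyNA(out$pills_per_day))            # totality
  expect_equal(out$source, c("nlp2", "carry_forward", "forest"))
  expect_equal(out$pills_per_day[2], 2)             # carried from R1
  # empty input passes through
  expect_equal(nrow(resolve_dispensations(recs[0, ], preds[0, ], forest)), 0)
})

test_that("earlier fallback resolutions feed later carry-forwards", {
  m <- tiny_models()
  g <- m$register$gold
  lab <- g$dosage_class[match(m$records$record_id, g$record_id)]
  keep <- !is.na(lab)
  forest <- train_forest(make_features(m$records[keep, ], m$records),
                         lab[keep], seed = 5)
  recs <- make_records(
    make_record(record_id = "R1", person_id = "PC",
                dispensation_date = as.Date("2013-01-01")),
    make_record(record_id = "R2", person_id = "PC",
                dispensation_date = as.Date("2013-02-01")))
  preds <- data.frame(record_id = c("R1", "R2"),
                      pills_per_day = c(NA, NA),
                      final_class = c(NA, NA),
                      source = c("unresolved", "unresolved"),
                      stringsAsFactors = FALSE)
  out <- resolve_dispensations(recs, preds, forest)
  expect_equal(out$source, c("forest", "carry_forward"))
  expect_equal(out$pills_per_day[2], out$pills_per_day[1])
})
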