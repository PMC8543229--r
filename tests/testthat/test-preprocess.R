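test_that("returned dispensations are removed, order preserved", {
  recs <- make_records(
    make_record(record_id = "R1", returned = FALSE),
    make_record(record_id = "R2", returned = TRUE),
    make_record(record_id = "R3", returned = FALSE))
  out <- filter_returned(recs)
  expect_equal(out$record_id, c("R1", "R3"))
  expect_equal(filter_returned(out), out)                 # idempotent
  all_ret <- make_record(returned = TRUE)
  expect_equal(nrow(filter_returned(all_ret)), 0)
})

test_that("indication filter partitions by substring keywords", {
  recs <- make_records(
    make_record(record_id = "R1",
                free_text = "mot narkolepsi 1 tablett dagligen"),
    make_record(record_id = "R2", free_text = "1 tablett dagligen"),
    make_record(record_id = "R3",
                free_text = "1 Tablett mot Multipel Skleros"))
  out <- filter_indication(recs, c("narkolepsi", "multipel skleros"))
  expect_equal(out$kept$record_id, "R2")
  expect_equal(out$excluded$record_id, c("R1", "R3"))
  # audit conservation and empty keyword set
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(recs))
  none <- filter_indication(recs, character(0))
  expect_equal(nrow(none$kept), 3)
})

test_that("record filters commute and are idempotent", {
  cfg <- synth_config(n_persons = 40, seed = 11, returned_fraction = 0.1,
                      other_indication_fraction = 0.1)
  recs <- generate_register(cfg)$records
  a <- filter_indication(filter_returned(recs))$kept
  b <- filter_returned(filter_indication(recs)$kept)
  expect_equal(a, b)
  expect_equal(filter_indication(filter_returned(a))$kept, a)
})

test_that("titration is detected on word boundaries", {
  expect_true(detect_titration(
    "1 tablett dagligen i 1 vecka, därefter 2 tabletter dagligen"))
  expect_false(detect_titration("2 tabletter på morgonen"))
  expect_false(detect_titration(""))
  # "sen" must not fire inside words like "dosen"
  expect_false(detect_titration("öka dosen vid behov"))
  expect_true(detect_titration("1 tablett, sen 2 tabletter"))
})

test_that("titrated texts split into ordered segments with durations", {
  s <- split_titration(
    "1 tablett dagligen i 1 vecka, därefter 2 tabletter dagligen")
  expect_equal(nrow(s), 2)
  expect_equal(s$segment_index, 0:1)
  expect_equal(s$stated_duration_days, c(7, NA))
  s3 <- split_titration(
    "1 tablett i 3 dagar, sedan 2 tabletter i 4 dagar, sedan 3 tabletter")
  expect_equal(nrow(s3), 3)
  expect_equal(s3$stated_duration_days, c(3, 4, NA))
  plain <- split_titration("2 tabletter morgon och kväll")
  expect_equal(nrow(plain), 1)
  expect_equal(plain$segment_index, 0L)
  # detected but unsplittable -> single flagged segment, not dropped
  odd <- split_titration("dosen ökas enligt schema")
  expect_equal(nrow(odd), 1)
  expect_true(isTRUE(attr(odd, "needs_review")))
})

test_that("duration phrases convert days, weeks and months", {
  expect_equal(split_titration("1 tablett dagligen i 10 dagar, därefter 2 tabletter")$stated_duration_days[1], 10)
  expect_equal(split_titration("1 tablett dagligen i 2 veckor, därefter 2 tabletter")$stated_duration_days[1], 14)
  expect_equal(split_titration("1 tablett dagligen i 1 månad, därefter 2 tabletter")$stated_duration_days[1], 30)
  expect_equal(split_titration("1 tablett första veckan, därefter 2 tabletter")$stated_duration_days[1], 7)
})

test_that("normalization lowercases, stems, keeps dose tokens", {
  expect_equal(normalize_text("Tabletten tas på morgonen.")[[1]],
               c("tablett", "tas", "morgon"))
  expect_equal(normalize_text("1 tablett 2 gånger dagligen")[[1]],
               c("1", "tablett", "2", "gång", "dag"))
  expect_equal(normalize_text("")[[1]], character(0))
  # dose-bearing characters survive as single tokens
  expect_equal(normalize_text("0,5 tablett dagligen")[[1]],
               c("0.5", "tablett", "dag"))
  expect_equal(normalize_text("½ tablett dagligen")[[1]],
               c("0.5", "tablett", "dag"))
  expect_equal(normalize_text("en halv tablett")[[1]],
               c("en", "0.5", "tablett"))
  expect_equal(normalize_text("1-2 tabletter vid behov")[[1]],
               c("1-2", "tablett", "behov"))
})

test_that("normalization is idempotent on generated sigs", {
  cfg <- synth_config(n_persons = 60, seed = 5)
  reg <- generate_register(cfg)
  toks <- normalize_text(reg$records$free_text)
  rejoined <- vapply(toks, paste, character(1), collapse = " ")
  again <- normalize_text(rejoined)
  expect_equal(again, toks)
})

test_that("vocabulary is frequency-ordered, deterministic, with reserved ids", {
  corp <- list(c("a", "b"), c("a"), c("c", "b", "a"))
  v <- build_vocabulary(corp)
  expect_equal(v$pad_id, 0L)
  expect_equal(v$oov_id, 1L)
  expect_equal(unname(v$index["a"]), 2L)      # most frequent first
  expect_equal(unname(v$index["b"]), 3L)
  expect_equal(v$size, 5L)
  expect_identical(build_vocabulary(corp), v) # rebuild identical
  # ties broken lexicographically
  v2 <- build_vocabulary(list(c("zz", "aa")))
  expect_lt(v2$index["aa"], v2$index["zz"])
  expect_error(build_vocabulary(list()), "empty")
})

test_that("encoding pads with zeros, maps OOV, truncates with warning", {
  v <- build_vocabulary(list(c("a", "b", "c")))
  expect_equal(encode_and_pad(c("a", "b"), v, 5),
               c(v$index[["a"]], v$index[["b"]], 0L, 0L, 0L))
  expect_equal(encode_and_pad("zzz", v, 3), c(1L, 0L, 0L))
  expect_warning(out <- encode_and_pad(rep("a", 7), v, 5), "truncated")
  expect_length(out, 5)
  expect_equal(encode_and_pad(character(0), v, 4), rep(0L, 4))
  m <- encode_corpus(list(c("a"), c("b", "c")), v, 4)
  expect_equal(dim(m), c(2, 4))
})
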