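#' Default keyword lists for preprocessing
#'
#' The exact keyword inventories used on real register extracts are
#' deployment configuration; these defaults cover the constructs the
#' synthetic register produces and are the documented starting point for
#' adaptation.
#'
#' @return A character vector of lowercase keywords.
#' @name sig_keywords
NULL

#' @describeIn sig_keywords Free-text markers of non-ADHD indications
#'   (e.g. narcolepsy, multiple sclerosis); matched case-folded as
#'   substrings.
#' @export
indication_keywords <- function() {
  c("narkolepsi", "multipel skleros", "ms")
}

#' @describeIn sig_keywords Markers of titration (stepwise dose change
#'   within one prescription).
#' @export
titration_keywords <- function() {
  c("därefter", "sedan", "sen", "upptrappning", "ökas",
    "vecka 1", "första veckan")
}

#' @describeIn sig_keywords Swedish stop words filtered out before
#'   tokenization.  Deliberately excludes dose-bearing function words
#'   ("en", "ett", "halv", "till"), which carry quantity information.
#' @export
swedish_stopwords <- function() {
  c("på", "och", "i", "att", "av", "den", "det", "de", "med",
    "för", "om", "är", "som", "var", "samt", "eller", "vid",
    "ska", "skall", "kan", "så")
}

#' Remove dispensations returned to the pharmacy
#'
#' @param records Prescription records (data.frame with a `returned`
#'   logical column).
#' @return The records with `returned == TRUE` rows removed, order
#'   preserved.
#' @export
filter_returned <- function(records) {
  out <- records[!records$returned, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition records by non-target indication keywords
#'
#' A record is excluded iff its case-folded free text contains any
#' keyword as a substring.  Both partitions are returned so excluded
#' records can be audited.
#'
#' @param records Prescription records.
#' @param keywords Lowercase keyword vector (default
#'   [indication_keywords()]).
#' @return A list with elements `kept` and `excluded`.
#' @export
filter_indication <- function(records, keywords = indication_keywords()) {
  if (length(keywords) == 0 || nrow(records) == 0) {
    return(list(kept = records,
                excluded = records[integer(0), , drop = FALSE]))
  }
  txt <- tolower(records$free_text)
  hit <- Reduce(`|`, lapply(keywords, function(k) grepl(k, txt, fixed = TRUE)))
  kept <- records[!hit, , drop = FALSE]
  excluded <- records[hit, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

# Regex that matches any titration keyword on word boundaries.
titration_pattern <- function(keywords) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keywords)
  paste0("(?<![\\p{L}])(?:", paste(esc, collapse = "|"), ")(?![\\p{L}])")
}

#' Detect titration in a dosing text
#'
#' True iff a titration keyword occurs in the case-folded text on word
#' boundaries (so "sen" does not fire inside "dosen").
#'
#' @param text Character vector of free texts.
#' @param keywords Titration keywords, lowercase.
#' @return Logical vector.
#' @export
detect_titration <- function(text, keywords = titration_keywords()) {
  grepl(titration_pattern(keywords), tolower(text), perl = TRUE)
}

# Parse a stated duration ("i 1 vecka", "i 10 dagar", "forsta veckan")
# out of one text segment; returns days or NA.
parse_duration_days <- function(text) {
  t <- tolower(text)
  m <- regmatches(t, regexec("i\\s+(\\d+)\\s+dag(?:ar)?\\b", t))[[1]]
  if (length(m)) return(as.numeric(m[2]))
  m <- regmatches(t, regexec("i\\s+(\\d+)\\s+veck(?:a|or)\\b", t))[[1]]
  if (length(m)) return(7 * as.numeric(m[2]))
  m <- regmatches(t, regexec("i\\s+(\\d+)\\s+månad(?:er)?\\b", t))[[1]]
  if (length(m)) return(30 * as.numeric(m[2]))
  if (grepl("i\\s+en\\s+vecka\\b", t)) return(7)
  if (grepl("i\\s+en\\s+månad\\b", t)) return(30)
  if (grepl("första\\s+veckan\\b", t)) return(7)
  m <- regmatches(t, regexec("första\\s+(\\d+)\\s+dagarna\\b", t))[[1]]
  if (length(m)) return(as.numeric(m[2]))
  NA_real_
}

#' Split a titrated dosing text into per-interval segments
#'
#' Titrated prescriptions state a stepwise schedule ("1 tablett dagligen
#' i 1 vecka, darefter 2 tabletter dagligen").  Each titration interval
#' becomes its own entry for classification.  The text is cut at
#' connective keywords ("darefter", "sedan", "sen"); each segment carries
#' its stated duration in days when the segment text states one.  Only
#' the text is segmented; pills, dates and the rest of the record are
#' untouched.
#'
#' @param text A single free text.
#' @param keywords Titration keywords.
#' @return A data.frame with columns `segment_index` (0-based),
#'   `segment_text`, `stated_duration_days` (NA when absent).  A
#'   non-titrated text yields a single segment with index 0.  If
#'   titration is detected but no connective boundary can be cut, the
#'   single returned segment has attribute `needs_review = TRUE`.
#' @export
split_titration <- function(text, keywords = titration_keywords()) {
  stopifnot(length(text) == 1)
  lower <- tolower(text)
  titrated <- detect_titration(text, keywords)
  connective <- "(?:,|;)?\\s*(?:och\\s+)?(?<![\\p{L}])(?:därefter|sedan|sen)(?![\\p{L}])[,:]?\\s*"
  parts <- strsplit(lower, connective, perl = TRUE)[[1]]
  parts <- trimws(gsub("\\s+", " ", parts))
  parts <- parts[nzchar(parts)]
  if (!titrated || length(parts) <= 1) {
    out <- data.frame(segment_index = 0L,
                      segment_text = trimws(gsub("\\s+", " ", lower)),
                      stated_duration_days = parse_duration_days(lower),
                      stringsAsFactors = FALSE)
    if (titrated && length(parts) <= 1) attr(out, "needs_review") <- TRUE
    return(out)
  }
  data.frame(
    segment_index = seq_along(parts) - 1L,
    segment_text = parts,
    stated_duration_days = vapply(parts, parse_duration_days, numeric(1),
                                  USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# Light rule-based Swedish suffix stripper.  Covers the inflections that
# occur in dosing texts ("tabletten" -> "tablett", "dagligen" -> "dag",
# "veckor"/"veckan"/"vecka" -> "veck"); applied once, and a fixed point
# of itself on its own output for this suffix set.
swedish_stem <- function(tokens) {
  suffixes <- c("heterna", "heten", "ligen", "erna", "arna", "orna",
                "ande", "ende", "aste", "aren", "ast", "are", "het",
                "ens", "ern", "ade", "or", "ar", "er", "en", "at",
                "an", "et", "a")
  vapply(tokens, function(w) {
    if (grepl("[0-9]", w) || nchar(w) < 5) return(w)
    for (s in suffixes) {
      if (endsWith(w, s) && nchar(w) - nchar(s) >= 3)
        return(substr(w, 1, nchar(w) - nchar(s)))
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a dosing text into tokens
#'
#' Lowercases, removes non-informative punctuation while preserving
#' intra-number characters needed for doses ("0,5" becomes the token
#' "0.5", "1-2" and "1/2" stay single tokens, the vulgar fraction and
#' the word "halv" become "0.5"), removes stop words, and stems the
#' remaining words with a light Swedish suffix stripper.  Digit-bearing
#' tokens are never stemmed.  The function is idempotent: normalizing
#' its own (re-joined) output changes nothing.
#'
#' @param text Character vector of texts.
#' @param stopwords Stop-word list (default [swedish_stopwords()]).
#' @param stem Apply the stemmer (default TRUE).
#' @return A list of character token vectors (one per input text).
#' @export
normalize_text <- function(text, stopwords = swedish_stopwords(),
                           stem = TRUE) {
  out <- lapply(text, function(t) {
    t <- tolower(t)
    t <- gsub("½", " 0.5 ", t, fixed = TRUE)
    t <- gsub("(?<=[0-9]),(?=[0-9])", ".", t, perl = TRUE)
    # punctuation to whitespace, keeping characters legal inside tokens
    t <- gsub("[^\\p{L}0-9./-]+", " ", t, perl = TRUE)
    toks <- strsplit(trimws(t), "\\s+")[[1]]
    if (length(toks) == 0) return(character(0))
    # strip sentence punctuation from token edges
    toks <- gsub("^[./-]+|[./-]+$", "", toks)
    toks <- toks[nzchar(toks)]
    toks[toks == "halv"] <- "0.5"
    toks <- toks[!toks %in% stopwords]
    if (stem) toks <- swedish_stem(toks)
    toks
  })
  out
}

#' Build a token vocabulary from a corpus
#'
#' Index 0 is reserved for padding and index 1 for out-of-vocabulary
#' tokens; corpus tokens are assigned contiguous indices from 2 upward
#' by descending frequency, ties broken lexicographically (byte order),
#' so rebuilding from the same corpus reproduces the identical mapping.
#'
#' @param corpus A non-empty list of token vectors (from
#'   [normalize_text()]).
#' @return An object of class `sig_vocabulary`: list with `index`
#'   (named integer vector token -> id), `pad_id` (0), `oov_id` (1) and
#'   `size` (number of embedding rows, i.e. max id + 1).
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0) stop("cannot build a vocabulary from an empty corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0) stop("corpus contains no tokens")
  tab <- table(tokens)
  toks <- names(tab)
  freq <- as.integer(tab)
  ord <- order(-freq, toks, method = "radix")
  index <- seq_along(ord) + 1L
  names(index) <- toks[ord]
  structure(list(index = index, pad_id = 0L, oov_id = 1L,
                 size = length(index) + 2L),
            class = "sig_vocabulary")
}

#' Encode tokens as a fixed-length id sequence
#'
#' Tokens map to vocabulary ids (unknown tokens to the OOV id); shorter
#' sequences are post-padded with 0, longer ones truncated from the end
#' (with a warning).
#'
#' @param tokens Character token vector.
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Pad length (default 40).
#' @return Integer vector of length `max_len`.
#' @export
encode_and_pad <- function(tokens, vocab, max_len = 40L) {
  stopifnot(max_len >= 1)
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- vocab$oov_id
  ids <- as.integer(ids)
  if (length(ids) > max_len) {
    warning("sequence of length ", length(ids), " truncated to ", max_len)
    ids <- ids[seq_len(max_len)]
  } else if (length(ids) < max_len) {
    ids <- c(ids, rep(vocab$pad_id, max_len - length(ids)))
  }
  ids
}

#' Encode a corpus into an id matrix
#'
#' @param corpus List of token vectors.
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Pad length.
#' @return Integer matrix, one row per text.
#' @export
encode_corpus <- function(corpus, vocab, max_len = 40L) {
  m <- t(vapply(corpus, encode_and_pad, integer(max_len),
                vocab = vocab, max_len = max_len))
  if (length(corpus) == 1) m <- matrix(m, nrow = 1)
  m
}
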