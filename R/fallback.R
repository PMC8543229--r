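#' Carry a recent dosage forward to a non-informative dispensation
#'
#' A dosage resolved for the same person and same medication (ATC)
#' within `window_days` strictly before the index date is assumed still
#' current; the most recent such dosage wins.  Never looks at
#' dispensations on or after the index date.
#'
#' @param atc ATC code of the index dispensation.
#' @param date Index dispensation date (`Date`).
#' @param history Data.frame of the person's already-resolved
#'   dispensations with columns `atc`, `dispensation_date`,
#'   `pills_per_day`, sorted by date.
#' @param window_days Look-back window (default 365).
#' @return Pills/day, or `NA` when no eligible prior dosage exists.
#' @export
carry_forward <- function(atc, date, history, window_days = 365) {
  if (is.null(history) || nrow(history) == 0) return(NA_real_)
  el <- history$atc == atc &
    history$dispensation_date < date &
    history$dispensation_date >= date - window_days &
    !is.na(history$pills_per_day)
  if (!any(el)) return(NA_real_)
  hits <- history[el, , drop = FALSE]
  hits$pills_per_day[which.max(as.integer(hits$dispensation_date))]
}

#' Build the six structured predictors for the fallback forest
#'
#' Predictors: age, sex, prescriber specialty (6 classes), county (20
#' classes), Nordic article number, and the sequence number of the
#' dispensation within a 6-month treatment window (1 + the number of
#' same-person, same-ATC dispensations in the preceding 183 days).
#'
#' @param records Prescription records for which features are wanted.
#' @param all_records The full record set used to count prior
#'   dispensations (defaults to `records`).
#' @return A data.frame with columns `age`, `sex`, `specialty`,
#'   `county`, `article_number` (factors/numeric) and `sequence_number`.
#' @export
make_features <- function(records, all_records = records) {
  seq_no <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    prior <- all_records$person_id == r$person_id &
      all_records$atc == r$atc &
      all_records$dispensation_date < r$dispensation_date &
      all_records$dispensation_date >= r$dispensation_date - 183
    1L + sum(prior)
  }, integer(1))
  data.frame(
    age = as.numeric(records$age),
    sex = as.character(records$sex),
    specialty = as.character(records$specialty),
    county = as.character(records$county),
    article_number = as.character(records$article_number),
    sequence_number = as.numeric(seq_no),
    stringsAsFactors = FALSE
  )
}

# Coerce character feature columns to the factor levels fixed at fit
# time; unseen categories go to the dedicated "unknown" level.
.apply_feature_levels <- function(features, levels_list) {
  for (nm in names(levels_list)) {
    v <- as.character(features[[nm]])
    v[!v %in% levels_list[[nm]]] <- ".unknown"
    features[[nm]] <- factor(v, levels = c(levels_list[[nm]], ".unknown"))
  }
  features
}

#' Train the fallback random forest
#'
#' 100 classification trees on bootstrap samples of the entries the
#' text model resolved confidently, predicting the dosage class from
#' the six structured features.  Prediction is by majority vote over
#' the per-tree votes, ties broken toward the lower dosage class, so
#' the vote tally is re-derived from the stored per-tree votes rather
#' than delegated to the forest's internal (randomised) tie-break.
#'
#' @param features Feature data.frame from [make_features()].
#' @param dosage_class Gold/confident class labels (codec labels).
#' @param seed Integer seed (fixes the bootstrap and split sampling).
#' @param ntree Number of trees (default 100).
#' @param codec Dosage codec.
#' @return An object of class `fallback_forest`.
#' @export
train_forest <- function(features, dosage_class, seed = 1L, ntree = 100L,
                         codec = dosage_codec()) {
  if (nrow(features) == 0) stop("no training entries for the fallback forest")
  if (length(unique(dosage_class)) < 2)
    stop("fallback forest needs at least 2 dosage classes in training data")
  levels_list <- list(
    sex = sort(unique(as.character(features$sex))),
    specialty = sort(unique(as.character(features$specialty))),
    county = sort(unique(as.character(features$county))),
    article_number = sort(unique(as.character(features$article_number)))
  )
  x <- .apply_feature_levels(features, levels_list)
  y <- factor(dosage_class, levels = codec$labels)
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = droplevels(y), ntree = ntree)
  structure(list(fit = fit, levels = levels_list, codec = codec,
                 classes_present = levels(droplevels(y)), seed = seed),
            class = "fallback_forest")
}

#' Predict pills/day with the fallback forest
#'
#' Majority class over the individual trees' votes; a tie is broken
#' toward the lower dosage class, mirroring the minimum-dosage
#' convention; the winning class is converted to pills/day through the
#' codec.
#'
#' @param model A [train_forest()] model.
#' @param features Feature rows ([make_features()]); unseen categories
#'   are mapped to the "unknown" level rather than failing.
#' @return A list with `pills_per_day`, `class` and the raw vote count
#'   matrix `votes`.
#' @export
predict_forest <- function(model, features) {
  x <- .apply_feature_levels(features, model$levels)
  votes <- stats::predict(model$fit, x, type = "vote", norm.votes = FALSE)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1,
                                           dimnames = list(NULL, model$classes_present))
  # columns ordered by ascending dose so "first" tie-break = lower class
  ord <- order(match(colnames(votes), model$codec$labels))
  votes <- votes[, ord, drop = FALSE]
  win <- max.col(votes, ties.method = "first")
  cls <- colnames(votes)[win]
  list(pills_per_day = class_to_pills(cls, model$codec), class = cls,
       votes = votes)
}

#' Resolve all unresolved dispensations (carry-forward, then forest)
#'
#' Dispensations the text cascade left unresolved are processed in date
#' order within person: first by carry-forward from the person's most
#' recent resolved dosage of the same medication within the look-back
#' window (earlier resolutions — from any source — feed later
#' carry-forwards), then, where no usable history exists, by the
#' fallback forest.  After this step every dispensation has a
#' pills/day value.
#'
#' @param records Prescription records (one row per dispensation), with
#'   a `record_id` column.
#' @param predictions Data.frame aligned with `records`: columns
#'   `pills_per_day`, `final_class`, `source` as returned by the text
#'   cascade (record level).
#' @param forest A [train_forest()] model.
#' @param window_days Carry-forward window (default 365).
#' @return `predictions` with every row resolved and `source` in
#'   `{"nlp2", "carry_forward", "forest"}`.
#' @export
resolve_dispensations <- function(records, predictions, forest,
                                  window_days = 365) {
  stopifnot(nrow(records) == nrow(predictions))
  if (nrow(records) == 0) return(predictions)
  preds <- predictions
  unresolved <- which(preds$source == "unresolved")
  if (length(unresolved) == 0) return(preds)
  # batch forest predictions (structural features; independent of the
  # sequential carry-forward state)
  ffeat <- make_features(records[unresolved, , drop = FALSE], records)
  fpred <- predict_forest(forest, ffeat)
  forest_pills <- setNames(fpred$pills_per_day, as.character(unresolved))
  forest_class <- setNames(fpred$class, as.character(unresolved))

  ord <- order(records$person_id, records$dispensation_date,
               records$record_id)
  for (i in ord) {
    if (preds$source[i] != "unresolved") next
    r <- records[i, ]
    same <- which(records$person_id == r$person_id)
    hist <- data.frame(
      atc = records$atc[same],
      dispensation_date = records$dispensation_date[same],
      pills_per_day = preds$pills_per_day[same],
      stringsAsFactors = FALSE
    )
    cf <- carry_forward(r$atc, r$dispensation_date, hist, window_days)
    if (!is.na(cf)) {
      preds$pills_per_day[i] <- cf
      preds$final_class[i] <- pills_to_class(cf)
      preds$source[i] <- "carry_forward"
    } else {
      key <- as.character(i)
      preds$pills_per_day[i] <- forest_pills[[key]]
      preds$final_class[i] <- forest_class[[key]]
      preds$source[i] <- "forest"
    }
  }
  preds
}
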