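#' Daily-dosage class codec
#'
#' The dosage classifier discretises prescribed daily dosage (pills/day)
#' into 16 ordered classes: 0.5, 1, 2, ..., 9 pills/day as singleton
#' classes, then 10-11, 12-13, 14-15, 16-17, 18-19 and 20+ (high dosages
#' are collapsed because they are rare).  Interval classes are represented
#' numerically by their lower bound, consistent with the convention that a
#' range or add-on instruction is read as the minimum number of pills
#' taken per day.
#'
#' @return An object of class `dosage_codec`: a list with `labels`
#'   (ordered class labels) and `pills` (representative pills/day per
#'   class, strictly increasing).
#' @examples
#' codec <- dosage_codec()
#' codec$labels
#' class_to_pills("10-11")
#' @export
dosage_codec <- function() {
  structure(list(
    labels = c("0.5", "1", "2", "3", "4", "5", "6", "7", "8", "9",
               "10-11", "12-13", "14-15", "16-17", "18-19", "20+"),
    pills  = c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20)
  ), class = "dosage_codec")
}

#' Convert a dosage-class label to its representative pills/day
#'
#' Singleton classes map to themselves; interval classes map to their
#' lower bound (`"10-11"` to 10, ..., `"20+"` to 20).
#'
#' @param label Character vector of class labels.
#' @param codec A [dosage_codec()].
#' @return Numeric vector of pills/day.
#' @export
class_to_pills <- function(label, codec = dosage_codec()) {
  i <- match(label, codec$labels)
  bad <- unique(label[is.na(i) & !is.na(label)])
  if (length(bad))
    stop("unknown dosage class label(s): ", paste(bad, collapse = ", "))
  out <- codec$pills[i]
  out[is.na(label)] <- NA_real_
  out
}

#' Map a numeric daily dosage to its dosage class
#'
#' Every nonnegative dosage maps to exactly one class.  Values are
#' assigned to the nearest class representative, with interval classes
#' covering their stated range (e.g. 10 and 11 pills/day both map to
#' `"10-11"`, anything at or above 20 maps to `"20+"`).
#'
#' @param pills Numeric vector of pills/day (>= 0).
#' @param codec A [dosage_codec()].
#' @return Character vector of class labels.
#' @export
pills_to_class <- function(pills, codec = dosage_codec()) {
  stopifnot(all(pills >= 0, na.rm = TRUE))
  # breakpoints half-way between representatives; interval classes absorb
  # their upper member (10-11 reaches up to <11.5 via the 12 midpoint)
  brk <- c(-Inf, (codec$pills[-length(codec$pills)] + codec$pills[-1]) / 2, Inf)
  codec$labels[findInterval(pills, brk, left.open = TRUE)]
}
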