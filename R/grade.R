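#' KVA grade labels
#'
#' The KVA scale assigns one of the ordinal labels \code{"NA"}, \code{"0"},
#' \code{"1"}, \code{"2"}, \code{"3"}, \code{"4"} to each component of the
#' eye examination. \code{"NA"} marks a best-corrected visual acuity (BCVA)
#' that is stable or improved relative to baseline: it carries no actionable
#' finding, is displayed distinctly in reports, but ranks equal to grade 0
#' when grades are combined by maximum severity.
#'
#' @format A character vector of the six labels in ascending severity order.
#' @export
kva_grade_labels <- c("NA", "0", "1", "2", "3", "4")

#' Numeric severity of a grade label
#'
#' Maps a grade label to the integer used for max-severity combination.
#' \code{"NA"} maps to 0; the numeric labels map to their face value.
#'
#' @param label character vector of grade labels.
#' @return integer vector of the same length.
#' @export
#' @examples
#' grade_severity(c("NA", "0", "3"))
grade_severity <- function(label) {
  bad <- setdiff(label, kva_grade_labels)
  if (length(bad) > 0) {
    kva_error(sprintf("unknown grade label(s): %s", paste(bad, collapse = ", ")),
              "kva_validation_error")
  }
  sev <- integer(length(label))
  num <- label != "NA"
  sev[num] <- as.integer(label[num])
  sev
}

#' Most severe grade among labels
#'
#' Combines grade labels by maximum severity ("most severe finding").
#' \code{"NA"} ranks as 0; the result is \code{"NA"} only when every input
#' is \code{"NA"}, otherwise a numeric label.
#'
#' @param ... grade labels (character scalars or vectors).
#' @return a single grade label.
#' @export
#' @examples
#' grade_max("1", "NA", "0", "2")  # "2"
#' grade_max("NA", "NA")           # "NA"
grade_max <- function(...) {
  labels <- unlist(list(...), use.names = FALSE)
  if (length(labels) == 0) kva_error("no grade labels supplied", "kva_validation_error")
  sev <- grade_severity(labels)
  m <- max(sev)
  if (m == 0L && all(labels == "NA")) "NA" else as.character(m)
}
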