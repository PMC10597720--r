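# KVA grading thresholds for BCVA change and the (decline, current acuity)
# -> grade mapping.

#' KVA scale configuration
#'
#' Holds the line-decline thresholds of the KVA scale for the BCVA-change
#' component. The defaults implement the belamaf KVA scale semantics:
#' a 1-line decline is grade 1; a 2-3 line decline (vision still better
#' than 20/200) is grade 2; a decline of more than 3 lines (still better
#' than 20/200) is grade 3; any decline to 20/200 or worse is grade 4.
#' Stable or improved vision is "N/A". All thresholds are configurable so
#' a revised scale can be dropped in without code changes; the constructor
#' rejects configurations that would leave some decline ungraded.
#'
#' @param grade1_lines decline (in lines) graded 1. Default 1.
#' @param grade2_lines inclusive decline range graded 2. Default \code{c(2, 3)}.
#' @param grade3_more_than declines strictly above this are graded 3.
#'   Default 3.
#' @param grade4_cutoff_logmar logMAR of the "20/200 or worse" cutoff row.
#'   Default 1.0.
#' @return a \code{kva_scale} object.
#' @export
#' @examples
#' sc <- kva_scale()
#' bcva_grade_from_lines(1, parse_acuity("20/25", "snellen"), sc)  # "1"
kva_scale <- function(grade1_lines = 1L, grade2_lines = c(2L, 3L),
                      grade3_more_than = 3L, grade4_cutoff_logmar = 1.0) {
  g1 <- as.integer(grade1_lines)
  g2 <- as.integer(range(grade2_lines))
  g3 <- as.integer(grade3_more_than)
  fail <- function(msg) kva_error(paste0("invalid KVA scale: ", msg), "kva_config_error")
  if (g1 < 1) fail("grade1_lines must be a positive decline")
  if (!(g1 < g2[1] && g2[1] <= g2[2] && g2[2] <= g3)) {
    fail("thresholds must be ordered grade1 < min(grade2) <= max(grade2) <= grade3")
  }
  if (g2[1] != g1 + 1L) fail("grade 2 range must start right after grade1_lines (no ungraded declines)")
  if (g3 != g2[2]) fail("grade 3 must start right after the grade 2 range (no ungraded declines)")
  structure(
    list(grade1_lines = g1, grade2_lines = g2, grade3_more_than = g3,
         grade4_cutoff_logmar = as.numeric(grade4_cutoff_logmar)),
    class = "kva_scale"
  )
}

#' Load a scale configuration from YAML or JSON
#'
#' @param path config file with any of the \code{\link{kva_scale}} fields;
#'   omitted fields keep their defaults.
#' @return a \code{kva_scale}.
#' @export
load_scale <- function(path) {
  cfg <- read_config_file(path)
  args <- cfg[intersect(names(cfg),
                        c("grade1_lines", "grade2_lines", "grade3_more_than",
                          "grade4_cutoff_logmar"))]
  args$grade2_lines <- unlist(args$grade2_lines)
  do.call(kva_scale, args)
}

#' BCVA-change grade from line decline and current acuity
#'
#' The KVA grade for the BCVA component of one eye. A grade is not merely
#' the decline in lines: it also depends on where the current reading sits.
#' Any improvement or no change returns \code{"NA"}; a current reading at
#' or beyond the grade-4 cutoff (20/200 by default) with any decline
#' returns \code{"4"}; otherwise the decline is graded against the
#' configured line thresholds.
#'
#' @param decline integer line change (positive = worse) computed on the
#'   same chart as \code{current}, e.g. by \code{\link{line_change}}.
#' @param current the current-reading \code{kva_acuity}.
#' @param scale a \code{\link{kva_scale}}.
#' @return a grade label: \code{"NA"}, \code{"1"}, \code{"2"}, \code{"3"}
#'   or \code{"4"}.
#' @export
bcva_grade_from_lines <- function(decline, current, scale = kva_scale()) {
  d <- as.integer(decline)
  if (d <= 0L) return("NA")
  if (current$logmar >= scale$grade4_cutoff_logmar - 1e-9) return("4")
  if (d == scale$grade1_lines) return("1")
  if (d >= scale$grade2_lines[1] && d <= scale$grade2_lines[2]) return("2")
  "3"  # by construction every remaining decline is > grade3_more_than
}

#' @export
print.kva_scale <- function(x, ...) {
  cat(sprintf(paste0(
    "<KVA scale> grade1: %d-line decline | grade2: %d-%d lines | grade3: >%d lines",
    " | grade4: current at/worse than logMAR %s\n"),
    x$grade1_lines, x$grade2_lines[1], x$grade2_lines[2], x$grade3_more_than,
    fmt_logmar(x$grade4_cutoff_logmar)))
  invisible(x)
}
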