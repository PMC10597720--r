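# Parsing of visual-acuity readings in three unit systems, conversion via
# canonical chart-row lookup, and line-change arithmetic.

#' Recognized acuity units
#' @format Character vector: \code{"snellen"}, \code{"logmar"}, \code{"decimal"}.
#' @export
acuity_units <- c("snellen", "logmar", "decimal")

# Parse raw text in a given unit to an exact logMAR-equivalent value,
# without reference to any chart. Errors name the offending token.
.raw_logmar <- function(text, unit) {
  bad <- function() {
    kva_error(sprintf("malformed %s acuity: '%s'", unit, text), "kva_parse_error")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) bad()
  if (unit == "snellen") {
    m <- regmatches(txt, regexec("^([0-9]+\\.?[0-9]*)\\s*/\\s*([0-9]+\\.?[0-9]*)$", txt))[[1]]
    if (length(m) == 0) bad()
    num <- as.numeric(m[2]); den <- as.numeric(m[3])
    if (!is.finite(num) || !is.finite(den) || num <= 0 || den <= 0) bad()
    # normalize any numerator to 20: N/D == 20/(D*20/N)
    list(logmar = log10(den / num), norm_den = den * 20 / num)
  } else if (unit == "logmar") {
    if (!grepl("^[+-]?[0-9]*\\.?[0-9]+$", txt)) bad()
    v <- suppressWarnings(as.numeric(txt))
    if (!is.finite(v)) bad()
    list(logmar = v)
  } else if (unit == "decimal") {
    if (!grepl("^[+-]?[0-9]*\\.?[0-9]+$", txt)) bad()
    v <- suppressWarnings(as.numeric(txt))
    if (!is.finite(v) || v <= 0) bad()
    list(logmar = -log10(v), decimal = v)
  } else {
    kva_error(sprintf("unknown acuity unit '%s' (expected one of %s)",
                      unit, paste(acuity_units, collapse = ", ")),
              "kva_parse_error")
  }
}

# Exact-match row index (or NA) for a raw value in its native unit. The
# chart row's listed representation is authoritative: "20/25" matches the
# row whose denominator is 25 even though log10(25/20) = 0.0969 != 0.1.
.strict_row <- function(raw, unit, chart) {
  hit <- switch(unit,
    snellen = which(abs(log10(chart$snellen_denominator) - log10(raw$norm_den)) < 1e-9),
    logmar  = which(abs(chart$logmar - raw$logmar) < 1e-9),
    decimal = which(abs(chart$decimal - raw$decimal) < 1e-9)
  )
  if (length(hit) == 1) hit else NA_integer_
}

.make_acuity <- function(chart, row_i, text, unit, snapped) {
  structure(
    list(
      index = chart$index[row_i],
      logmar = chart$logmar[row_i],
      snellen = chart$snellen[row_i],
      decimal = chart$decimal[row_i],
      source_text = text,
      source_unit = unit,
      snapped = snapped,
      chart_name = chart_name(chart)
    ),
    class = "kva_acuity"
  )
}

#' Parse a visual-acuity reading onto the chart
#'
#' Resolves a raw reading in any of the three units onto a canonical chart
#' row. Under \code{snap = "strict"} (the default, mirroring dropdown-only
#' entry) the value must match a chart row's listed representation in that
#' unit; under \code{snap = "nearest"} an off-chart value is snapped to the
#' row with minimal absolute logMAR difference, ties broken toward the worse
#' row (higher logMAR), and the result is flagged \code{snapped}.
#'
#' @param text the raw reading: Snellen \code{"N/D"} (numerators other than
#'   20 are normalized via logMAR), logMAR as a signed decimal number, or
#'   decimal acuity as a positive number.
#' @param unit one of \code{"snellen"}, \code{"logmar"}, \code{"decimal"}.
#' @param chart a \code{kva_chart}; defaults to \code{\link{default_chart}}.
#' @param snap \code{"strict"} or \code{"nearest"}.
#' @return a \code{kva_acuity} value holding the resolved row, the raw
#'   input text/unit, and the \code{snapped} flag.
#' @export
#' @examples
#' a <- parse_acuity("20/25", "snellen")
#' a$logmar              # 0.1
#' convert_acuity(a, "decimal")  # "0.8"
parse_acuity <- function(text, unit = c("snellen", "logmar", "decimal"),
                         chart = default_chart(),
                         snap = c("strict", "nearest")) {
  unit <- match.arg(unit)
  snap <- match.arg(snap)
  raw <- .raw_logmar(text, unit)
  hit <- .strict_row(raw, unit, chart)
  if (!is.na(hit)) {
    return(.make_acuity(chart, hit, text, unit, snapped = FALSE))
  }
  d <- raw$logmar - chart$logmar
  near <- order(abs(d))[1:2]
  if (snap == "strict") {
    kva_error(sprintf(
      "'%s' (%s) is not on chart '%s'; nearest rows are %s (logMAR %s) and %s (logMAR %s)",
      text, unit, chart_name(chart),
      chart$snellen[near[1]], fmt_logmar(chart$logmar[near[1]]),
      chart$snellen[near[2]], fmt_logmar(chart$logmar[near[2]])),
      "kva_offchart_error")
  }
  # nearest: minimal |delta logMAR|, ties toward worse vision (higher index)
  best <- abs(abs(d) - min(abs(d))) < 1e-12
  row_i <- max(which(best))
  .make_acuity(chart, row_i, text, unit, snapped = TRUE)
}

#' Render an acuity value in a target unit
#'
#' Conversion is a lookup of the value's chart row's canonical
#' representation (never recomputed floating point), so any
#' parse/convert/parse round trip lands on the same row.
#'
#' @param value a \code{kva_acuity}.
#' @param target one of \code{"snellen"}, \code{"logmar"}, \code{"decimal"}.
#' @return the canonical string for that row in the target unit.
#' @export
convert_acuity <- function(value, target = c("snellen", "logmar", "decimal")) {
  target <- match.arg(target)
  switch(target,
    snellen = value$snellen,
    logmar  = fmt_logmar(value$logmar),
    decimal = fmt_decimal(value$decimal)
  )
}

#' Line change between two readings
#'
#' The number of chart lines between baseline and current reading:
#' positive means decline (worse vision), negative improvement, zero no
#' change. One line is one chart row (0.1 logMAR on the default chart).
#'
#' @param baseline,current \code{kva_acuity} values parsed on the same chart.
#' @return an integer line change.
#' @export
#' @examples
#' line_change(parse_acuity("20/20", "snellen"), parse_acuity("20/25", "snellen"))  # 1
line_change <- function(baseline, current) {
  if (!identical(baseline$chart_name, current$chart_name)) {
    kva_error(sprintf("cannot compare readings from different charts ('%s' vs '%s')",
                      baseline$chart_name, current$chart_name),
              "kva_mixed_chart_error")
  }
  as.integer(current$index - baseline$index)
}

#' @export
print.kva_acuity <- function(x, ...) {
  cat(sprintf("<acuity> %s | logMAR %s | decimal %s (chart %s, row %d%s)\n",
              x$snellen, fmt_logmar(x$logmar), fmt_decimal(x$decimal),
              x$chart_name, x$index,
              if (isTRUE(x$snapped)) sprintf(", snapped from '%s'", x$source_text) else ""))
  invisible(x)
}
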