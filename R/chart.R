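# Canonical visual-acuity chart: ordered rows, one row = one line of vision
# = 0.1 logMAR, with per-row Snellen / logMAR / decimal representations.

# Preferred-number ladder used by geometric acuity charts; chart values are
# this ladder scaled by powers of ten (10, 12.5, 16, ..., 63, 80, 100, ...).
.acuity_ladder <- c(1, 1.25, 1.6, 2, 2.5, 3.2, 4, 5, 6.3, 8)

# Snap a positive real to the nearest ladder value (nearest on a log scale).
.ladder_snap <- function(x) {
  k <- floor(log10(x))
  cand <- c(.acuity_ladder * 10^(k - 1), .acuity_ladder * 10^k, .acuity_ladder * 10^(k + 1))
  cand[which.min(abs(log10(cand) - log10(x)))]
}

.new_chart <- function(logmar, snellen_denominator, decimal, name) {
  n <- length(logmar)
  chart <- data.frame(
    index = seq_len(n) - 1L,
    logmar = round(logmar, 10),
    snellen_denominator = snellen_denominator,
    decimal = decimal,
    stringsAsFactors = FALSE
  )
  chart$snellen <- vapply(chart$snellen_denominator, fmt_snellen, character(1))
  attr(chart, "chart_name") <- name
  class(chart) <- c("kva_chart", "data.frame")
  validate_chart(chart)
  chart
}

#' Name of a chart
#' @param chart a \code{kva_chart}.
#' @return the chart's dialect identifier string.
#' @export
chart_name <- function(chart) attr(chart, "chart_name")

#' Default 24-row acuity chart
#'
#' The default chart spans logMAR \eqn{-0.3} to \eqn{2.0} in uniform 0.1
#' steps (24 rows), i.e. Snellen 20/10 down to 20/2000, with denominators on
#' the conventional 1 / 1.25 / 1.6 / 2 / 2.5 / 3.2 / 4 / 5 / 6.3 / 8 ladder
#' and decimal acuity listed as the ladder value nearest
#' \eqn{10^{-\mathrm{logMAR}}} (so 20/32 lists decimal 0.63, not 0.625).
#' One chart row is one "line of vision"; all grading arithmetic is in row
#' (line) units, which makes it independent of the input unit.
#'
#' @return a \code{kva_chart} data frame with columns \code{index},
#'   \code{logmar}, \code{snellen_denominator}, \code{decimal},
#'   \code{snellen}.
#' @export
#' @examples
#' chart <- default_chart()
#' nrow(chart)                         # 24
#' chart[chart$logmar == 0, "snellen"] # "20/20"
default_chart <- function() {
  logmar <- seq(-0.3, 2.0, by = 0.1)
  den <- vapply(20 * 10^logmar, .ladder_snap, numeric(1))
  dec <- vapply(10^(-logmar), .ladder_snap, numeric(1))
  .new_chart(logmar, den, dec, name = "etdrs24")
}

#' Validate a chart against its structural invariants
#'
#' Checks uniform 0.1-logMAR spacing, strict monotonicity of the three
#' representations, no duplicate or missing indices, and the presence of the
#' 20/20 (logMAR 0.0) and 20/200 (logMAR 1.0) rows.
#'
#' @param chart a \code{kva_chart}.
#' @return the chart, invisibly, if valid; otherwise a config error.
#' @export
validate_chart <- function(chart) {
  fail <- function(msg) kva_error(paste0("invalid chart: ", msg), "kva_config_error")
  if (nrow(chart) < 2) fail("needs at least two rows")
  if (!identical(chart$index, seq_len(nrow(chart)) - 1L)) fail("row indices must be 0,1,2,... without gaps")
  steps <- diff(chart$logmar)
  if (any(abs(steps - 0.1) > 1e-6)) fail("rows must be uniformly spaced at 0.1 logMAR")
  if (any(diff(chart$snellen_denominator) <= 0)) fail("Snellen denominators must strictly increase")
  if (any(diff(chart$decimal) >= 0)) fail("decimal acuities must strictly decrease")
  if (any(chart$snellen_denominator <= 0) || any(chart$decimal <= 0)) fail("Snellen/decimal values must be positive")
  rel <- abs(20 / chart$snellen_denominator - chart$decimal) / chart$decimal
  if (any(rel > 0.05)) fail("decimal must agree with 20/denominator to ~2 significant figures")
  if (!any(abs(chart$logmar - 0.0) < 1e-9)) fail("must contain the 20/20 (logMAR 0.0) row")
  if (!any(abs(chart$logmar - 1.0) < 1e-9)) fail("must contain the 20/200 (logMAR 1.0) row")
  invisible(chart)
}

#' Load a chart from a YAML or JSON config file
#'
#' The file holds \code{name} and a \code{rows} list, each row
#' \code{{logmar, snellen: "20/D", decimal}}. Rows are sorted by logMAR and
#' validated against the chart invariants.
#'
#' @param path path to a \code{.yaml}/\code{.yml}/\code{.json} file.
#' @return a \code{kva_chart}.
#' @export
load_chart <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$rows)) kva_error("chart config must have a 'rows' list", "kva_config_error")
  nm <- if (!is.null(cfg$name)) as.character(cfg$name) else tools::file_path_sans_ext(basename(path))
  logmar <- vapply(cfg$rows, function(r) as.numeric(r$logmar), numeric(1))
  den <- vapply(cfg$rows, function(r) {
    s <- as.character(r$snellen)
    if (!grepl("^\\s*20\\s*/", s)) {
      kva_error(sprintf("chart row snellen '%s' must have numerator 20", s), "kva_config_error")
    }
    as.numeric(sub("^\\s*20\\s*/\\s*", "", s))
  }, numeric(1))
  dec <- vapply(cfg$rows, function(r) as.numeric(r$decimal), numeric(1))
  ord <- order(logmar)
  .new_chart(logmar[ord], den[ord], dec[ord], name = nm)
}
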