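# Per-baseline finite-state transition models: for each baseline chart row,
# a total precompiled map from every current row to a BCVA-change grade.
# Grading at query time is a pure table lookup, never a recomputation.

.baseline_index <- function(baseline, chart) {
  if (inherits(baseline, "kva_acuity")) {
    if (!identical(baseline$chart_name, chart_name(chart))) {
      kva_error(sprintf("baseline parsed on chart '%s' but model chart is '%s'",
                        baseline$chart_name, chart_name(chart)),
                "kva_mixed_chart_error")
    }
    return(baseline$index)
  }
  i <- as.integer(baseline)
  if (is.na(i) || i < 0L || i >= nrow(chart)) {
    kva_error(sprintf("baseline row %s is not in chart '%s' (rows 0..%d)",
                      as.character(baseline), chart_name(chart), nrow(chart) - 1L),
              "kva_config_error")
  }
  i
}

#' Compile one transition model for a baseline row
#'
#' Builds the total map from every current chart row to a BCVA-change grade
#' label for a fixed baseline row, by evaluating the KVA scale on the line
#' change and current acuity of each row. The model for the baseline row
#' itself and for every better row is \code{"NA"} (stable or improved
#' vision carries no grade).
#'
#' @param baseline a chart row index (0-based) or a \code{kva_acuity}.
#' @param chart a \code{kva_chart}.
#' @param scale a \code{\link{kva_scale}}.
#' @return a \code{kva_model}: baseline row, named transition vector
#'   (names are Snellen row labels), chart name, and scale fingerprint.
#' @export
#' @examples
#' m <- compile_model(parse_acuity("20/20", "snellen"), default_chart(), kva_scale())
#' m$transitions[["20/25"]]  # "1"
compile_model <- function(baseline, chart = default_chart(), scale = kva_scale()) {
  b <- .baseline_index(baseline, chart)
  transitions <- vapply(seq_len(nrow(chart)), function(i) {
    bcva_grade_from_lines(chart$index[i] - b, list(logmar = chart$logmar[i]), scale)
  }, character(1))
  names(transitions) <- chart$snellen
  structure(
    list(baseline_index = b,
         baseline_label = chart$snellen[b + 1L],
         transitions = transitions,
         chart_name = chart_name(chart),
         scale_fingerprint = kva_fingerprint(unclass(scale))),
    class = "kva_model"
  )
}

#' Compile the full model library
#'
#' One transition model per chart row (24 on the default chart), carrying
#' chart and scale fingerprints so a library applied against an edited
#' configuration fails loudly rather than silently regrading.
#'
#' @param chart a \code{kva_chart}.
#' @param scale a \code{\link{kva_scale}}.
#' @return a \code{kva_library}.
#' @export
compile_library <- function(chart = default_chart(), scale = kva_scale()) {
  validate_chart(chart)
  models <- lapply(chart$index, compile_model, chart = chart, scale = scale)
  structure(
    list(chart = chart,
         scale = scale,
         chart_fingerprint = kva_fingerprint(.chart_as_list(chart)),
         scale_fingerprint = kva_fingerprint(unclass(scale)),
         models = models),
    class = "kva_library"
  )
}

#' Grade a baseline/current pair by model lookup
#'
#' Selects the transition model matching the baseline reading and looks up
#' the current reading's row. This is the production grading path; it never
#' recomputes thresholds at query time.
#'
#' @param library a \code{kva_library}.
#' @param baseline,current \code{kva_acuity} values parsed on the library's
#'   chart.
#' @return a grade label.
#' @export
#' @examples
#' lib <- compile_library()
#' apply_model(lib, parse_acuity("20/20", "snellen"), parse_acuity("20/25", "snellen"))  # "1"
apply_model <- function(library, baseline, current) {
  cn <- chart_name(library$chart)
  for (v in list(baseline, current)) {
    if (!identical(v$chart_name, cn)) {
      kva_error(sprintf("reading parsed on chart '%s' but library was compiled on '%s'",
                        v$chart_name, cn),
                "kva_mixed_chart_error")
    }
  }
  unname(library$models[[baseline$index + 1L]]$transitions[current$index + 1L])
}

.chart_as_list <- function(chart) {
  list(name = chart_name(chart),
       rows = lapply(seq_len(nrow(chart)), function(i) {
         list(logmar = chart$logmar[i],
              snellen = chart$snellen[i],
              decimal = chart$decimal[i])
       }))
}

#' Export a model library as JSON or Graphviz DOT
#'
#' JSON carries the chart rows, scale configuration, fingerprints and one
#' object per baseline with the complete current-row-to-grade map, in
#' stable key order so output is byte-reproducible;
#' \code{\link{import_library}} restores an identical library from it.
#' DOT renders one digraph per baseline with edges labeled by grade;
#' \code{"NA"} transitions (improvement or no change) are omitted from the
#' drawing, though they remain present in the JSON for totality.
#'
#' @param library a \code{kva_library}.
#' @param format \code{"json"} or \code{"dot"}.
#' @return a single character string (the document).
#' @export
export_library <- function(library, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      chart = .chart_as_list(library$chart),
      scale = unclass(library$scale),
      chart_fingerprint = library$chart_fingerprint,
      scale_fingerprint = library$scale_fingerprint,
      models = lapply(library$models, function(m) {
        list(baseline = m$baseline_label, transitions = as.list(m$transitions))
      })
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10, pretty = TRUE)))
  }
  out <- character(0)
  for (m in library$models) {
    out <- c(out, sprintf('digraph "baseline %s" {', m$baseline_label),
             '  rankdir=LR;')
    keep <- m$transitions != "NA"
    for (target in names(m$transitions)[keep]) {
      out <- c(out, sprintf('  "%s" -> "%s" [label="%s"];',
                            m$baseline_label, target, m$transitions[[target]]))
    }
    out <- c(out, "}", "")
  }
  paste(out, collapse = "\n")
}

#' Restore a model library from its JSON export
#'
#' Rebuilds the chart and scale from the document, re-attaches the stored
#' transition tables, and verifies the stored fingerprints against the
#' reconstructed chart/scale (a mismatch means the export is stale or was
#' edited and is rejected).
#'
#' @param text JSON text produced by \code{\link{export_library}}, or a
#'   path to a file containing it.
#' @return a \code{kva_library}.
#' @export
import_library <- function(text) {
  if (length(text) == 1 && !grepl("{", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  rows <- doc$chart$rows
  chart <- .new_chart(
    logmar = vapply(rows, function(r) as.numeric(r$logmar), numeric(1)),
    snellen_denominator = vapply(rows, function(r) as.numeric(sub("^20/", "", r$snellen)), numeric(1)),
    decimal = vapply(rows, function(r) as.numeric(r$decimal), numeric(1)),
    name = doc$chart$name
  )
  scale <- kva_scale(doc$scale$grade1_lines, unlist(doc$scale$grade2_lines),
                     doc$scale$grade3_more_than, doc$scale$grade4_cutoff_logmar)
  if (!identical(kva_fingerprint(.chart_as_list(chart)), doc$chart_fingerprint) ||
      !identical(kva_fingerprint(unclass(scale)), doc$scale_fingerprint)) {
    kva_error("library export is stale: fingerprints do not match its chart/scale",
              "kva_config_error")
  }
  models <- lapply(doc$models, function(m) {
    tr <- vapply(m$transitions, as.character, character(1))
    b <- match(m$baseline, chart$snellen) - 1L
    structure(
      list(baseline_index = b, baseline_label = m$baseline,
           transitions = tr, chart_name = chart_name(chart),
           scale_fingerprint = doc$scale_fingerprint),
      class = "kva_model"
    )
  })
  structure(
    list(chart = chart, scale = scale,
         chart_fingerprint = doc$chart_fingerprint,
         scale_fingerprint = doc$scale_fingerprint,
         models = models),
    class = "kva_library"
  )
}

#' @export
print.kva_library <- function(x, ...) {
  cat(sprintf("<KVA model library> %d transition models on chart '%s' (%d rows)\n",
              length(x$models), chart_name(x$chart), nrow(x$chart)))
  invisible(x)
}
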