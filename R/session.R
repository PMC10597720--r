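# Exam sessions (one visit, both eyes) and the grading pipeline:
# parse acuities -> select + apply transition model per eye -> grade the
# corneal exam per eye -> combine into the overall KVA grade, with a full
# audit trail of raw inputs. Sessions are stateless single-visit
# computations; nothing is persisted.

#' Construct an exam session
#'
#' One visit's raw inputs for both eyes: baseline and current BCVA readings
#' (as raw strings in one declared unit) plus the corneal-exam answers per
#' eye. The session stores inputs only; grading happens in
#' \code{\link{run_session}}.
#'
#' @param patient_label opaque display label (no identifying semantics).
#' @param unit \code{"snellen"}, \code{"logmar"} or \code{"decimal"};
#'   applies to all four acuity strings.
#' @param baseline,current named lists/vectors with \code{od} and \code{os}
#'   raw acuity strings.
#' @param corneal named list with \code{od} and \code{os} answer sets
#'   (question id to response).
#' @param schema_variant corneal schema variant name.
#' @param chart_name identifier of the chart the readings refer to.
#' @return a \code{kva_session}.
#' @export
#' @examples
#' s <- exam_session(
#'   patient_label = "demo",
#'   unit = "snellen",
#'   baseline = list(od = "20/20", os = "20/20"),
#'   current = list(od = "20/25", os = "20/20"),
#'   corneal = list(
#'     od = c(spk = "none", mec = "no", defect = "no", other = "no"),
#'     os = c(spk = "none", mec = "no", defect = "no", other = "no")))
#' run_session(s)$overall_kva  # "1"
exam_session <- function(patient_label = "anonymous",
                         unit = c("snellen", "logmar", "decimal"),
                         baseline, current, corneal,
                         schema_variant = "dreamm_kva",
                         chart_name = "etdrs24") {
  unit <- match.arg(unit)
  need_eyes <- function(x, what) {
    x <- as.list(x)
    if (!all(c("od", "os") %in% names(x))) {
      kva_error(sprintf("%s must have 'od' and 'os' entries", what), "kva_validation_error")
    }
    x[c("od", "os")]
  }
  structure(
    list(patient_label = as.character(patient_label),
         unit = unit,
         baseline = lapply(need_eyes(baseline, "baseline"), as.character),
         current = lapply(need_eyes(current, "current"), as.character),
         corneal = lapply(need_eyes(corneal, "corneal"), as.list),
         schema_variant = schema_variant,
         chart_name = chart_name),
    class = "kva_session"
  )
}

#' Read / write a session JSON file
#'
#' @param path file path.
#' @return \code{read_session}: a \code{kva_session}.
#' @export
read_session <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("unit", "baseline", "current", "corneal")) {
    if (is.null(doc[[f]])) {
      kva_error(sprintf("session file is missing required field '%s'", f), "kva_validation_error")
    }
  }
  exam_session(patient_label = if (is.null(doc$patient_label)) "anonymous" else doc$patient_label,
               unit = doc$unit, baseline = doc$baseline, current = doc$current,
               corneal = doc$corneal,
               schema_variant = if (is.null(doc$schema_variant)) "dreamm_kva" else doc$schema_variant,
               chart_name = if (is.null(doc$chart_name)) "etdrs24" else doc$chart_name)
}

#' @rdname read_session
#' @param session a \code{kva_session} to write.
#' @export
write_session <- function(session, path) {
  writeLines(as.character(jsonlite::toJSON(unclass(session), auto_unbox = TRUE, pretty = TRUE)),
             path)
  invisible(path)
}

#' Re-render a session's acuity strings in another unit
#'
#' Parses the four readings under the session's declared unit and rewrites
#' them as the canonical strings of the same chart rows in \code{unit}.
#' Grading is unit-invariant, so the re-rendered session grades
#' identically.
#'
#' @param session a \code{kva_session}.
#' @param unit target unit.
#' @param chart the chart to parse against.
#' @return a \code{kva_session} in the target unit.
#' @export
convert_session_units <- function(session, unit, chart = default_chart()) {
  rerender <- function(text) {
    convert_acuity(parse_acuity(text, session$unit, chart, snap = "strict"), unit)
  }
  session$baseline <- lapply(session$baseline, rerender)
  session$current <- lapply(session$current, rerender)
  session$unit <- unit
  session
}

#' Grade an exam session
#'
#' Runs the full pipeline: parse the four acuity readings, select the
#' transition model matching each eye's baseline and look up its current
#' reading, validate and grade the corneal answers per eye, and combine
#' everything into the overall KVA grade. Any validation failure aborts
#' with an error; there is no partial grading.
#'
#' @param session a \code{kva_session}.
#' @param library a compiled \code{kva_library}; defaults to the default
#'   chart and scale.
#' @param schema a \code{kva_schema}; defaults to the session's declared
#'   variant.
#' @param snap acuity snap policy, \code{"strict"} or \code{"nearest"}.
#' @param verbose if \code{TRUE}, messages each decision (model selected
#'   per eye, snapped inputs, disabled questions).
#' @return a \code{kva_report}.
#' @export
run_session <- function(session, library = compile_library(),
                        schema = NULL, snap = c("strict", "nearest"),
                        verbose = FALSE) {
  snap <- match.arg(snap)
  if (!inherits(session, "kva_session")) {
    kva_error("session must be a kva_session (see exam_session())", "kva_validation_error")
  }
  if (!identical(session$chart_name, chart_name(library$chart))) {
    kva_error(sprintf("session refers to chart '%s' but library was compiled on '%s'",
                      session$chart_name, chart_name(library$chart)),
              "kva_mixed_chart_error")
  }
  if (is.null(schema)) schema <- default_schema(session$schema_variant)
  say <- function(...) if (isTRUE(verbose)) message(sprintf(...))

  parse_one <- function(text, what) {
    v <- parse_acuity(text, session$unit, library$chart, snap = snap)
    if (isTRUE(v$snapped)) say("%s '%s' snapped to %s", what, text, v$snellen)
    v
  }
  acuities <- list(
    baseline = lapply(c(od = "od", os = "os"), function(e) {
      parse_one(session$baseline[[e]], paste("baseline", toupper(e)))
    }),
    current = lapply(c(od = "od", os = "os"), function(e) {
      parse_one(session$current[[e]], paste("current", toupper(e)))
    })
  )
  bcva <- lapply(c(od = "od", os = "os"), function(e) {
    b <- acuities$baseline[[e]]
    say("eye %s: selected transition model for baseline %s", toupper(e), b$snellen)
    apply_model(library, b, acuities$current[[e]])
  })
  corneal_resp <- list(
    od = validate_responses(session$corneal$od, schema, eye = "OD"),
    os = validate_responses(session$corneal$os, schema, eye = "OS")
  )
  for (e in c("od", "os")) {
    disabled <- setdiff(vapply(schema$questions, `[[`, character(1), "id"),
                        names(corneal_resp[[e]]$answers))
    if (length(disabled) > 0) {
      say("eye %s: question(s) %s disabled by earlier answers",
          toupper(e), paste(disabled, collapse = ", "))
    }
  }
  corneal <- lapply(corneal_resp, grade_corneal, schema = schema)
  overall <- compute_overall(bcva$od, bcva$os, corneal$od, corneal$os)

  echo_acuity <- function(v) {
    list(raw = v$source_text, unit = v$source_unit, snellen = v$snellen,
         logmar = fmt_logmar(v$logmar), snapped = v$snapped)
  }
  structure(
    list(patient_label = session$patient_label,
         od = overall$od, os = overall$os,
         overall_kva = overall$overall_kva,
         inputs_echo = list(
           unit = session$unit,
           snap_policy = snap,
           baseline = lapply(acuities$baseline, echo_acuity),
           current = lapply(acuities$current, echo_acuity),
           corneal = list(od = corneal_resp$od$answers, os = corneal_resp$os$answers),
           schema_variant = schema$variant,
           chart_name = chart_name(library$chart)),
         fingerprints = list(chart = library$chart_fingerprint,
                             scale = library$scale_fingerprint,
                             schema = schema$fingerprint)),
    class = "kva_report"
  )
}

#' Render a grade report
#'
#' Text layout follows clinical charting convention: the patient's right
#' eye (OD) is printed in the left column. JSON is stable-ordered and
#' re-parses to an equal report via \code{\link{parse_report}}.
#'
#' @param report a \code{kva_report}.
#' @param format \code{"text"} or \code{"json"}.
#' @return a single character string.
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)))
  }
  e <- report$inputs_echo
  flag <- function(a) if (isTRUE(a$snapped)) sprintf("%s [snapped from %s]", a$snellen, a$raw) else a$snellen
  row3 <- function(label, od, os) sprintf("  %-22s %-24s %-24s", label, od, os)
  lines <- c(
    sprintf("KVA grade report — %s", report$patient_label),
    sprintf("unit: %s | chart: %s | schema: %s | snap: %s",
            e$unit, e$chart_name, e$schema_variant, e$snap_policy),
    "",
    row3("", "OD (right eye)", "OS (left eye)"),
    row3("baseline BCVA", flag(e$baseline$od), flag(e$baseline$os)),
    row3("current BCVA", flag(e$current$od), flag(e$current$os)),
    row3("BCVA change grade", report$od$bcva_grade, report$os$bcva_grade),
    row3("corneal exam grade", report$od$corneal_grade, report$os$corneal_grade),
    row3("eye KVA grade", report$od$eye_kva, report$os$eye_kva),
    "",
    sprintf("Overall KVA grade: %s", report$overall_kva),
    "",
    "Audit — raw inputs:",
    vapply(c(od = "od", os = "os"), function(eye) {
      sprintf("  %s: baseline '%s', current '%s' (%s)%s | corneal: %s",
              toupper(eye),
              e$baseline[[eye]]$raw, e$current[[eye]]$raw, e$unit,
              if (isTRUE(e$baseline[[eye]]$snapped) || isTRUE(e$current[[eye]]$snapped)) " [snapped]" else "",
              paste(names(e$corneal[[eye]]), unlist(e$corneal[[eye]]),
                    sep = "=", collapse = ", "))
    }, character(1))
  )
  paste(lines, collapse = "\n")
}

#' Re-parse a JSON report
#'
#' @param text JSON produced by \code{render_report(report, "json")}.
#' @return a \code{kva_report} equal to the rendered one.
#' @export
parse_report <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  fix_acuity <- function(a) {
    a$snapped <- isTRUE(a$snapped)
    a[c("raw", "unit", "snellen", "logmar", "snapped")]
  }
  doc$inputs_echo$baseline <- lapply(doc$inputs_echo$baseline, fix_acuity)
  doc$inputs_echo$current <- lapply(doc$inputs_echo$current, fix_acuity)
  structure(doc, class = "kva_report")
}

#' @export
print.kva_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
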