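# Conditional question schema for the corneal examination and the
# per-eye corneal-component grade.
#
# A schema is an ordered list of dropdown questions. Each question may be
# gated by `enabled_when`, a predicate over EARLIER answers expressed
# declaratively (so schemas can live in config files, not code):
#   enabled_when = list(  # OR over alternatives
#     list(               # AND within an alternative
#       list(question = "spk", op = "ne", value = "none")
#     )
#   )
# Each response option carries exactly one grade contribution; the corneal
# grade for the eye is the maximum contribution over answered questions
# ("most severe finding"), subject to the clear-cornea short-circuit.

.cond <- function(question, op, value) list(question = question, op = op, value = value)

.question <- function(id, prompt, responses, contributions, enabled_when = NULL) {
  stopifnot(length(responses) == length(contributions))
  list(id = id, prompt = prompt, responses = responses,
       grade_contribution = stats::setNames(as.character(contributions), responses),
       enabled_when = enabled_when)
}

#' Default corneal-examination question schema
#'
#' The \code{dreamm_kva} variant has exactly 5 questions: (1) superficial
#' punctate keratopathy (SPK), answered none/mild/moderate/severe and
#' contributing grades 0/1/2/3; (2) microcyst-like epithelial changes
#' (MECs), yes/no, documentation only; (3) predominant location of corneal
#' findings (peripheral/paracentral/central), enabled only when SPK or MECs
#' are present — answering it when neither finding exists is an impossible
#' scenario and is rejected; (4) corneal epithelial defect, yes/no, with
#' yes contributing grade 4; (5) other clinically significant corneal
#' finding, yes/no, documentation only.
#'
#' The \code{clear_cornea} variant prepends a "clear cornea?" question;
#' answering yes disables every subsequent question and fixes the corneal
#' grade at 0 (the lowest level possible) without consulting anything else.
#'
#' Prompts, response vocabularies, gating predicates and grade
#' contributions beyond the SPK wording and the epithelial-defect linkage
#' are conventional defaults and can be replaced wholesale via
#' \code{\link{load_schema}}.
#'
#' @param variant \code{"dreamm_kva"} or \code{"clear_cornea"}.
#' @return a \code{kva_schema}.
#' @export
#' @examples
#' s <- default_schema()
#' length(s$questions)               # 5
#' s$questions[[1]]$responses        # none mild moderate severe
default_schema <- function(variant = c("dreamm_kva", "clear_cornea")) {
  variant <- match.arg(variant)
  qs <- list(
    .question("spk", "Superficial punctate keratopathy (SPK)?",
              c("none", "mild", "moderate", "severe"), c("0", "1", "2", "3")),
    .question("mec", "Microcyst-like epithelial changes present?",
              c("no", "yes"), c("0", "0")),
    .question("location", "Predominant location of corneal findings?",
              c("peripheral", "paracentral", "central"), c("0", "0", "0"),
              enabled_when = list(list(.cond("spk", "ne", "none")),
                                  list(.cond("mec", "eq", "yes")))),
    .question("defect", "Corneal epithelial defect present?",
              c("no", "yes"), c("0", "4")),
    .question("other", "Other clinically significant corneal finding?",
              c("no", "yes"), c("0", "0"))
  )
  short_circuit <- NULL
  if (variant == "clear_cornea") {
    gate <- .cond("clear", "eq", "no")
    qs <- lapply(qs, function(q) {
      q$enabled_when <- if (is.null(q$enabled_when)) {
        list(list(gate))
      } else {
        lapply(q$enabled_when, function(alt) c(list(gate), alt))
      }
      q
    })
    qs <- c(list(.question("clear", "Clear cornea?",
                           c("yes", "no"), c("0", "0"))), qs)
    short_circuit <- list(question = "clear", response = "yes", grade = "0")
  }
  .new_schema(variant, qs, short_circuit)
}

.new_schema <- function(variant, questions, short_circuit = NULL) {
  schema <- list(variant = variant, questions = questions,
                 short_circuit = short_circuit)
  schema$fingerprint <- kva_fingerprint(schema[c("variant", "questions", "short_circuit")])
  class(schema) <- "kva_schema"
  validate_schema(schema)
  schema
}

#' Validate schema structural invariants
#'
#' Unique ids, non-empty response lists, one grade contribution per
#' response, and gating predicates that reference only earlier questions.
#'
#' @param schema a \code{kva_schema}.
#' @return the schema, invisibly.
#' @export
validate_schema <- function(schema) {
  fail <- function(msg) kva_error(paste0("invalid schema: ", msg), "kva_config_error")
  ids <- vapply(schema$questions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) fail("duplicate question ids")
  for (k in seq_along(schema$questions)) {
    q <- schema$questions[[k]]
    if (length(q$responses) == 0) fail(sprintf("question '%s' has no responses", q$id))
    if (!setequal(names(q$grade_contribution), q$responses) ||
        length(q$grade_contribution) != length(q$responses)) {
      fail(sprintf("question '%s' needs exactly one grade contribution per response", q$id))
    }
    grade_severity(q$grade_contribution)  # rejects unknown labels
    for (alt in q$enabled_when) {
      for (cond in alt) {
        ref <- match(cond$question, ids)
        if (is.na(ref) || ref >= k) {
          fail(sprintf("question '%s' is gated on '%s', which is not an earlier question",
                       q$id, cond$question))
        }
        if (!cond$op %in% c("eq", "ne")) fail(sprintf("unknown predicate op '%s'", cond$op))
      }
    }
  }
  invisible(schema)
}

#' Load a question schema from YAML or JSON
#'
#' The file holds \code{variant}, a \code{questions} list (each with
#' \code{id}, \code{prompt}, \code{responses}, \code{grade_contribution},
#' optional \code{enabled_when}) and an optional \code{short_circuit}
#' block. Validated on load; the fingerprint is recomputed from the
#' normalized content.
#'
#' @param path config file path.
#' @return a \code{kva_schema}.
#' @export
load_schema <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$questions)) kva_error("schema config must have a 'questions' list", "kva_config_error")
  qs <- lapply(cfg$questions, function(q) {
    responses <- as.character(unlist(q$responses))
    contrib <- q$grade_contribution
    if (!is.null(names(contrib))) contrib <- unlist(contrib)[responses]
    .question(q$id, q$prompt, responses, as.character(unlist(contrib)),
              enabled_when = if (is.null(q$enabled_when)) NULL else {
                lapply(q$enabled_when, function(alt) {
                  lapply(alt, function(cond) .cond(cond$question, cond$op, cond$value))
                })
              })
  })
  .new_schema(if (is.null(cfg$variant)) "custom" else cfg$variant, qs,
              short_circuit = cfg$short_circuit)
}

# Evaluate an enabled_when predicate against the answers collected so far.
.question_enabled <- function(q, answers) {
  if (is.null(q$enabled_when)) return(TRUE)
  for (alt in q$enabled_when) {
    ok <- TRUE
    for (cond in alt) {
      a <- answers[[cond$question]]
      hit <- !is.null(a) && identical(a, cond$value)
      if ((cond$op == "eq" && !hit) || (cond$op == "ne" && (is.null(a) || hit))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Which questions are enabled for a (possibly partial) answer set
#'
#' @param schema a \code{kva_schema}.
#' @param answers named list/character vector of answers so far.
#' @return character vector of enabled question ids, in schema order.
#' @export
enabled_questions <- function(schema, answers = list()) {
  answers <- as.list(answers)
  ids <- character(0)
  for (q in schema$questions) {
    if (.question_enabled(q, answers)) ids <- c(ids, q$id)
  }
  ids
}

#' Validate one eye's corneal-exam responses
#'
#' Walks the schema in order enforcing the conditional gating: every
#' enabled question must be answered with a response from its dropdown
#' vocabulary, and an answer to a disabled question — an impossible
#' scenario, such as a findings location when no finding was reported — is
#' rejected. Returns the answers normalized to schema order.
#'
#' @param answers named list or character vector, question id to response.
#' @param schema a \code{kva_schema}.
#' @param eye \code{"OD"} (right) or \code{"OS"} (left).
#' @return a \code{kva_corneal_responses} carrying the eye, the normalized
#'   answers and the schema fingerprint.
#' @export
#' @examples
#' r <- validate_responses(c(spk = "mild", mec = "no", location = "central",
#'                           defect = "no", other = "no"), default_schema())
#' grade_corneal(r, default_schema())  # "1"
validate_responses <- function(answers, schema = default_schema(), eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  answers <- as.list(answers)
  ids <- vapply(schema$questions, `[[`, character(1), "id")
  unknown <- setdiff(names(answers), ids)
  if (length(unknown) > 0) {
    kva_error(sprintf("unknown corneal question(s): %s", paste(unknown, collapse = ", ")),
              "kva_validation_error")
  }
  normalized <- list()
  for (q in schema$questions) {
    a <- answers[[q$id]]
    if (.question_enabled(q, normalized)) {
      if (is.null(a)) {
        kva_error(sprintf("missing answer to enabled question '%s' (%s)", q$id, q$prompt),
                  "kva_validation_error")
      }
      if (!a %in% q$responses) {
        kva_error(sprintf("'%s' is not a valid response to '%s' (expected one of: %s)",
                          a, q$id, paste(q$responses, collapse = ", ")),
                  "kva_validation_error")
      }
      normalized[[q$id]] <- a
    } else if (!is.null(a)) {
      kva_error(sprintf("impossible scenario: question '%s' is disabled by earlier answers but was answered '%s'",
                        q$id, a),
                "kva_validation_error")
    }
  }
  structure(list(eye = eye, answers = normalized,
                 schema_fingerprint = schema$fingerprint),
            class = "kva_corneal_responses")
}

#' Corneal-component grade for one eye
#'
#' The maximum grade contribution over the answered questions. If the
#' schema has a clear-cornea short-circuit and it fires, the grade is 0
#' without consulting any other contribution. Responses must have been
#' validated against this same schema (fingerprints are compared).
#'
#' @param responses a \code{kva_corneal_responses} from
#'   \code{\link{validate_responses}}.
#' @param schema the \code{kva_schema} the responses were validated against.
#' @return a grade label \code{"0"}..\code{"4"}.
#' @export
grade_corneal <- function(responses, schema = default_schema()) {
  if (!inherits(responses, "kva_corneal_responses")) {
    kva_error("responses must come from validate_responses()", "kva_validation_error")
  }
  if (!identical(responses$schema_fingerprint, schema$fingerprint)) {
    kva_error("stale schema: responses were validated against a different question schema",
              "kva_validation_error")
  }
  sc <- schema$short_circuit
  if (!is.null(sc) && identical(responses$answers[[sc$question]], sc$response)) {
    return(sc$grade)
  }
  contributions <- "0"
  for (q in schema$questions) {
    a <- responses$answers[[q$id]]
    if (!is.null(a)) contributions <- c(contributions, q$grade_contribution[[a]])
  }
  grade_max(contributions)
}
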