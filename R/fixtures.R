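# Seeded synthetic exam-session generator. Powers property tests and demos
# without external data: sessions are sampled from chart rows (never raw
# reals), so strict parsing and corneal gating always hold by construction.

#' Generator parameters for synthetic exam sessions
#'
#' Defaults describe a mixed toxicity-monitoring population: half of the
#' eyes decline, mostly by 1-4 lines; superficial punctate keratopathy is
#' present in about half of eyes (mild more often than severe); epithelial
#' defects are rare; the three acuity units are used equally often.
#'
#' @param seed integer RNG seed.
#' @param n_sessions number of sessions to generate.
#' @param p_decline probability that an eye's current reading is worse than
#'   baseline.
#' @param decline_line_distribution named probability vector over declines
#'   of \code{"1"}..\code{"10"} lines; must sum to 1.
#' @param p_epithelial_defect probability of a corneal epithelial defect.
#' @param p_spk_by_severity named probability vector over the SPK
#'   responses none/mild/moderate/severe; must sum to 1.
#' @param p_mec probability of microcyst-like epithelial changes.
#' @param p_other probability of another clinically significant finding.
#' @param unit_mix named probability vector over snellen/logmar/decimal;
#'   must sum to 1.
#' @param jitter half-width (in logMAR) of uniform noise added to the raw
#'   acuity strings; 0 keeps every string exactly on-chart, a positive
#'   value exercises the \code{"nearest"} snap policy.
#' @return a \code{kva_generator_params} list.
#' @export
generator_params <- function(seed = 1L, n_sessions = 10L, p_decline = 0.5,
                             decline_line_distribution = c(
                               "1" = 0.35, "2" = 0.25, "3" = 0.15, "4" = 0.10,
                               "5" = 0.06, "6" = 0.04, "7" = 0.02, "8" = 0.01,
                               "9" = 0.01, "10" = 0.01),
                             p_epithelial_defect = 0.05,
                             p_spk_by_severity = c(none = 0.45, mild = 0.30,
                                                   moderate = 0.15, severe = 0.10),
                             p_mec = 0.2, p_other = 0.05,
                             unit_mix = c(snellen = 1, logmar = 1, decimal = 1) / 3,
                             jitter = 0) {
  fail <- function(msg) kva_error(paste0("invalid generator params: ", msg), "kva_config_error")
  probs <- c(p_decline, p_epithelial_defect, p_mec, p_other,
             decline_line_distribution, p_spk_by_severity, unit_mix)
  if (any(probs < 0 | probs > 1)) fail("all probabilities must be in [0, 1]")
  for (nm in c("decline_line_distribution", "p_spk_by_severity", "unit_mix")) {
    v <- get(nm)
    if (abs(sum(v) - 1) > 1e-9) fail(sprintf("%s must sum to 1", nm))
  }
  structure(
    list(seed = as.integer(seed), n_sessions = as.integer(n_sessions),
         p_decline = p_decline,
         decline_line_distribution = decline_line_distribution,
         p_epithelial_defect = p_epithelial_defect,
         p_spk_by_severity = p_spk_by_severity,
         p_mec = p_mec, p_other = p_other,
         unit_mix = unit_mix, jitter = jitter),
    class = "kva_generator_params"
  )
}

.sample_one <- function(p) stats::runif(1) < p
.sample_cat <- function(probs) sample(names(probs), 1L, prob = probs)
# sample one element of a vector (immune to sample()'s scalar-n behavior)
.sample_from <- function(v) v[sample.int(length(v), 1L)]

.sample_corneal <- function(params, schema) {
  answers <- list()
  for (q in schema$questions) {
    if (!.question_enabled(q, answers)) next
    answers[[q$id]] <- switch(q$id,
      clear = if (.sample_one(0.3)) "yes" else "no",
      spk = .sample_cat(params$p_spk_by_severity),
      mec = if (.sample_one(params$p_mec)) "yes" else "no",
      location = sample(q$responses, 1L),
      defect = if (.sample_one(params$p_epithelial_defect)) "yes" else "no",
      other = if (.sample_one(params$p_other)) "yes" else "no",
      sample(q$responses, 1L)  # custom schemas: uniform over the vocabulary
    )
  }
  answers
}

.render_raw <- function(row_logmar, unit, chart, jitter) {
  if (jitter > 0) {
    m <- row_logmar + stats::runif(1, -jitter, jitter)
    return(switch(unit,
      snellen = sprintf("20/%.1f", 20 * 10^m),
      logmar = sprintf("%.3f", m),
      decimal = sprintf("%.4f", 10^(-m))))
  }
  i <- which(abs(chart$logmar - row_logmar) < 1e-9)
  switch(unit,
    snellen = chart$snellen[i],
    logmar = fmt_logmar(chart$logmar[i]),
    decimal = fmt_decimal(chart$decimal[i]))
}

#' Generate synthetic exam sessions
#'
#' Reproducible given the seed. Per eye: with probability
#' \code{p_decline} a decline of d lines is sampled and the baseline is
#' drawn uniformly from the rows that admit a d-line decline; otherwise
#' the current reading is drawn at or better than a uniformly sampled
#' baseline. Corneal answers are sampled question by question and always
#' satisfy the schema's gating predicates. Acuity strings are rendered in
#' the session's sampled unit.
#'
#' @param params a \code{\link{generator_params}}.
#' @param chart the chart to sample rows from.
#' @param schema the corneal question schema.
#' @return a list of \code{kva_session} objects.
#' @export
#' @examples
#' sessions <- generate_sessions(generator_params(seed = 7, n_sessions = 3))
#' run_session(sessions[[1]])$overall_kva
generate_sessions <- function(params = generator_params(),
                              chart = default_chart(),
                              schema = default_schema()) {
  n_rows <- nrow(chart)
  declines <- as.integer(names(params$decline_line_distribution))
  feasible <- declines[params$decline_line_distribution > 0]
  if (any(feasible > n_rows - 1L)) {
    kva_error(sprintf("a %d-line decline is unsatisfiable from every baseline of a %d-row chart",
                      max(feasible), n_rows),
              "kva_config_error")
  }
  set.seed(params$seed)
  lapply(seq_len(params$n_sessions), function(k) {
    unit <- .sample_cat(params$unit_mix)
    eye_pair <- lapply(c(od = "od", os = "os"), function(e) {
      if (.sample_one(params$p_decline)) {
        d <- as.integer(.sample_cat(params$decline_line_distribution))
        b <- .sample_from(0:(n_rows - 1L - d))
        cur <- b + d
      } else {
        b <- .sample_from(0:(n_rows - 1L))
        cur <- .sample_from(0:b)  # same or better
      }
      list(baseline = .render_raw(chart$logmar[b + 1L], unit, chart, params$jitter),
           current = .render_raw(chart$logmar[cur + 1L], unit, chart, params$jitter))
    })
    exam_session(
      patient_label = sprintf("synthetic-%03d", k),
      unit = unit,
      baseline = list(od = eye_pair$od$baseline, os = eye_pair$os$baseline),
      current = list(od = eye_pair$od$current, os = eye_pair$os$current),
      corneal = list(od = .sample_corneal(params, schema),
                     os = .sample_corneal(params, schema)),
      schema_variant = schema$variant,
      chart_name = chart_name(chart)
    )
  })
}
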