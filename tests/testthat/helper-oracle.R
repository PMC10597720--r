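# Independent oracles, written directly from the grading rules and kept
# deliberately separate from the package's implementation paths.

# Shared compiled objects (built once per test run).
shared_chart <- default_chart()
shared_scale <- kva_scale()
shared_lib <- compile_library(shared_chart, shared_scale)
shared_schema <- default_schema("dreamm_kva")

# BCVA-change oracle: straight if/else transcription of the scale semantics
# on 0-based row indices of the default chart (grade-4 cutoff at logMAR 1.0,
# i.e. row index 13).
oracle_bcva <- function(baseline_idx, current_idx, chart = shared_chart) {
  decline <- current_idx - baseline_idx
  if (decline <= 0) return("NA")
  cutoff_idx <- which(abs(chart$logmar - 1.0) < 1e-9) - 1L
  if (current_idx >= cutoff_idx) return("4")
  if (decline == 1) return("1")
  if (decline %in% c(2, 3)) return("2")
  "3"
}

# Corneal-exam oracle: hand-written truth table over the default answers.
oracle_corneal <- function(answers) {
  answers <- as.list(answers)
  if (identical(answers$clear, "yes")) return("0")
  g <- 0L
  g <- max(g, switch(answers$spk, none = 0L, mild = 1L, moderate = 2L, severe = 3L))
  if (identical(answers$defect, "yes")) g <- max(g, 4L)
  as.character(g)
}

# All valid answer combinations of the default dreamm_kva schema: location
# is present exactly when SPK or MECs report a finding.
all_valid_corneal_combos <- function() {
  combos <- list()
  for (spk in c("none", "mild", "moderate", "severe")) {
    for (mec in c("no", "yes")) {
      for (defect in c("no", "yes")) {
        for (other in c("no", "yes")) {
          base <- c(spk = spk, mec = mec, defect = defect, other = other)
          if (spk != "none" || mec == "yes") {
            for (loc in c("peripheral", "paracentral", "central")) {
              combos[[length(combos) + 1L]] <- c(base, location = loc)
            }
          } else {
            combos[[length(combos) + 1L]] <- base
          }
        }
      }
    }
  }
  combos
}

# Acuity values for every default-chart row, one list per unit.
chart_values_by_unit <- function(chart = shared_chart) {
  lapply(c(snellen = "snellen", logmar = "logmar", decimal = "decimal"), function(u) {
    lapply(seq_len(nrow(chart)), function(i) {
      text <- switch(u,
        snellen = chart$snellen[i],
        logmar = format(round(chart$logmar[i], 1), nsmall = 1, trim = TRUE),
        decimal = format(chart$decimal[i], drop0trailing = TRUE, trim = TRUE))
      parse_acuity(text, u, chart, snap = "strict")
    })
  })
}

clean_corneal <- c(spk = "none", mec = "no", defect = "no", other = "no")

worked_example_session <- function() {
  exam_session(
    patient_label = "worked-example",
    unit = "snellen",
    baseline = list(od = "20/20", os = "20/20"),
    current = list(od = "20/25", os = "20/20"),
    corneal = list(od = clean_corneal, os = clean_corneal))
}

# Small 11-row chart (20/20 .. 20/200) loaded from a config file, for
# mixed-chart and config-loading tests.
toy_chart <- local({
  path <- tempfile(fileext = ".yaml")
  logmar <- seq(0, 1, by = 0.1)
  den <- c(20, 25, 32, 40, 50, 63, 80, 100, 125, 160, 200)
  dec <- c(1.0, 0.8, 0.63, 0.5, 0.4, 0.32, 0.25, 0.2, 0.16, 0.125, 0.1)
  rows <- lapply(seq_along(logmar), function(i) {
    list(logmar = logmar[i], snellen = paste0("20/", den[i]), decimal = dec[i])
  })
  yaml::write_yaml(list(name = "toy11", rows = rows), path)
  load_chart(path)
})
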