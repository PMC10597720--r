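test_that("the default exam schema asks exactly five dropdown questions", {
  s <- shared_schema
  expect_length(s$questions, 5)
  expect_equal(s$questions[[1]]$id, "spk")
  expect_equal(s$questions[[1]]$responses, c("none", "mild", "moderate", "severe"))
  expect_equal(unname(s$questions[[1]]$grade_contribution), c("0", "1", "2", "3"))
  defect <- Filter(function(q) q$id == "defect", s$questions)[[1]]
  expect_equal(unname(defect$grade_contribution[["yes"]]), "4")
})

test_that("the clear-cornea variant short-circuits every follow-up to grade 0", {
  s <- default_schema("clear_cornea")
  expect_equal(s$questions[[1]]$id, "clear")
  expect_equal(enabled_questions(s, list(clear = "yes")), "clear")
  r <- validate_responses(c(clear = "yes"), s)
  expect_equal(grade_corneal(r, s), "0")
  # clear = no re-enables the ordinary questionnaire
  expect_true(all(c("spk", "defect") %in% enabled_questions(s, list(clear = "no"))))
  r2 <- validate_responses(c(clear = "no", spk = "severe", mec = "no",
                             location = "central", defect = "no", other = "no"), s)
  expect_equal(grade_corneal(r2, s), "3")
})

test_that("gating accepts possible scenarios and rejects impossible ones", {
  ok <- validate_responses(clean_corneal, shared_schema)
  expect_named(ok$answers, c("spk", "mec", "defect", "other"))  # location disabled
  err <- expect_error(
    validate_responses(c(spk = "none", mec = "no", location = "central",
                         defect = "no", other = "no"), shared_schema),
    class = "kva_validation_error")
  expect_match(conditionMessage(err), "impossible scenario")
  expect_error(validate_responses(c(spk = "mild", mec = "no", defect = "no",
                                    other = "no"), shared_schema),
               class = "kva_validation_error")  # enabled location unanswered
  expect_error(validate_responses(c(spk = "terrible", mec = "no", defect = "no",
                                    other = "no"), shared_schema),
               class = "kva_validation_error")  # vocabulary
  expect_error(validate_responses(c(clean_corneal, haze = "yes"), shared_schema),
               class = "kva_validation_error")  # unknown question
})

test_that("the corneal grade is the most severe contribution", {
  g <- function(a) grade_corneal(validate_responses(a, shared_schema), shared_schema)
  expect_equal(g(clean_corneal), "0")
  expect_equal(g(c(spk = "severe", mec = "no", location = "central",
                   defect = "no", other = "no")), "3")
  expect_equal(g(c(spk = "none", mec = "no", defect = "yes", other = "no")), "4")
  expect_equal(g(c(spk = "mild", mec = "yes", location = "peripheral",
                   defect = "yes", other = "yes")), "4")
})

test_that("grading matches the hand-enumerated truth table on every valid combination", {
  combos <- all_valid_corneal_combos()
  expect_gt(length(combos), 50)
  for (a in combos) {
    r <- validate_responses(a, shared_schema)
    expect_identical(grade_corneal(r, shared_schema), oracle_corneal(a))
  }
})

test_that("upgrading any single answer never lowers the corneal grade", {
  for (a in all_valid_corneal_combos()) {
    base <- grade_severity(grade_corneal(validate_responses(a, shared_schema),
                                         shared_schema))
    for (q in shared_schema$questions) {
      if (!q$id %in% names(a)) next
      vocab <- q$responses
      pos <- match(a[[q$id]], vocab)
      if (pos >= length(vocab)) next
      up <- a
      up[[q$id]] <- vocab[pos + 1L]
      # keep the combination valid if the upgrade enables the location question
      if (!"location" %in% names(up) &&
          "location" %in% enabled_questions(shared_schema, as.list(up))) {
        up <- c(up, location = "central")
      }
      upgraded <- grade_severity(grade_corneal(validate_responses(up, shared_schema),
                                               shared_schema))
      expect_gte(upgraded, base)
    }
  }
})

test_that("responses validated against one schema cannot grade under another", {
  r <- validate_responses(clean_corneal, shared_schema)
  other <- default_schema("clear_cornea")
  expect_error(grade_corneal(r, other), class = "kva_validation_error")
})

test_that("schemas load from config files with gating intact", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    variant = "custom",
    questions = list(
      list(id = "spk", prompt = "SPK?", responses = c("none", "severe"),
           grade_contribution = list(none = "0", severe = "3")),
      list(id = "location", prompt = "Where?", responses = c("peripheral", "central"),
           grade_contribution = list(peripheral = "0", central = "0"),
           enabled_when = list(list(list(question = "spk", op = "ne", value = "none"))))
    )), path)
  s <- load_schema(path)
  expect_length(s$questions, 2)
  expect_equal(enabled_questions(s, list(spk = "none")), "spk")
  r <- validate_responses(c(spk = "severe", location = "central"), s)
  expect_equal(grade_corneal(r, s), "3")
  # forward references are rejected
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(questions = list(
    list(id = "a", prompt = "?", responses = c("x"), grade_contribution = list(x = "0"),
         enabled_when = list(list(list(question = "b", op = "eq", value = "x")))),
    list(id = "b", prompt = "?", responses = c("x"), grade_contribution = list(x = "0"))
  )), bad)
  expect_error(load_schema(bad), class = "kva_config_error")
})
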