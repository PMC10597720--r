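test_that("default chart matches the canonical 24-row geometric progression", {
  ch <- shared_chart
  expect_s3_class(ch, "kva_chart")
  expect_equal(nrow(ch), 24)
  expect_gte(nrow(ch), 21)
  expect_equal(ch$snellen_denominator,
               c(10, 12.5, 16, 20, 25, 32, 40, 50, 63, 80, 100, 125, 160, 200,
                 250, 320, 400, 500, 630, 800, 1000, 1250, 1600, 2000))
  expect_equal(ch$logmar, seq(-0.3, 2.0, by = 0.1))
  # the three representations agree at the anchor rows
  r20 <- ch[abs(ch$logmar - 0) < 1e-9, ]
  expect_equal(r20$snellen, "20/20")
  expect_equal(r20$decimal, 1.0)
  r200 <- ch[abs(ch$logmar - 1) < 1e-9, ]
  expect_equal(r200$snellen, "20/200")
  expect_equal(r200$decimal, 0.1)
  expect_no_error(validate_chart(ch))
})

test_that("listed decimals agree with 20/denominator to about 2 significant figures", {
  ch <- shared_chart
  rel <- abs(20 / ch$snellen_denominator - ch$decimal) / ch$decimal
  expect_true(all(rel < 0.05))
  # conventional listed values, not raw quotients
  expect_equal(ch$decimal[ch$snellen == "20/32"], 0.63)
  expect_equal(ch$decimal[ch$snellen == "20/63"], 0.32)
})

test_that("strict parsing resolves canonical representations in all three units", {
  a <- parse_acuity("20/25", "snellen", shared_chart, "strict")
  expect_equal(a$index, 4L)
  expect_equal(a$logmar, 0.1)
  expect_false(a$snapped)
  b <- parse_acuity("0.0", "logmar", shared_chart, "strict")
  expect_equal(b$snellen, "20/20")
  d <- parse_acuity("0.8", "decimal", shared_chart, "strict")
  expect_equal(d$snellen, "20/25")
  # non-20 numerators are normalized via logMAR: 40/50 == 20/25
  expect_equal(parse_acuity("40/50", "snellen", shared_chart, "strict")$index, 4L)
})

test_that("malformed and off-chart inputs fail with actionable errors", {
  expect_error(parse_acuity("20/abc", "snellen"), class = "kva_parse_error")
  expect_error(parse_acuity("-0.5", "decimal"), class = "kva_parse_error")
  expect_error(parse_acuity("", "logmar"), class = "kva_parse_error")
  err <- expect_error(parse_acuity("20/70", "snellen", shared_chart, "strict"),
                      class = "kva_offchart_error")
  expect_match(conditionMessage(err), "20/63")
  expect_match(conditionMessage(err), "20/80")
})

test_that("nearest snapping picks minimal logMAR distance, ties toward worse vision", {
  a <- parse_acuity("20/70", "snellen", shared_chart, "nearest")
  expect_equal(a$snellen, "20/63")  # |0.544-0.5| < |0.544-0.6|
  expect_true(a$snapped)
  # exactly between two rows: worse row (higher logMAR) wins
  tie <- parse_acuity("0.05", "logmar", shared_chart, "nearest")
  expect_equal(tie$snellen, "20/25")
  # on-chart values are never flagged snapped
  expect_false(parse_acuity("20/25", "snellen", shared_chart, "nearest")$snapped)
})

test_that("nearest snapping is monotone in the raw logMAR", {
  grid <- seq(-0.45, 2.15, by = 0.01)
  idx <- vapply(grid, function(m) {
    parse_acuity(sprintf("%.4f", m), "logmar", shared_chart, "nearest")$index
  }, integer(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("conversion is canonical-row lookup and round-trips over every row and unit pair", {
  vals <- chart_values_by_unit()
  expect_equal(convert_acuity(vals$snellen[[4]], "logmar"), "0.0")
  expect_equal(convert_acuity(vals$snellen[[4]], "decimal"), "1.0")
  expect_equal(convert_acuity(vals$logmar[[14]], "snellen"), "20/200")
  for (u1 in acuity_units) {
    for (u2 in acuity_units) {
      for (i in seq_len(nrow(shared_chart))) {
        reparsed <- parse_acuity(convert_acuity(vals[[u1]][[i]], u2), u2,
                                 shared_chart, "strict")
        expect_equal(reparsed$index, shared_chart$index[i])
      }
    }
  }
})

test_that("line change is the signed row difference, antisymmetric and order-consistent", {
  vals <- chart_values_by_unit()$snellen
  b2020 <- vals[[4]]; c2025 <- vals[[5]]
  expect_equal(line_change(b2020, c2025), 1L)
  expect_equal(line_change(c2025, c2025), 0L)
  expect_equal(line_change(c2025, b2020), -1L)
  for (i in seq_along(vals)) {
    for (j in seq_along(vals)) {
      d <- line_change(vals[[i]], vals[[j]])
      expect_identical(d, -line_change(vals[[j]], vals[[i]]))
      expect_identical(d > 0, vals[[j]]$logmar > vals[[i]]$logmar)
    }
  }
})

test_that("readings from different chart dialects cannot be compared", {
  a <- parse_acuity("20/20", "snellen", shared_chart)
  b <- parse_acuity("20/25", "snellen", toy_chart)
  expect_error(line_change(a, b), class = "kva_mixed_chart_error")
})

test_that("chart config loading validates structural invariants", {
  expect_equal(nrow(toy_chart), 11)
  expect_equal(chart_name(toy_chart), "toy11")
  # a chart missing the 20/200 row is rejected
  bad <- tempfile(fileext = ".yaml")
  rows <- lapply(0:5, function(i) {
    list(logmar = i / 10, snellen = paste0("20/", c(20, 25, 32, 40, 50, 63)[i + 1]),
         decimal = c(1, 0.8, 0.63, 0.5, 0.4, 0.32)[i + 1])
  })
  yaml::write_yaml(list(name = "bad", rows = rows), bad)
  expect_error(load_chart(bad), class = "kva_config_error")
})
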