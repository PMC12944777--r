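test_that("cohort construction validates records and derives prevalence", {
  co <- cohort(data.frame(
    exam_id = c("a", "b", "c"),
    ai_score = c(0.1, 0.5, 0.9),
    recall = c(0, 1, 1),
    cancer = c(0, 0, 1)
  ))
  expect_s3_class(co, "ruleout_cohort")
  expect_equal(n_exams(co), 3)
  expect_equal(prevalence(co), 1 / 3)

  # out-of-range score names the offending row
  expect_error(
    cohort(data.frame(exam_id = "x", ai_score = 1.2, recall = 0, cancer = 0)),
    class = "ruleout_validation_error"
  )
  err <- tryCatch(
    cohort(data.frame(exam_id = c("x", "y"), ai_score = c(0.2, 1.2),
                      recall = 0, cancer = 0)),
    error = identity
  )
  expect_match(conditionMessage(err), "2")

  # cancer_type only on cancer rows
  expect_error(
    cohort(data.frame(exam_id = "x", ai_score = 0.2, recall = 0, cancer = 0,
                      cancer_type = "invasive")),
    class = "ruleout_validation_error"
  )
  # duplicate ids warn by default, error in strict mode
  dup <- data.frame(exam_id = c("a", "a"), ai_score = c(0.1, 0.2),
                    recall = 0, cancer = 0)
  expect_warning(cohort(dup), "duplicated")
  expect_error(cohort(dup, strict = TRUE), class = "ruleout_validation_error")
})

test_that("read_cohort validates input and honours column maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mirai,rec,cx",
               "a,0.1,0,0", "b,0.5,1,0", "c,0.9,1,1"), path)
  expect_error(read_cohort(path), class = "ruleout_config_error")
  co <- read_cohort(path, column_map = c(
    exam_id = "id", ai_score = "mirai", recall = "rec", cancer = "cx"))
  expect_equal(n_exams(co), 3)
  expect_equal(prevalence(co), 1 / 3)
  expect_identical(co$metadata$source, path)

  expect_error(read_cohort(file.path(tempdir(), "nope.csv")),
               class = "ruleout_input_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("exam_id,ai_score,recall,cancer", empty)
  expect_error(read_cohort(empty), class = "ruleout_input_error")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("exam_id,ai_score,recall,cancer", "a,1.2,0,0"), bad)
  expect_error(read_cohort(bad), class = "ruleout_validation_error")
})

test_that("write-then-read is the identity on validated cohorts", {
  co <- simulate_cohort(simulation_config(n = 500, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$records, co$records)
  # and the written file is byte-stable under a re-write
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("filter_cohort checks fields, records provenance, composes", {
  co <- simulate_cohort(simulation_config(n = 2000, seed = 5))
  expect_error(filter_cohort(co, unknown_field > 1),
               class = "ruleout_config_error")
  # empty predicate is the identity
  expect_identical(filter_cohort(co)$records, co$records)

  hi <- filter_cohort(co, ai_score > 0.5)
  expect_true(all(hi$records$ai_score > 0.5))
  expect_lte(n_exams(hi), n_exams(co))
  expect_match(hi$metadata$filters, "ai_score")

  # composition equals conjunction
  both <- filter_cohort(filter_cohort(co, ai_score > 0.3), recall)
  conj <- filter_cohort(co, ai_score > 0.3, recall)
  expect_equal(both$records, conj$records)
})

test_that("predicates excluding all cancers drive every FOR to zero", {
  co <- cohort(data.frame(
    exam_id = sprintf("e%d", 1:10),
    ai_score = seq(0.05, 0.95, by = 0.1),
    recall = c(0, 0, 1, 0, 1, 0, 1, 0, 1, 1),
    cancer = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1)
  ))
  noc <- filter_cohort(co, !cancer)
  expect_equal(prevalence(noc), 0)
  for (t in c(0.1, 0.4, 0.9)) {
    cells <- brute_stratify(noc$records, t)
    expect_equal(cells[["C"]] + cells[["E"]], 0)
    sc <- stratify(noc, t)
    expect_equal(gross_for(sc), 0)
    expect_equal(net_for(sc), 0)
  }
})

test_that("invasive-only mode recodes or drops in-situ cancers", {
  rec <- data.frame(
    exam_id = sprintf("e%d", 1:10),
    ai_score = seq(0.05, 0.95, by = 0.1),
    recall = rep(c(0, 1), 5),
    cancer = c(1, 1, 1, rep(0, 7)),
    cancer_type = c("invasive", "invasive", "in_situ", rep(NA, 7))
  )
  co <- cohort(rec)
  rc <- invasive_only(co, "recode")
  expect_equal(n_exams(rc), 10)
  expect_equal(sum(rc$records$cancer), 2)
  dr <- invasive_only(co, "drop")
  expect_equal(n_exams(dr), 9)
  expect_equal(sum(dr$records$cancer), 2)

  # fail fast when cancer rows lack the label
  rec$cancer_type[1] <- NA
  expect_error(invasive_only(cohort(rec)), class = "ruleout_input_error")
})

test_that("validate_cohort reports per-rule failures without throwing", {
  clean <- simulate_cohort(simulation_config(n = 300, seed = 2))
  rep1 <- validate_cohort(clean)
  expect_true(all(rep1$pass))

  dirty <- data.frame(
    exam_id = c("a", "a", "b"),
    ai_score = c(0.5, 1.4, 0.2),
    recall = c(0, 0, 1),
    cancer = c(0, 0, 0),
    cancer_type = c(NA, NA, "invasive")
  )
  rep2 <- validate_cohort(dirty)
  expect_equal(rep2$n_fail[rep2$rule == "unique_exam_id"], 1L)
  expect_equal(rep2$n_fail[rep2$rule == "score_in_range"], 1L)
  expect_equal(rep2$n_fail[rep2$rule == "cancer_type_on_cancer_only"], 1L)
  expect_false(any(rep2$pass[rep2$n_fail > 0]))
})
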