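test_that("reconstructed pseudo-cohort reproduces every published cell", {
  cells <- ref_cells()
  co <- ref_cohort()
  expect_equal(n_exams(co), 114229)
  expect_equal(sum(co$records$cancer), 864)

  sw <- run_sweep(co, grid = cells$threshold)
  for (col in c("B", "C", "D", "E", "F", "G", "H", "I", "J", "K")) {
    expect_equal(sw[[col]], cells[[col]], info = col)
  }
  expect_equal(sw$N, cells$total)
})

test_that("golden table: printed derived columns recompute on all complete rows", {
  cells <- ref_cells()
  sw <- sweep_from_cells(cells)
  complete <- !is.na(cells$gfor_pct)
  expect_equal(sum(complete), 84)
  printed <- list(
    gfor_pct = sw$g_for, nfor_pct = sw$n_for,
    anfor10_pct = sw$an_for_10, anfor30_pct = sw$an_for_30,
    anfor50_pct = sw$an_for_50, anfor70_pct = sw$an_for_70,
    fdr_pct = sw$fdr, crr_pct = sw$crr
  )
  for (col in names(printed)) {
    expect_equal(round_half_up(100 * printed[[col]][complete]),
                 cells[[col]][complete], info = col)
  }
})

test_that("sweeps are single-threshold-consistent and partition-exact", {
  co <- random_cohort(300, 7)
  grid <- c(0.2, 0.5, 0.8)
  sw <- run_sweep(co, grid, fractions = c(0.3))
  expect_equal(nrow(sw), 3)
  for (i in seq_along(grid)) {
    m <- compute_metrics(stratify(co, grid[i]), fractions = c(0.3))
    expect_equal(sw$crr[i], m$crr)
    expect_equal(sw$g_for[i], m$g_for)
    expect_equal(sw$an_for_30[i], m$an_for_30)
    expect_equal(sw$fdr[i], m$fdr)
  }
  expect_true(all(sw$F + sw$K == n_exams(co)))

  one <- cohort(data.frame(exam_id = "s", ai_score = 0.4, recall = 1, cancer = 0))
  sw1 <- run_sweep(one, grid = c(0.1, 0.5, 0.9))
  expect_true(all(sw1$F + sw1$K == 1))

  expect_error(run_sweep(co, grid = numeric(0)), class = "ruleout_config_error")
  expect_error(run_sweep(co, grid = c(0.5, 0.2)), class = "ruleout_config_error")
})

test_that("ruled-out cells grow and retained cells shrink along any sweep", {
  for (seed in 1:4) {
    co <- random_cohort(500, seed + 100)
    sw <- run_sweep(co, grid = seq(0.05, 0.95, by = 0.05))
    for (col in c("B", "C", "D", "E", "F")) {
      expect_true(all(diff(sw[[col]]) >= 0), info = col)
    }
    for (col in c("G", "H", "I", "J", "K")) {
      expect_true(all(diff(sw[[col]]) <= 0), info = col)
    }
    expect_true(all(diff(sw$crr) >= 0))
  }
})

test_that("Youden selection matches brute-force enumeration", {
  # perfect separation: smallest maximising threshold wins the tie
  sep <- cohort(data.frame(
    exam_id = sprintf("e%d", 1:8),
    ai_score = c(rep(0.1, 5), rep(0.9, 3)),
    recall = 0, cancer = c(rep(0, 5), rep(1, 3))
  ))
  sel <- select_youden(sep)
  expect_equal(sel$threshold, 0.1)
  expect_equal(max(sel$diagnostics$youden_j), 1)

  # interleaved scores against the oracle
  co <- cohort(data.frame(
    exam_id = sprintf("e%d", 1:10),
    ai_score = c(0.05, 0.15, 0.22, 0.31, 0.40, 0.48, 0.55, 0.63, 0.74, 0.88),
    recall = rep(0, 10),
    cancer = c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1)
  ))
  sel <- select_youden(co)
  oracle <- brute_youden(co$records, unique(co$records$ai_score))
  expect_equal(sel$threshold, oracle$threshold)
  expect_equal(max(sel$diagnostics$youden_j), oracle$j)

  # random cohorts, including a grid-restricted mode
  for (seed in 1:3) {
    rco <- random_cohort(150, seed + 50)
    sel <- select_youden(rco)
    oracle <- brute_youden(rco$records, unique(rco$records$ai_score))
    expect_equal(sel$threshold, oracle$threshold)
    grid <- seq(0.1, 0.9, by = 0.1)
    selg <- select_youden(rco, candidates = grid)
    oracleg <- brute_youden(rco$records, grid)
    expect_equal(selg$threshold, oracleg$threshold)
  }

  degenerate <- cohort(data.frame(exam_id = c("a", "b"),
                                  ai_score = c(0.1, 0.9),
                                  recall = 0, cancer = c(1, 1)))
  expect_error(select_youden(degenerate), class = "ruleout_input_error")
})

test_that("the reference grid J profile peaks beside 0.20 and is exposed", {
  sel <- select_youden(ref_cohort(), candidates = ref_cells()$threshold)
  expect_s3_class(sel$diagnostics, "tbl_df")
  expect_equal(nrow(sel$diagnostics), 85)
  # grid-level argmax sits within one step of the full-resolution 0.20 point
  expect_lte(abs(sel$threshold - 0.20), 0.01)
  j20 <- sel$diagnostics$youden_j[sel$diagnostics$threshold == 0.20]
  expect_gt(j20, 0.49)
})

test_that("adjusted-net-zero policy picks the largest qualifying threshold", {
  sw <- sweep_from_cells(ref_cells())
  s30 <- select_anfor_zero(sw, f = 0.30)
  expect_equal(s30$threshold, 0.05)
  s70 <- select_anfor_zero(sw, f = 0.70)
  expect_equal(s70$threshold, 0.09)

  # bracketing: the successor row is strictly above target
  for (sel in list(s30, s70)) {
    succ <- sw[which(sw$threshold == sel$threshold) + 1, ]
    expect_gt((succ$E - sel$f * succ$H) / succ$F, sel$target)
  }

  # no crossing is a flagged result, not an error
  none <- select_anfor_zero(sw, f = 0)
  expect_true(none$no_crossing)
  expect_true(is.na(none$threshold))
})

test_that("biopsy tallies split avoidable from retained work-ups", {
  co <- cohort(data.frame(
    exam_id = sprintf("e%d", 1:6),
    ai_score = c(0.01, 0.1, 0.9, 0.3, 0.02, 0.6),
    recall = c(1, 1, 1, 0, 1, 1),
    cancer = 0,
    biopsy_outcome = c("benign", "benign", "benign", NA, "high_risk", "none")
  ))
  tab <- biopsies_avoided(co, 0.05)
  expect_equal(tab$ruled_out[tab$biopsy_outcome == "benign"], 1)
  expect_equal(tab$retained[tab$biopsy_outcome == "benign"], 2)
  expect_equal(tab$ruled_out[tab$biopsy_outcome == "high_risk"], 1)

  # threshold 1.0 rules everything out
  tab1 <- biopsies_avoided(co, 1.0)
  expect_equal(sum(tab1$retained), 0)
  expect_equal(sum(tab1$ruled_out), 4)

  # missing labels on recalled records fail fast
  bad <- cohort(data.frame(exam_id = "x", ai_score = 0.5, recall = 1, cancer = 0))
  expect_error(biopsies_avoided(bad, 0.5), class = "ruleout_input_error")
})

test_that("avoidable biopsies grow with threshold and match brute tallies", {
  co <- simulate_cohort(simulation_config(n = 5000, seed = 31))
  grid <- seq(0.1, 0.9, by = 0.2)
  avoided <- vapply(grid, function(t) sum(biopsies_avoided(co, t)$ruled_out),
                    numeric(1))
  expect_true(all(diff(avoided) >= 0))
  # enumeration oracle at one threshold
  rec <- co$records
  t <- 0.3
  brute <- sum(!is.na(rec$biopsy_outcome) &
                 rec$biopsy_outcome %in% c("benign", "high_risk") &
                 rec$ai_score <= t)
  expect_equal(sum(biopsies_avoided(co, t)$ruled_out), brute)
})

test_that("sweep writer renders the published layout with blank sentinels", {
  sw <- sweep_from_cells(ref_cells())
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(out), names(ref_cells()))
  # undefined metrics render blank (NA), counts render as zeros
  expect_true(is.na(out$gfor_pct[1]))
  expect_equal(out$F[1], 0)
  # every printed (non-blank) golden value matches
  gold <- ref_cells()
  for (col in setdiff(names(gold), "crr_pct")) {
    has <- !is.na(gold[[col]])
    expect_equal(out[[col]][has], gold[[col]][has], info = col)
  }
  has <- !is.na(gold$crr_pct)
  expect_equal(out$crr_pct[has], gold$crr_pct[has])
})
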