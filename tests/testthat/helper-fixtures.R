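# Shared fixtures and independent oracles.

# Four-record toy used by the stratification examples.
toy_cohort <- function() {
  cohort(data.frame(
    exam_id = c("e1", "e2", "e3", "e4"),
    ai_score = c(0.1, 0.1, 0.9, 0.9),
    recall = c(0, 1, 0, 1),
    cancer = c(0, 1, 1, 0)
  ))
}

# Packaged reference stratification table and its exam-level
# reconstruction, built once per test run.
ref_cells <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- reference_sweep_counts()
    memo
  }
})

ref_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- cohort_from_cells(ref_cells())
    memo
  }
})

# Brute-force stratification oracle: per-record enumeration, no vectorised
# shortcuts shared with the implementation.
brute_stratify <- function(records, threshold) {
  cells <- c(B = 0, C = 0, D = 0, E = 0, G = 0, H = 0, I = 0, J = 0)
  for (i in seq_len(nrow(records))) {
    ruled <- records$ai_score[i] <= threshold
    key <- if (ruled) {
      if (!records$recall[i]) {
        if (!records$cancer[i]) "B" else "C"
      } else {
        if (!records$cancer[i]) "D" else "E"
      }
    } else {
      if (!records$recall[i]) {
        if (!records$cancer[i]) "G" else "H"
      } else {
        if (!records$cancer[i]) "I" else "J"
      }
    }
    cells[key] <- cells[key] + 1
  }
  cells
}

# Brute-force Youden oracle: evaluate J at every candidate by counting.
brute_youden <- function(records, candidates) {
  best_t <- NA_real_
  best_j <- -Inf
  for (t in sort(candidates)) {
    sens <- sum(records$cancer & records$ai_score > t) / sum(records$cancer)
    spec <- sum(!records$cancer & records$ai_score <= t) / sum(!records$cancer)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Random small cohort generator for property-style tests.
random_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    cohort(data.frame(
      exam_id = sprintf("r%05d", seq_len(n)),
      ai_score = round(runif(n), 3),
      recall = runif(n) < 0.2,
      cancer = runif(n) < 0.3
    ))
  })
}
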