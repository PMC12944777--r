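#' Sweep a cohort over a grid of rule-out thresholds
#'
#' Stratifies the cohort at every grid threshold and derives the full
#' metric set per row, producing the in-memory analogue of a published
#' threshold table: cells `B`..`K` plus `N`, then `crr`, `g_for`, `n_for`,
#' the `an_for_<pct>` scenario columns, `fdr`, `ppv`, `npv`,
#' `sensitivity`, `specificity`, `youden_j`.
#'
#' Because rule-out is "score at or below threshold", the ruled-out cells
#' are cumulative: `B`, `C`, `D`, `E`, `F` are non-decreasing along the
#' grid and the retained cells non-increasing. Undefined metrics (empty
#' arm) are carried as `NA`, not errors.
#'
#' @param cohort A [cohort()] object.
#' @param grid Strictly increasing numeric vector of thresholds in
#'   \[0, 1\]. Default `seq(0.01, 0.99, by = 0.01)`.
#' @param fractions Adjusted-net scenario fractions (default
#'   `c(0.1, 0.3, 0.5, 0.7)`).
#' @return A tibble of class `ruleout_sweep`, one row per threshold,
#'   with attributes `fractions` and `n_total`.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n = 2000, seed = 7))
#' sw <- run_sweep(co, grid = seq(0.05, 0.95, by = 0.05))
#' sw[sw$threshold == 0.2, c("threshold", "crr", "g_for", "n_for")]
run_sweep <- function(cohort, grid = seq(0.01, 0.99, by = 0.01),
                      fractions = c(0.1, 0.3, 0.5, 0.7)) {
  check_cohort(cohort)
  check_grid(grid)
  rec <- cohort$records
  cells <- sweep_cells(rec$ai_score, rec$recall, rec$cancer, grid)
  sweep_from_cells(cells, fractions = fractions)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) == 0) {
    stop_config("`grid` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(grid)) || any(grid < 0 | grid > 1)) {
    stop_config("`grid` thresholds must lie in [0, 1].")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_config("`grid` thresholds must be strictly increasing.")
  }
  invisible(grid)
}

# Cumulative cell counts over a threshold grid, one findInterval per
# recall x cancer stratum (O(n log n) total, reused by the bootstrap).
sweep_cells <- function(score, recall, cancer, grid) {
  cum_le <- function(s) {
    if (length(s) == 0) return(rep(0L, length(grid)))
    findInterval(grid, sort(s))
  }
  b <- cum_le(score[!recall & !cancer])
  c_ <- cum_le(score[!recall & cancer])
  d <- cum_le(score[recall & !cancer])
  e <- cum_le(score[recall & cancer])
  tibble(
    threshold = grid,
    B = b, C = c_, D = d, E = e,
    G = sum(!recall & !cancer) - b,
    H = sum(!recall & cancer) - c_,
    I = sum(recall & !cancer) - d,
    J = sum(recall & cancer) - e
  )
}

#' Build a sweep table directly from stratified cell counts
#'
#' Derives the full metric columns from a table of per-threshold cells
#' `B`, `C`, `D`, `E`, `G`, `H`, `I`, `J` (plus `threshold`), e.g. the
#' packaged reference table from [reference_sweep_counts()]. This is how
#' published stratifications are re-analysed without the underlying
#' exam-level data.
#'
#' @param cells Data frame with columns `threshold`, `B`, `C`, `D`, `E`,
#'   `G`, `H`, `I`, `J`; any other columns are ignored.
#' @param fractions Adjusted-net scenario fractions.
#' @return A `ruleout_sweep` tibble (see [run_sweep()]).
#' @export
sweep_from_cells <- function(cells, fractions = c(0.1, 0.3, 0.5, 0.7)) {
  need <- c("threshold", "B", "C", "D", "E", "G", "H", "I", "J")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    stop_config(paste0("`cells` lacks column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  x <- as_tibble(cells)[need]
  if (!is.numeric(fractions) || any(fractions < 0 | fractions > 1)) {
    stop_config("`fractions` must lie in [0, 1].")
  }
  x$F <- x$B + x$C + x$D + x$E
  x$K <- x$G + x$H + x$I + x$J
  x$N <- x$F + x$K
  f_pos <- x$F > 0
  k_pos <- x$K > 0
  na_unless <- function(ok, value) ifelse(ok, value, NA_real_)

  out <- x[c("threshold", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "N")]
  out$crr <- x$F / x$N
  out$g_for <- na_unless(f_pos, (x$C + x$E) / x$F)
  out$n_for <- na_unless(f_pos, x$E / x$F)
  for (f in fractions) {
    out[[anfor_name(f)]] <- na_unless(f_pos, (x$E - f * x$H) / x$F)
  }
  out$fdr <- na_unless(k_pos, (x$G + x$I) / x$K)
  out$ppv <- na_unless(k_pos, (x$H + x$J) / x$K)
  out$npv <- 1 - out$g_for
  pos <- x$C + x$E + x$H + x$J
  neg <- x$B + x$D + x$G + x$I
  out$sensitivity <- na_unless(pos > 0, (x$H + x$J) / pos)
  out$specificity <- na_unless(neg > 0, (x$B + x$D) / neg)
  out$youden_j <- out$sensitivity + out$specificity - 1
  structure(out,
            fractions = fractions,
            n_total = max(x$N),
            class = c("ruleout_sweep", class(out)))
}

#' Packaged reference stratification table
#'
#' Per-threshold stratified counts (cells `B`..`K`, thresholds 0.01-0.85 in
#' steps of 0.01) from a published retrospective screening cohort of
#' 114,229 bilateral 2D digital screening mammograms with 864 confirmed
#' cancers, scored by an open-source 1-year-risk deep-learning model. The
#' printed derived percentage columns (`gfor_pct`, ..., `crr_pct`; 2
#' decimals, blank where the ruled-out arm is empty) are included so the
#' package's own formulas can be audited against them.
#'
#' @return A tibble with the cell columns and the printed percentage
#'   columns.
#' @export
reference_sweep_counts <- function() {
  path <- system.file("extdata", "screening_sweep_counts.csv",
                      package = "ruleout", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reconstruct an exam-level pseudo-cohort from sweep cell counts
#'
#' A table of cumulative ruled-out cells over a threshold grid determines
#' an exam-level cohort up to the exact score values: the increment of
#' each ruled-out cell between consecutive thresholds is realised as that
#' many records with the score placed at the bin's upper threshold, and
#' the final row's retained cells as records above the last threshold.
#' Stratifying the result at any grid threshold reproduces the input
#' cells exactly, which makes published tables usable as exam-level
#' fixtures for the whole pipeline.
#'
#' @param cells Data frame as in [sweep_from_cells()].
#' @param tail_score Score assigned to records retained beyond the final
#'   threshold; must exceed `max(cells$threshold)`.
#' @return A [cohort()] object.
#' @export
cohort_from_cells <- function(cells, tail_score = NULL) {
  need <- c("threshold", "B", "C", "D", "E", "G", "H", "I", "J")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    stop_config(paste0("`cells` lacks column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  x <- as.data.frame(cells)[need]
  check_grid(x$threshold)
  last <- nrow(x)
  if (is.null(tail_score)) {
    tail_score <- min(1, x$threshold[last] + 0.05)
  }
  if (tail_score <= x$threshold[last] || tail_score > 1) {
    stop_config("`tail_score` must exceed the final threshold and stay within [0, 1].")
  }
  inc <- function(col) diff(c(0, x[[col]]))
  incs <- lapply(c("B", "C", "D", "E"), inc)
  names(incs) <- c("B", "C", "D", "E")
  if (any(unlist(incs) < 0)) {
    stop_validation("Ruled-out cells must be non-decreasing in threshold.")
  }
  # totals implied by cumulative structure must match every row's retained cells
  tot <- list(B = x$B[last] + x$G[last], C = x$C[last] + x$H[last],
              D = x$D[last] + x$I[last], E = x$E[last] + x$J[last])
  if (any(x$G != tot$B - x$B | x$H != tot$C - x$C |
            x$I != tot$D - x$D | x$J != tot$E - x$E)) {
    stop_validation("Retained cells are inconsistent with the cumulative ruled-out cells.")
  }

  cell_def <- list(B = c(FALSE, FALSE), C = c(FALSE, TRUE),
                   D = c(TRUE, FALSE), E = c(TRUE, TRUE))
  pieces <- list()
  for (cell in names(cell_def)) {
    n_bin <- incs[[cell]]
    n_tail <- tot[[cell]] - x[[cell]][last]
    pieces[[cell]] <- tibble(
      ai_score = c(rep(x$threshold, n_bin), rep(tail_score, n_tail)),
      recall = cell_def[[cell]][1],
      cancer = cell_def[[cell]][2]
    )
  }
  rec <- dplyr::bind_rows(pieces)
  rec$exam_id <- sprintf("px%07d", seq_len(nrow(rec)))
  cohort(rec, metadata = list(source = "reconstructed from sweep cells",
                              tail_score = tail_score))
}

#' Select a rule-out threshold by Youden's J
#'
#' Classical operating-point selection: maximise
#' `J = sensitivity + specificity - 1` over candidate thresholds. By
#' default the candidates are all distinct observed scores (every
#' achievable operating point of the empirical ROC); pass `candidates` to
#' restrict to a grid. Ties are broken toward the smallest threshold,
#' which rules out the fewest exams.
#'
#' @param cohort A [cohort()] with at least one cancer and one non-cancer.
#' @param candidates Optional numeric vector of candidate thresholds;
#'   default: sorted distinct observed scores.
#' @param fractions Scenario fractions for the achieved metric row.
#' @return A `ruleout_selection` list: `policy`, `threshold`, `metrics`
#'   (one-row tibble), and `diagnostics` (the full J profile as a tibble
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`).
#' @export
select_youden <- function(cohort, candidates = NULL,
                          fractions = c(0.1, 0.3, 0.5, 0.7)) {
  check_cohort(cohort)
  rec <- cohort$records
  n_pos <- sum(rec$cancer)
  n_neg <- sum(!rec$cancer)
  if (n_pos == 0 || n_neg == 0) {
    stop_input("Youden selection needs at least one cancer and one non-cancer exam.")
  }
  if (is.null(candidates)) {
    candidates <- sort(unique(rec$ai_score))
  } else {
    check_grid(candidates)
  }
  pos_sorted <- sort(rec$ai_score[rec$cancer])
  neg_sorted <- sort(rec$ai_score[!rec$cancer])
  ruled_pos <- findInterval(candidates, pos_sorted)
  ruled_neg <- findInterval(candidates, neg_sorted)
  sens <- (n_pos - ruled_pos) / n_pos
  spec <- ruled_neg / n_neg
  j <- sens + spec - 1
  profile <- tibble(threshold = candidates, sensitivity = sens,
                    specificity = spec, youden_j = j)
  best <- which(j == max(j))[1]
  structure(list(
    policy = "youden",
    threshold = candidates[best],
    metrics = compute_metrics(stratify(cohort, candidates[best]), fractions),
    diagnostics = profile
  ), class = "ruleout_selection")
}

#' Select a rule-out threshold by the adjusted-net-zero rule
#'
#' Outcome-based selection: the largest grid threshold whose adjusted net
#' false omission rate at scenario fraction `f` is at or below `target`
#' (default 0). At that operating point the cancers missed by ruling
#' exams out are fully offset by the extra detections assumed among
#' retained exams, so triage introduces no net increase in missed
#' cancers while maximising caseload reduction. If no row qualifies the
#' result is flagged `no_crossing` rather than an error.
#'
#' @param sweep A `ruleout_sweep` from [run_sweep()] or
#'   [sweep_from_cells()].
#' @param f Scenario fraction in \[0, 1\].
#' @param target Acceptable adjusted-net rate (default 0).
#' @return A `ruleout_selection` list: `policy`, `threshold` (`NA` if no
#'   crossing), `f`, `target`, `metrics` (selected sweep row), and
#'   `diagnostics` (selected row and its successor, bracketing the sign
#'   change when both exist).
#' @export
select_anfor_zero <- function(sweep, f, target = 0) {
  if (!inherits(sweep, "ruleout_sweep")) {
    stop_config("`sweep` must be a `ruleout_sweep` (see run_sweep()).")
  }
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1) {
    stop_config("`f` must be a single fraction in [0, 1].")
  }
  value <- ifelse(sweep$F > 0, (sweep$E - f * sweep$H) / sweep$F, NA_real_)
  ok <- which(!is.na(value) & value <= target)
  if (length(ok) == 0) {
    return(structure(list(
      policy = "anfor_zero", threshold = NA_real_, f = f, target = target,
      no_crossing = TRUE, metrics = NULL,
      diagnostics = tibble(threshold = sweep$threshold, an_for = value)
    ), class = "ruleout_selection"))
  }
  idx <- ok[which.max(sweep$threshold[ok])]
  bracket <- sweep[idx:min(idx + 1, nrow(sweep)), , drop = FALSE]
  bracket$an_for_selected <- value[idx:min(idx + 1, nrow(sweep))]
  row <- sweep[idx, , drop = FALSE]
  row[[anfor_name(f)]] <- value[idx]
  structure(list(
    policy = "anfor_zero", threshold = sweep$threshold[idx],
    f = f, target = target, no_crossing = FALSE,
    metrics = row, diagnostics = bracket
  ), class = "ruleout_selection")
}

#' @export
print.ruleout_selection <- function(x, ...) {
  if (isTRUE(x$no_crossing)) {
    cat("<ruleout_selection> policy ", x$policy,
        ": no threshold attains the target\n", sep = "")
    return(invisible(x))
  }
  cat("<ruleout_selection> policy ", x$policy,
      if (!is.null(x$f)) paste0(" (f = ", x$f, ")") else "",
      ": threshold ", format(x$threshold), "\n", sep = "")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  CRR %.2f%%  G-FOR %.2f%%  N-FOR %.2f%%  FDR %.2f%%\n",
                100 * m$crr, 100 * m$g_for, 100 * m$n_for, 100 * m$fdr))
  }
  invisible(x)
}

#' Biopsies avoided and retained at a rule-out threshold
#'
#' Cross-tabulates benign and high-risk biopsy outcomes (which arise from
#' recalled exams) by rule-out arm. Ruled-out counts are biopsies the
#' triage would avoid; retained counts remain in the downstream clinical
#' workflow. Every recalled record must carry a `biopsy_outcome` label
#' (`"none"` for recalls without biopsy).
#'
#' @param cohort A [cohort()] object.
#' @param threshold Rule-out threshold in \[0, 1\].
#' @return A tibble with columns `biopsy_outcome` (`benign`, `high_risk`),
#'   `ruled_out`, `retained`.
#' @export
biopsies_avoided <- function(cohort, threshold) {
  check_cohort(cohort)
  rec <- cohort$records
  unlabelled <- rec$recall & is.na(rec$biopsy_outcome)
  if (any(unlabelled)) {
    stop_input(paste0(
      "biopsies_avoided requires `biopsy_outcome` on every recalled record ",
      "('none' for recalls without biopsy); ", sum(unlabelled),
      " recalled row(s) lack it."
    ))
  }
  out <- rec$ai_score <= threshold
  tally <- function(kind) {
    sel <- !is.na(rec$biopsy_outcome) & rec$biopsy_outcome == kind
    c(ruled_out = sum(sel & out), retained = sum(sel & !out))
  }
  b <- tally("benign")
  h <- tally("high_risk")
  tibble(
    biopsy_outcome = c("benign", "high_risk"),
    ruled_out = c(b[["ruled_out"]], h[["ruled_out"]]),
    retained = c(b[["retained"]], h[["retained"]])
  )
}

#' Write a sweep table to CSV in the published column layout
#'
#' Columns: `threshold`, cells `B`..`K`, `total`, then the derived
#' percentages (`gfor_pct`, `nfor_pct`, one `anfor<pct>_pct` per scenario
#' fraction, `fdr_pct`, `crr_pct`) rounded half-away-from-zero to two
#' decimals, with undefined metrics written as blanks.
#'
#' @param sweep A `ruleout_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  if (!inherits(sweep, "ruleout_sweep")) {
    stop_config("`sweep` must be a `ruleout_sweep`.")
  }
  fractions <- attr(sweep, "fractions")
  out <- tibble(
    threshold = sweep$threshold,
    B = sweep$B, C = sweep$C, D = sweep$D, E = sweep$E, F = sweep$F,
    G = sweep$G, H = sweep$H, I = sweep$I, J = sweep$J, K = sweep$K,
    total = sweep$N,
    gfor_pct = as_pct(sweep$g_for),
    nfor_pct = as_pct(sweep$n_for)
  )
  for (f in fractions) {
    out[[paste0("anfor", formatC(100 * f, format = "fg"), "_pct")]] <-
      as_pct(sweep[[anfor_name(f)]])
  }
  out$fdr_pct <- as_pct(sweep$fdr)
  out$crr_pct <- as_pct(sweep$crr)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
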