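#' Stratified counts at a rule-out threshold
#'
#' The eight-cell stratification that underlies every rule-out metric.
#' An exam is *ruled out* when its AI score is at or below the threshold
#' (ties go to the ruled-out side) and *retained* otherwise; within each
#' arm, exams are split by the radiologist's standard-practice recall and
#' by the cancer outcome:
#'
#' | cell | arm       | recall | cancer |
#' |------|-----------|--------|--------|
#' | B    | ruled out | no     | no     |
#' | C    | ruled out | no     | yes    |
#' | D    | ruled out | yes    | no     |
#' | E    | ruled out | yes    | yes    |
#' | G    | retained  | no     | no     |
#' | H    | retained  | no     | yes    |
#' | I    | retained  | yes    | no     |
#' | J    | retained  | yes    | yes    |
#'
#' with totals `F = B+C+D+E` (ruled out), `K = G+H+I+J` (retained), and
#' `N = F+K`. Cell E holds cancers the triage would drop but the
#' radiologist would have recalled; cell H holds cancers the triage keeps
#' in front of a radiologist who missed them in standard practice — the two
#' cells that drive the net and adjusted-net false omission rates.
#'
#' `stratified_counts()` builds the object directly from cell counts (for
#' published tables); [stratify()] derives it from a cohort.
#'
#' @param threshold Rule-out threshold in \[0, 1\].
#' @param B,C,D,E,G,H,I,J Non-negative integer cell counts as defined above.
#' @return An object of class `ruleout_counts`: a named list with the eight
#'   cells plus `threshold`, `F_total`, `K_total`, `N`.
#' @export
#' @examples
#' sc <- stratified_counts(0.20, B = 79194, C = 82, D = 5803, E = 141,
#'                         G = 24995, H = 66, I = 3373, J = 575)
#' gross_for(sc)
stratified_counts <- function(threshold, B, C, D, E, G, H, I, J) {
  cells <- c(B = B, C = C, D = D, E = E, G = G, H = H, I = I, J = J)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_validation("All cells must be non-negative integers.")
  }
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop_config("`threshold` must be in [0, 1].")
  }
  out <- as.list(cells)
  out$threshold <- threshold
  out$F_total <- B + C + D + E
  out$K_total <- G + H + I + J
  out$N <- out$F_total + out$K_total
  structure(out, class = "ruleout_counts")
}

#' @export
print.ruleout_counts <- function(x, ...) {
  cat(sprintf("<ruleout_counts> threshold %.4g: ruled out %d (B=%d C=%d D=%d E=%d), retained %d (G=%d H=%d I=%d J=%d), N=%d\n",
              x$threshold, x$F_total, x$B, x$C, x$D, x$E,
              x$K_total, x$G, x$H, x$I, x$J, x$N))
  invisible(x)
}

#' Stratify a cohort at a rule-out threshold
#'
#' Assigns every exam to exactly one of the eight cells by
#' (score at-or-below threshold, recall, cancer). Partition identities
#' (`F + K = N`; ruled-out plus retained cancers equal total cancers) are
#' asserted after construction.
#'
#' @param cohort A [cohort()] object.
#' @param threshold Rule-out threshold in \[0, 1\]; scores exactly equal to
#'   it are ruled out.
#' @return A [stratified_counts()] object.
#' @export
stratify <- function(cohort, threshold) {
  check_cohort(cohort)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop_config("`threshold` must be a single value in [0, 1].")
  }
  rec <- cohort$records
  out <- rec$ai_score <= threshold
  cnt <- function(ruled, recall, cancer) {
    sum(out == ruled & rec$recall == recall & rec$cancer == cancer)
  }
  sc <- stratified_counts(
    threshold,
    B = cnt(TRUE, FALSE, FALSE), C = cnt(TRUE, FALSE, TRUE),
    D = cnt(TRUE, TRUE, FALSE),  E = cnt(TRUE, TRUE, TRUE),
    G = cnt(FALSE, FALSE, FALSE), H = cnt(FALSE, FALSE, TRUE),
    I = cnt(FALSE, TRUE, FALSE),  J = cnt(FALSE, TRUE, TRUE)
  )
  stopifnot(sc$N == nrow(rec),
            sc$C + sc$E + sc$H + sc$J == sum(rec$cancer))
  sc
}

check_counts <- function(counts) {
  if (!inherits(counts, "ruleout_counts")) {
    stop_input("Expected a `ruleout_counts` object; see `stratify()`.")
  }
  invisible(counts)
}

#' Caseload reduction rate
#'
#' Fraction of the screening caseload removed from radiologist review by
#' the rule-out: `F / N`.
#'
#' @param counts A [stratified_counts()] object.
#' @return A proportion in \[0, 1\].
#' @export
caseload_reduction_rate <- function(counts) {
  check_counts(counts)
  if (counts$N == 0) stop_input("Empty stratification (N = 0).")
  counts$F_total / counts$N
}

#' Gross false omission rate
#'
#' Probability that a ruled-out exam harbours cancer: `(C + E) / F`, the
#' complement of the rule-out arm's negative predictive value. Undefined
#' (`NA`) when nothing is ruled out.
#'
#' @param counts A [stratified_counts()] object.
#' @return A proportion, or `NA_real_` when `F = 0`.
#' @export
gross_for <- function(counts) {
  check_counts(counts)
  if (counts$F_total == 0) return(NA_real_)
  (counts$C + counts$E) / counts$F_total
}

#' Net false omission rate
#'
#' Gross rate with mutually-missed cancers deducted: only ruled-out cancers
#' that the radiologist *would have recalled* under standard practice count,
#' so the numerator is cell E alone: `E / F`. Undefined when `F = 0`.
#'
#' @inheritParams gross_for
#' @return A proportion, or `NA_real_` when `F = 0`.
#' @export
net_for <- function(counts) {
  check_counts(counts)
  if (counts$F_total == 0) return(NA_real_)
  counts$E / counts$F_total
}

#' Adjusted net false omission rate
#'
#' Net rate credited with the extra detections triage enables on the
#' retained side: under the scenario that radiologists, reading a smaller
#' and higher-prevalence retained pool, catch a fraction `f` of the cancers
#' they missed in standard practice (cell H), the adjusted numerator is
#' `E - f * H`, so the rate `(E - f*H) / F` may be negative — triage then
#' *reduces* total missed cancers relative to standard practice.
#'
#' @inheritParams gross_for
#' @param f Scenario fraction in \[0, 1\] of standard-practice misses that
#'   become detections among retained exams.
#' @return A signed proportion, or `NA_real_` when `F = 0`.
#' @export
adjusted_net_for <- function(counts, f) {
  check_counts(counts)
  if (!is.numeric(f) || any(f < 0 | f > 1)) {
    stop_config("`f` must be in [0, 1].")
  }
  if (counts$F_total == 0) return(NA_real_[rep(1, length(f))])
  (counts$E - f * counts$H) / counts$F_total
}

#' Net number of missed cancers under a scenario
#'
#' The headline count behind [adjusted_net_for()]: `round(E - f * H)`,
#' half away from zero. With `clamp = TRUE` negative balances report as 0
#' (the usual convention for "no additional missed cancers").
#'
#' @inheritParams adjusted_net_for
#' @param clamp If `TRUE`, floor the count at zero.
#' @return An integer count (possibly negative when `clamp = FALSE`).
#' @export
#' @examples
#' sc <- stratified_counts(0.20, B = 79194, C = 82, D = 5803, E = 141,
#'                         G = 24995, H = 66, I = 3373, J = 575)
#' net_missed_count(sc, f = 0.30)  # 121
net_missed_count <- function(counts, f, clamp = FALSE) {
  check_counts(counts)
  x <- round_half_up(counts$E - f * counts$H, 0)
  if (clamp) x <- pmax(x, 0)
  as.integer(x)
}

#' False discovery rate among retained exams
#'
#' Probability that a retained exam does not harbour cancer:
#' `(G + I) / K`, the complement of [ppv()]. Because screening prevalence
#' is well under 1%, this rate stays near 1 at every threshold. Undefined
#' when nothing is retained.
#'
#' @inheritParams gross_for
#' @return A proportion, or `NA_real_` when `K = 0`.
#' @export
fdr <- function(counts) {
  check_counts(counts)
  if (counts$K_total == 0) return(NA_real_)
  (counts$G + counts$I) / counts$K_total
}

#' Positive predictive value among retained exams
#' @inheritParams gross_for
#' @return A proportion, or `NA_real_` when `K = 0`.
#' @export
ppv <- function(counts) {
  check_counts(counts)
  if (counts$K_total == 0) return(NA_real_)
  (counts$H + counts$J) / counts$K_total
}

#' Negative predictive value among ruled-out exams
#' @inheritParams gross_for
#' @return `1 - gross_for(counts)`, or `NA_real_` when `F = 0`.
#' @export
npv <- function(counts) {
  g <- gross_for(counts)
  if (is.na(g)) NA_real_ else 1 - g
}

#' AI-level sensitivity and specificity
#'
#' Treating "retained" as the positive test result: sensitivity is the
#' fraction of cancers retained, `(H + J) / (C + E + H + J)`; specificity
#' is the fraction of non-cancers ruled out, `(B + D) / (B + D + G + I)`.
#' Undefined (`NA`) when the corresponding class is empty.
#'
#' @inheritParams gross_for
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(counts) {
  check_counts(counts)
  pos <- counts$C + counts$E + counts$H + counts$J
  neg <- counts$B + counts$D + counts$G + counts$I
  c(
    sensitivity = if (pos == 0) NA_real_ else (counts$H + counts$J) / pos,
    specificity = if (neg == 0) NA_real_ else (counts$B + counts$D) / neg
  )
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Standard Bayes-theorem forms:
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1 - sp)(1 - p)}, \quad
#'       NPV = \frac{sp (1 - p)}{sp (1 - p) + (1 - se) p}}
#' Applied to count-derived (sensitivity, specificity, prevalence) these
#' reproduce the count-ratio [ppv()] and [npv()] exactly. A 0/0 form
#' returns `NA_real_` for that value.
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\].
#' @return Named numeric vector `c(ppv = , npv = )`.
#' @export
bayes_predictive <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity, specificity, prevalence)
  if (any(!is.finite(args) | args < 0 | args > 1)) {
    stop_config("sensitivity, specificity, prevalence must all be in [0, 1].")
  }
  p_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  n_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  c(
    ppv = if (p_den == 0) NA_real_ else sensitivity * prevalence / p_den,
    npv = if (n_den == 0) NA_real_ else specificity * (1 - prevalence) / n_den
  )
}

#' All rule-out metrics at one threshold
#'
#' One-row summary combining every rate this framework tracks, with the
#' adjusted-net scenarios evaluated at the supplied fractions (default
#' 10/30/50/70%). Undefined metrics (empty arm) are `NA` and stay `NA`
#' through downstream tables.
#'
#' @param counts A [stratified_counts()] object.
#' @param fractions Numeric vector of adjusted-net scenario fractions.
#' @return A one-row tibble with columns `threshold`, `crr`, `g_for`,
#'   `n_for`, one `an_for_<pct>` column per fraction, `fdr`, `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `youden_j`, `prevalence`.
#' @export
compute_metrics <- function(counts, fractions = c(0.1, 0.3, 0.5, 0.7)) {
  check_counts(counts)
  ss <- sensitivity_specificity(counts)
  out <- tibble(
    threshold = counts$threshold,
    crr = caseload_reduction_rate(counts),
    g_for = gross_for(counts),
    n_for = net_for(counts)
  )
  for (f in fractions) {
    out[[anfor_name(f)]] <- adjusted_net_for(counts, f)
  }
  out$fdr <- fdr(counts)
  out$ppv <- ppv(counts)
  out$npv <- npv(counts)
  out$sensitivity <- ss[["sensitivity"]]
  out$specificity <- ss[["specificity"]]
  out$youden_j <- ss[["sensitivity"]] + ss[["specificity"]] - 1
  out$prevalence <- (counts$C + counts$E + counts$H + counts$J) / counts$N
  out
}

# Column name for an adjusted-net scenario fraction: 0.3 -> "an_for_30".
anfor_name <- function(f) {
  paste0("an_for_", formatC(100 * f, format = "fg"))
}
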