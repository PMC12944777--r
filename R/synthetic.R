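#' Configuration for the synthetic screening-cohort simulator
#'
#' The simulator emulates the joint structure a rule-out analysis relies
#' on: a rare cancer outcome, class-separated AI score distributions on
#' \[0, 1\], and radiologist recall behaviour that may be coupled to the
#' AI score. Records are drawn independently (exchangeable exams; no
#' per-patient clustering).
#'
#' Defaults describe a screening-mammography-like population: prevalence
#' 0.76%; Beta score distributions calibrated so that roughly 36% / 75% of
#' non-cancer exams fall at or below scores 0.05 / 0.20 while cancers
#' concentrate at higher scores; a non-cancer recall (false-positive)
#' rate of 8.1%; and a radiologist cancer-detection rate of 82.9%.
#'
#' The optional per-class log-odds slopes couple recall to the score:
#' recall probability is `plogis(qlogis(rate) + slope * (score - m))`
#' with `m` the class mean score, so a positive cancer-class slope makes
#' low-score cancers more likely to be radiologist-missed — the
#' phenomenon that separates gross from net false omission. Slope 0
#' (default) means independence, which is the regime the closed-form
#' [expected_metrics()] covers.
#'
#' @param n Number of exams to draw.
#' @param prevalence Cancer probability per exam.
#' @param shape_noncancer,shape_cancer Length-2 positive Beta shape
#'   parameters for the class score distributions.
#' @param recall_rate_noncancer Recall probability for non-cancer exams.
#' @param detection_rate_cancer Recall (detection) probability for cancer
#'   exams.
#' @param recall_slope_noncancer,recall_slope_cancer Log-odds slopes
#'   linking recall to the score within each class (0 = independent).
#' @param biopsy_rate_benign,biopsy_rate_high_risk Probabilities that a
#'   recalled non-cancer exam leads to a benign / high-risk biopsy
#'   (remainder: no biopsy); recalled cancers are labelled malignant.
#' @param p_invasive Probability a simulated cancer is invasive (vs
#'   in situ).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A validated list of class `ruleout_simconfig`.
#' @export
simulation_config <- function(n = 10000,
                              prevalence = 0.0076,
                              shape_noncancer = c(0.62, 3.78),
                              shape_cancer = c(0.90, 1.05),
                              recall_rate_noncancer = 0.081,
                              detection_rate_cancer = 0.829,
                              recall_slope_noncancer = 0,
                              recall_slope_cancer = 0,
                              biopsy_rate_benign = 0.10,
                              biopsy_rate_high_risk = 0.02,
                              p_invasive = 0.8,
                              seed = NULL) {
  cfg <- list(
    n = n, prevalence = prevalence,
    shape_noncancer = as.numeric(shape_noncancer),
    shape_cancer = as.numeric(shape_cancer),
    recall_rate_noncancer = recall_rate_noncancer,
    detection_rate_cancer = detection_rate_cancer,
    recall_slope_noncancer = recall_slope_noncancer,
    recall_slope_cancer = recall_slope_cancer,
    biopsy_rate_benign = biopsy_rate_benign,
    biopsy_rate_high_risk = biopsy_rate_high_risk,
    p_invasive = p_invasive,
    seed = seed
  )
  probs <- c(prevalence, recall_rate_noncancer, detection_rate_cancer,
             biopsy_rate_benign, biopsy_rate_high_risk, p_invasive)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop_config("`n` must be a positive integer.")
  }
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop_config("All probabilities must lie in [0, 1].")
  }
  if (biopsy_rate_benign + biopsy_rate_high_risk > 1) {
    stop_config("biopsy_rate_benign + biopsy_rate_high_risk must not exceed 1.")
  }
  for (nm in c("shape_noncancer", "shape_cancer")) {
    s <- cfg[[nm]]
    if (length(s) != 2 || any(!is.finite(s) | s <= 0)) {
      stop_config(paste0("`", nm, "` must be two positive Beta shape parameters."))
    }
  }
  structure(cfg, class = "ruleout_simconfig")
}

#' Simulate a synthetic screening cohort
#'
#' Draws `config$n` independent exams: cancer status Bernoulli(prevalence),
#' score from the class Beta distribution, recall Bernoulli with the
#' (optionally score-modulated) class recall probability, plus cancer-type
#' and biopsy-outcome labels. Byte-for-byte reproducible given the seed.
#'
#' @param config A [simulation_config()].
#' @return A [cohort()] whose metadata echoes the configuration.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n = 1000, seed = 42))
#' prevalence(co)
simulate_cohort <- function(config) {
  if (!inherits(config, "ruleout_simconfig")) {
    stop_config("`config` must come from simulation_config().")
  }
  with_private_seed(config$seed, {
    n <- config$n
    cancer <- runif(n) < config$prevalence
    score <- numeric(n)
    score[cancer] <- rbeta(sum(cancer), config$shape_cancer[1], config$shape_cancer[2])
    score[!cancer] <- rbeta(sum(!cancer), config$shape_noncancer[1], config$shape_noncancer[2])

    mean_beta <- function(s) s[1] / (s[1] + s[2])
    p_recall <- ifelse(
      cancer,
      plogis(qlogis(config$detection_rate_cancer) +
               config$recall_slope_cancer * (score - mean_beta(config$shape_cancer))),
      plogis(qlogis(config$recall_rate_noncancer) +
               config$recall_slope_noncancer * (score - mean_beta(config$shape_noncancer)))
    )
    recall <- runif(n) < p_recall

    cancer_type <- rep(NA_character_, n)
    cancer_type[cancer] <- ifelse(runif(sum(cancer)) < config$p_invasive,
                                  "invasive", "in_situ")

    biopsy <- rep(NA_character_, n)
    biopsy[recall & cancer] <- "malignant"
    n_rn <- sum(recall & !cancer)
    if (n_rn > 0) {
      u <- runif(n_rn)
      biopsy[recall & !cancer] <- ifelse(
        u < config$biopsy_rate_benign, "benign",
        ifelse(u < config$biopsy_rate_benign + config$biopsy_rate_high_risk,
               "high_risk", "none"))
    }

    cohort(
      tibble(
        exam_id = sprintf("sim%07d", seq_len(n)),
        ai_score = score, recall = recall, cancer = cancer,
        cancer_type = cancer_type, biopsy_outcome = biopsy
      ),
      metadata = list(source = "simulate_cohort",
                      config = unclass(config), seed = config$seed)
    )
  })
}

#' Closed-form expected metrics for a simulated population
#'
#' Analytic large-sample values of the sweep metrics under a
#' [simulation_config()] with score-independent recall (both slopes 0):
#' sensitivity is the cancer-class upper-tail probability beyond the
#' threshold, specificity the non-cancer-class lower-tail probability,
#' and the FOR family follows from Bayes' theorem with the net rate equal
#' to the gross rate times the radiologist detection probability.
#' Ratio metrics are limits of count ratios (exact as `n` grows).
#'
#' @param config A [simulation_config()] with both recall slopes 0.
#' @param threshold Rule-out threshold(s) in \[0, 1\].
#' @param fractions Adjusted-net scenario fractions.
#' @return A tibble with one row per threshold, in the column layout of
#'   [compute_metrics()].
#' @export
expected_metrics <- function(config, threshold,
                             fractions = c(0.1, 0.3, 0.5, 0.7)) {
  if (!inherits(config, "ruleout_simconfig")) {
    stop_config("`config` must come from simulation_config().")
  }
  if (config$recall_slope_noncancer != 0 || config$recall_slope_cancer != 0) {
    stop_config(
      "expected_metrics has closed forms only for score-independent recall (slopes 0).")
  }
  if (any(threshold < 0 | threshold > 1)) {
    stop_config("`threshold` must lie in [0, 1].")
  }
  p <- config$prevalence
  d <- config$detection_rate_cancer
  sens <- 1 - pbeta(threshold, config$shape_cancer[1], config$shape_cancer[2])
  spec <- pbeta(threshold, config$shape_noncancer[1], config$shape_noncancer[2])
  crr <- p * (1 - sens) + (1 - p) * spec
  na0 <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- tibble(
    threshold = threshold,
    crr = crr,
    g_for = na0(p * (1 - sens), crr),
    n_for = na0(p * (1 - sens) * d, crr)
  )
  for (f in fractions) {
    out[[anfor_name(f)]] <-
      na0(p * (1 - sens) * d - f * p * sens * (1 - d), crr)
  }
  out$fdr <- na0((1 - p) * (1 - spec), 1 - crr)
  out$ppv <- 1 - out$fdr
  out$npv <- 1 - out$g_for
  out$sensitivity <- sens
  out$specificity <- spec
  out$youden_j <- sens + spec - 1
  out$prevalence <- p
  out
}
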