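#' Bootstrap confidence bands for rule-out error curves
#'
#' Nonparametric bootstrap of the whole threshold sweep: exam records are
#' resampled with replacement at cohort size, the sweep is recomputed per
#' replicate, and per (threshold, metric) the band is the percentile
#' interval of the replicate distribution (simple quantiles at
#' `(1 - level)/2` and `1 - (1 - level)/2`, inclusive linear interpolation
#' between order statistics — R quantile type 7 — so bands are
#' bit-reproducible). Replicates where a metric is undefined at a
#' threshold (empty arm) are excluded from that cell's percentiles;
#' `n_defined` reports how many contributed. The resampling unit is the
#' exam record.
#'
#' @param cohort A [cohort()] object.
#' @param grid Threshold grid as in [run_sweep()].
#' @param metrics Character vector of sweep metric names to band:
#'   any of `"g_for"`, `"n_for"`, `"fdr"`, `"crr"`, `"ppv"`, `"npv"`,
#'   or adjusted-net names like `"an_for_30"`.
#' @param replicates Number of bootstrap replicates (>= 2; default 1000).
#' @param level Coverage level in (0, 1) (default 0.95).
#' @param seed Integer seed for the resampling stream; same seed, same
#'   bands. `NULL` uses the current RNG stream.
#' @return A tibble of class `ruleout_bands`, long format: `threshold`,
#'   `metric`, `estimate` (full-cohort value), `lower`, `upper`,
#'   `replicate_sd`, `n_defined`; attributes record `replicates`, `level`,
#'   `seed`, and `method = "percentile"`.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n = 2000, seed = 3))
#' bootstrap_bands(co, grid = c(0.1, 0.2), replicates = 50, seed = 9)
bootstrap_bands <- function(cohort, grid = seq(0.01, 0.99, by = 0.01),
                            metrics = c("g_for", "n_for", "fdr", "crr"),
                            replicates = 1000, level = 0.95, seed = NULL) {
  check_cohort(cohort)
  check_grid(grid)
  if (!is.numeric(replicates) || replicates < 2 || replicates != round(replicates)) {
    stop_config("`replicates` must be an integer >= 2.")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_config("`level` must lie strictly between 0 and 1.")
  }
  anfor_fractions(metrics)  # validates metric names

  rec <- cohort$records
  score <- rec$ai_score
  recall <- rec$recall
  cancer <- rec$cancer
  n <- length(score)

  point <- metric_matrix(sweep_cells(score, recall, cancer, grid), metrics)
  draws <- array(NA_real_,
                 dim = c(replicates, length(grid), length(metrics)))
  with_private_seed(seed, {
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, n, replace = TRUE)
      draws[r, , ] <- metric_matrix(
        sweep_cells(score[idx], recall[idx], cancer[idx], grid), metrics)
    }
  })

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- vector("list", length(grid) * length(metrics))
  k <- 0L
  for (m in seq_along(metrics)) {
    for (g in seq_along(grid)) {
      vals <- draws[, g, m]
      vals <- vals[!is.na(vals)]
      k <- k + 1L
      if (length(vals) == 0) {
        rows[[k]] <- tibble(threshold = grid[g], metric = metrics[m],
                            estimate = unname(point[g, m]), lower = NA_real_,
                            upper = NA_real_, replicate_sd = NA_real_,
                            n_defined = 0L)
      } else {
        q <- quantile(vals, probs = probs, names = FALSE, type = 7)
        rows[[k]] <- tibble(threshold = grid[g], metric = metrics[m],
                            estimate = unname(point[g, m]), lower = q[1],
                            upper = q[2],
                            replicate_sd = stats::sd(vals),
                            n_defined = length(vals))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, replicates = replicates, level = level, seed = seed,
            method = "percentile",
            class = c("ruleout_bands", class(out)))
}

# Parse requested adjusted-net metric names ("an_for_30" -> 0.30).
anfor_fractions <- function(metrics) {
  known <- c("g_for", "n_for", "fdr", "crr", "ppv", "npv")
  an <- grepl("^an_for_", metrics)
  bad <- !an & !metrics %in% known
  if (any(bad)) {
    stop_config(paste0("Unknown metric(s): ",
                       paste(metrics[bad], collapse = ", "), "."))
  }
  f <- as.numeric(sub("^an_for_", "", metrics[an])) / 100
  if (any(is.na(f) | f < 0 | f > 1)) {
    stop_config("Adjusted-net metric names must look like 'an_for_30'.")
  }
  f
}

# Metric values (grid x metrics matrix) straight from cumulative cells,
# lean enough to sit in the bootstrap inner loop.
metric_matrix <- function(cells, metrics) {
  Fv <- cells$B + cells$C + cells$D + cells$E
  Kv <- cells$G + cells$H + cells$I + cells$J
  Nv <- Fv + Kv
  na0 <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  col <- function(name) {
    if (grepl("^an_for_", name)) {
      f <- as.numeric(sub("^an_for_", "", name)) / 100
      return(na0(cells$E - f * cells$H, Fv))
    }
    switch(name,
      crr = Fv / Nv,
      g_for = na0(cells$C + cells$E, Fv),
      n_for = na0(cells$E, Fv),
      fdr = na0(cells$G + cells$I, Kv),
      ppv = na0(cells$H + cells$J, Kv),
      npv = 1 - na0(cells$C + cells$E, Fv)
    )
  }
  out <- vapply(metrics, col, numeric(length(Fv)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, metrics))
  out
}

#' Write bootstrap bands to long-format CSV
#'
#' @param bands A `ruleout_bands` object from [bootstrap_bands()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bands <- function(bands, path) {
  if (!inherits(bands, "ruleout_bands")) {
    stop_config("`bands` must come from bootstrap_bands().")
  }
  readr::write_csv(as_tibble(bands), path, na = "", progress = FALSE)
  invisible(path)
}
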