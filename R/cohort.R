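#' Screening cohort objects
#'
#' A cohort is the unit of analysis for every rule-out computation: one row
#' per screening exam, holding the exam's continuous AI risk score in
#' \[0, 1\], whether the radiologist recalled the exam under standard
#' practice (no triage), and whether cancer was confirmed within the
#' follow-up window. Two optional labels support subgroup analyses:
#' `cancer_type` (`"invasive"` / `"in_situ"`, only on cancer rows) and
#' `biopsy_outcome` (`"benign"` / `"high_risk"` / `"malignant"` / `"none"`).
#'
#' Under this data model a screen-detected cancer is a row with
#' `cancer & recall`, and an interval cancer ("missed by radiology") is a
#' row with `cancer & !recall`.
#'
#' @param records A data frame with columns `exam_id`, `ai_score`, `recall`,
#'   `cancer`, and optionally `cancer_type` and `biopsy_outcome`. `recall`
#'   and `cancer` may be logical or 0/1.
#' @param metadata Named list of free-form provenance (source path, follow-up
#'   window, applied filters, simulation seed, ...).
#' @param strict If `TRUE`, duplicated `exam_id` values are an error instead
#'   of a warning.
#' @return An object of class `ruleout_cohort`: a list with elements
#'   `records` (a tibble) and `metadata` (a list).
#' @export
#' @examples
#' co <- cohort(data.frame(
#'   exam_id = c("a", "b", "c"),
#'   ai_score = c(0.1, 0.5, 0.9),
#'   recall = c(0, 1, 1),
#'   cancer = c(0, 0, 1)
#' ))
#' prevalence(co)
cohort <- function(records, metadata = list(), strict = FALSE) {
  if (!is.data.frame(records)) {
    stop_input("`records` must be a data frame.")
  }
  if (nrow(records) == 0) {
    stop_input("A cohort needs at least one exam record.")
  }
  required <- c("exam_id", "ai_score", "recall", "cancer")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", "), "."
    ))
  }
  rec <- as_tibble(records)
  rec$exam_id <- as.character(rec$exam_id)
  rec$ai_score <- suppressWarnings(as.numeric(rec$ai_score))
  rec$recall <- as_flag(rec$recall, "recall")
  rec$cancer <- as_flag(rec$cancer, "cancer")
  if (!"cancer_type" %in% names(rec)) rec$cancer_type <- NA_character_
  if (!"biopsy_outcome" %in% names(rec)) rec$biopsy_outcome <- NA_character_
  rec$cancer_type <- as.character(rec$cancer_type)
  rec$biopsy_outcome <- as.character(rec$biopsy_outcome)
  rec <- rec[, c("exam_id", "ai_score", "recall", "cancer",
                 "cancer_type", "biopsy_outcome")]

  bad_score <- which(!is.finite(rec$ai_score) | rec$ai_score < 0 | rec$ai_score > 1)
  if (length(bad_score) > 0) {
    stop_validation(paste0(
      "ai_score must be finite and in [0, 1]; offending row(s): ",
      paste(head(bad_score, 20), collapse = ", "),
      if (length(bad_score) > 20) ", ..." else "", "."
    ), rows = bad_score)
  }
  bad_flag <- which(is.na(rec$recall) | is.na(rec$cancer))
  if (length(bad_flag) > 0) {
    stop_validation(paste0(
      "recall and cancer must be non-missing 0/1 flags; offending row(s): ",
      paste(head(bad_flag, 20), collapse = ", "), "."
    ), rows = bad_flag)
  }
  bad_type <- which(!is.na(rec$cancer_type) & !rec$cancer)
  if (length(bad_type) > 0) {
    stop_validation(paste0(
      "cancer_type may only be set on cancer rows; offending row(s): ",
      paste(head(bad_type, 20), collapse = ", "), "."
    ), rows = bad_type)
  }
  bad_enum <- which(!is.na(rec$cancer_type) &
                      !rec$cancer_type %in% c("invasive", "in_situ"))
  if (length(bad_enum) > 0) {
    stop_validation(paste0(
      "cancer_type must be 'invasive' or 'in_situ'; offending row(s): ",
      paste(head(bad_enum, 20), collapse = ", "), "."
    ), rows = bad_enum)
  }
  bad_bx <- which(!is.na(rec$biopsy_outcome) &
                    !rec$biopsy_outcome %in%
                    c("benign", "high_risk", "malignant", "none"))
  if (length(bad_bx) > 0) {
    stop_validation(paste0(
      "biopsy_outcome must be one of benign/high_risk/malignant/none; ",
      "offending row(s): ", paste(head(bad_bx, 20), collapse = ", "), "."
    ), rows = bad_bx)
  }
  dup <- duplicated(rec$exam_id)
  if (any(dup)) {
    msg <- paste0(sum(dup), " duplicated exam_id value(s), e.g. '",
                  rec$exam_id[which(dup)[1]], "'.")
    if (strict) stop_validation(msg) else warn(msg)
  }

  structure(list(records = rec, metadata = metadata),
            class = "ruleout_cohort")
}

as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1) | is.na(x))) return(x == 1)
  if (is.character(x)) {
    lo <- tolower(trimws(x))
    if (all(lo %in% c("0", "1", "true", "false", "yes", "no") | is.na(lo))) {
      out <- rep(NA, length(lo))
      out[lo %in% c("1", "true", "yes")] <- TRUE
      out[lo %in% c("0", "false", "no")] <- FALSE
      return(out)
    }
  }
  stop_validation(paste0("Column '", name, "' is not interpretable as a 0/1 flag."))
}

#' @export
print.ruleout_cohort <- function(x, ...) {
  n <- nrow(x$records)
  k <- sum(x$records$cancer)
  cat("<ruleout_cohort> ", format(n, big.mark = ","), " exams, ",
      format(k, big.mark = ","), " cancers (prevalence ",
      sprintf("%.2f%%", 100 * k / n), "), recall rate ",
      sprintf("%.1f%%", 100 * mean(x$records$recall)), "\n", sep = "")
  invisible(x)
}

#' Number of exams in a cohort
#' @param cohort A [cohort()] object.
#' @return Integer count of exam records.
#' @export
n_exams <- function(cohort) {
  check_cohort(cohort)
  nrow(cohort$records)
}

#' Cancer prevalence of a cohort
#'
#' Derived, never stored: the fraction of exams with a confirmed cancer
#' within the follow-up window.
#'
#' @param cohort A [cohort()] object.
#' @return A proportion in \[0, 1\].
#' @export
prevalence <- function(cohort) {
  check_cohort(cohort)
  mean(cohort$records$cancer)
}

check_cohort <- function(cohort) {
  if (!inherits(cohort, "ruleout_cohort")) {
    stop_input("Expected a `ruleout_cohort` object; see `cohort()` or `read_cohort()`.")
  }
  invisible(cohort)
}

#' Read a screening cohort from CSV
#'
#' Reads an exam-level CSV (UTF-8, '.' decimal) and validates it into a
#' [cohort()]. Column names can be remapped for files whose headers differ
#' from the canonical `exam_id`/`ai_score`/`recall`/`cancer` layout.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional named character vector mapping canonical field
#'   names to the file's column names, e.g.
#'   `c(ai_score = "mirai_1yr", recall = "birads_recall")`.
#' @param strict Passed to [cohort()]: escalate duplicate `exam_id` to error.
#' @return A validated [cohort()] with `metadata$source = path`.
#' @export
read_cohort <- function(path, column_map = NULL, strict = FALSE) {
  if (!file.exists(path)) {
    stop_input(paste0("Input file not found: ", path))
  }
  # read columns as text and coerce in cohort(): base R's numeric parser is
  # correctly rounded, so write -> read round-trips scores bit-exactly
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    stop_input(paste0("Input file has no data rows: ", path))
  }
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop_config("`column_map` must be a named character vector (field = column).")
    }
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0) {
      stop_config(paste0(
        "Mapped column(s) absent from file: ",
        paste(missing_src, collapse = ", "), "."
      ))
    }
    for (field in names(column_map)) {
      df[[field]] <- df[[column_map[[field]]]]
    }
  }
  missing_cols <- setdiff(c("exam_id", "ai_score", "recall", "cancer"), names(df))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", "),
      "; use `column_map` to remap headers."
    ))
  }
  cohort(df, metadata = list(source = path), strict = strict)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] on the canonical column layout: reading the
#' written file back yields a field-for-field identical cohort.
#'
#' @param cohort A [cohort()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  out <- cohort$records
  out$recall <- as.integer(out$recall)
  out$cancer <- as.integer(out$cancer)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Filter a cohort by record-level predicates
#'
#' Keeps the exams matching dplyr-style logical expressions on the record
#' fields. The applied filter is appended to the cohort metadata so derived
#' tables carry their provenance. An empty predicate returns the cohort
#' unchanged.
#'
#' @param cohort A [cohort()] object.
#' @param ... Logical expressions in terms of `exam_id`, `ai_score`,
#'   `recall`, `cancer`, `cancer_type`, `biopsy_outcome`. Referencing any
#'   other name is a configuration error.
#' @return A new [cohort()] (possibly empty predicates return the input).
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n = 500, seed = 1))
#' filter_cohort(co, ai_score > 0.5)
filter_cohort <- function(cohort, ...) {
  check_cohort(cohort)
  quos <- rlang::enquos(...)
  if (length(quos) == 0) return(cohort)
  allowed <- names(cohort$records)
  used <- unique(unlist(lapply(quos, function(q) all.vars(rlang::get_expr(q)))))
  unknown <- setdiff(used, allowed)
  if (length(unknown) > 0) {
    stop_config(paste0(
      "Filter references undefined field(s): ",
      paste(unknown, collapse = ", "), "."
    ))
  }
  rec <- dplyr::filter(cohort$records, !!!quos)
  if (nrow(rec) == 0) {
    stop_input("Filter removed every record; a cohort must keep at least one exam.")
  }
  meta <- cohort$metadata
  meta$filters <- c(meta$filters,
                    vapply(quos, rlang::quo_text, character(1)))
  cohort(rec, metadata = meta)
}

#' Restrict the cancer outcome to invasive cancers
#'
#' Supports invasive-only subanalyses. Two modes:
#' * `"recode"` (default): in-situ cancer rows stay in the cohort but are
#'   relabelled as non-cancer, so the caseload denominator (and hence the
#'   caseload reduction axis) is identical to the all-cancers analysis.
#' * `"drop"`: in-situ cancer rows are removed entirely.
#'
#' Every cancer row must carry a `cancer_type` label; the operation fails
#' fast otherwise.
#'
#' @param cohort A [cohort()] object.
#' @param mode `"recode"` or `"drop"`.
#' @return A new [cohort()] whose cancers are all invasive.
#' @export
invasive_only <- function(cohort, mode = c("recode", "drop")) {
  check_cohort(cohort)
  mode <- match.arg(mode)
  rec <- cohort$records
  unlabelled <- rec$cancer & is.na(rec$cancer_type)
  if (any(unlabelled)) {
    stop_input(paste0(
      "Invasive-only analysis requires `cancer_type` on every cancer row; ",
      sum(unlabelled), " cancer row(s) lack it."
    ))
  }
  in_situ <- rec$cancer & rec$cancer_type == "in_situ"
  if (mode == "recode") {
    rec$cancer[in_situ] <- FALSE
    rec$cancer_type[in_situ] <- NA_character_
  } else {
    rec <- rec[!in_situ, , drop = FALSE]
  }
  meta <- cohort$metadata
  meta$filters <- c(meta$filters, paste0("invasive_only(mode=", mode, ")"))
  cohort(rec, metadata = meta)
}

#' Validation report for cohort-like data
#'
#' Report-only rule checks (never throws): score range and finiteness,
#' label consistency, enum membership, duplicate exam identifiers. Accepts
#' a raw data frame so that files rejected by [cohort()] can still be
#' audited.
#'
#' @param x A [cohort()] or a data frame with the canonical columns.
#' @return A tibble with one row per rule: `rule`, `n_checked`, `n_fail`,
#'   `pass`.
#' @export
validate_cohort <- function(x) {
  rec <- if (inherits(x, "ruleout_cohort")) x$records else as_tibble(x)
  score <- suppressWarnings(as.numeric(rec$ai_score))
  cancer <- as_flag(rec$cancer, "cancer")
  rules <- list(
    score_in_range = !is.finite(score) | score < 0 | score > 1,
    flags_binary = is.na(cancer) | is.na(as_flag(rec$recall, "recall")),
    cancer_type_on_cancer_only =
      if ("cancer_type" %in% names(rec)) !is.na(rec$cancer_type) & !cancer
      else rep(FALSE, nrow(rec)),
    biopsy_outcome_enum =
      if ("biopsy_outcome" %in% names(rec)) {
        !is.na(rec$biopsy_outcome) &
          !rec$biopsy_outcome %in% c("benign", "high_risk", "malignant", "none")
      } else rep(FALSE, nrow(rec)),
    unique_exam_id = duplicated(rec$exam_id)
  )
  tibble(
    rule = names(rules),
    n_checked = nrow(rec),
    n_fail = unname(vapply(rules, sum, integer(1))),
    pass = vapply(rules, function(f) !any(f), logical(1))
  )
}
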