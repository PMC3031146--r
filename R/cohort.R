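# Descriptive case-control comparison of cohort covariates by Fisher's
# exact test, mirroring the classic "Table 1" layout: counts and percentages
# per level with "Missing" reported separately and excluded from testing.

.check_counts <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("counts must be a matrix of non-negative integers",
                 class = "methylwas_input_error")
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided by the probability-mass rule: the p-value sums the
#' hypergeometric probabilities of every margin-fixed table no more probable
#' than the observed one.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `p_value`, `odds_ratio` (conditional MLE).
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(54, 35, 126, 151), 2))  # p ~ 0.015
fisher_exact_2x2 <- function(counts) {
  .check_counts(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    rlang::abort("`counts` must be 2x2", class = "methylwas_input_error")
  }
  ft <- stats::fisher.test(counts)
  tibble::tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
                 method = "exact")
}

#' Fisher's exact test for an r x c table
#'
#' Exact mode enumerates margin-fixed tables (Freeman-Halton definition,
#' network algorithm); Monte Carlo mode samples `n_resamples` margin-fixed
#' tables and reports `(1 + #{prob <= observed}) / (n_resamples + 1)`.
#'
#' @param counts r x c matrix of non-negative integer counts (both
#'   dimensions >= 2).
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param n_resamples Monte Carlo resamples (ignored in exact mode).
#' @param seed Optional seed for Monte Carlo reproducibility.
#' @return One-row tibble: `p_value`, `method`, `n_resamples`.
#' @export
fisher_exact_rxc <- function(counts, mode = c("exact", "monte_carlo"),
                             n_resamples = 10000, seed = NULL) {
  .check_counts(counts)
  if (min(dim(counts)) < 2L) {
    rlang::abort("`counts` must be at least 2x2", class = "methylwas_input_error")
  }
  mode <- match.arg(mode)
  if (mode == "exact") {
    ft <- tryCatch(
      stats::fisher.test(counts, workspace = 2e7),
      error = function(e) {
        rlang::abort(paste0("exact enumeration failed (", conditionMessage(e),
                            "); use mode = 'monte_carlo'"),
                     class = "methylwas_enumeration_error")
      })
    return(tibble::tibble(p_value = ft$p.value, method = "exact",
                          n_resamples = NA_integer_))
  }
  run <- function() stats::fisher.test(counts, simulate.p.value = TRUE,
                                       B = n_resamples)
  ft <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(p_value = ft$p.value, method = "monte_carlo",
                 n_resamples = as.integer(n_resamples))
}

# Table-1 covariate encodings: each entry maps a sample tibble to a factor
# with the study's categories (NA = missing).
.table1_encoders <- list(
  age = function(s) factor(ifelse(s$age_years >= 30, ">=30", "<30"),
                           levels = c("<30", ">=30")),
  race = function(s) factor(s$race,
                            levels = c("caucasian", "african_american", "other")),
  smoker = function(s) factor(ifelse(s$smoker, "yes", "no"), levels = c("no", "yes")),
  alcohol = function(s) factor(ifelse(s$alcohol, "yes", "no"), levels = c("no", "yes")),
  vitamin = function(s) factor(ifelse(s$vitamin_use, "yes", "no"),
                               levels = c("no", "yes")),
  education = function(s) factor(s$education,
                                 levels = c("hs_or_lower", "college_plus")),
  income = function(s) factor(as.character(s$income_bracket),
                              levels = c("1", "2", "3", "4")),
  bmi = function(s) cut(s$bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
                        labels = c("underweight", "normal", "overweight", "obese"),
                        right = FALSE)
)

#' Build a Table-1-style cohort comparison
#'
#' Encodes each covariate into the study's categories (age dichotomized at
#' 30 years, BMI binned at 18.5/25/30, income in 4 brackets), counts cases
#' and controls per level (with a "Missing" row when applicable), and tests
#' the observed-level contingency table with Fisher's exact test. Percentages
#' use the full group denominators (missing included), as printed in the
#' emulated study; the tests use observed counts only.
#'
#' @param samples Sample tibble with `status` plus the covariate columns.
#' @param covariates Subset of age, race, smoker, alcohol, vitamin,
#'   education, income, bmi.
#' @return Tibble: `covariate`, `level`, `case_n`, `case_pct`, `control_n`,
#'   `control_pct`, `p_value` (repeated on each observed level of a
#'   covariate; `NA` on Missing rows and for covariates with fewer than two
#'   observed levels, the latter with a `note`).
#' @export
build_table1 <- function(samples, covariates = names(.table1_encoders)) {
  covariates <- match.arg(covariates, names(.table1_encoders), several.ok = TRUE)
  dat <- samples[samples$status %in% c("case", "control"), , drop = FALSE]
  n_case <- sum(dat$status == "case")
  n_control <- sum(dat$status == "control")
  rows <- list()
  for (cv in covariates) {
    enc <- .table1_encoders[[cv]](dat)
    tab <- table(level = enc, status = factor(dat$status, c("case", "control")))
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = dimnames(tab))
    observed <- counts[rowSums(counts) > 0, , drop = FALSE]
    p <- NA_real_
    note <- NA_character_
    if (nrow(observed) < 2L) {
      note <- "single observed level; no test"
    } else if (nrow(observed) == 2L) {
      p <- fisher_exact_2x2(observed)$p_value
    } else {
      p <- fisher_exact_rxc(observed, mode = "exact")$p_value
    }
    lv_rows <- tibble::tibble(
      covariate = cv, level = rownames(counts),
      case_n = counts[, "case"], case_pct = 100 * counts[, "case"] / n_case,
      control_n = counts[, "control"],
      control_pct = 100 * counts[, "control"] / n_control,
      p_value = ifelse(rowSums(counts) > 0, p, NA_real_),
      note = note
    )
    n_miss_case <- sum(is.na(enc) & dat$status == "case")
    n_miss_control <- sum(is.na(enc) & dat$status == "control")
    if (n_miss_case + n_miss_control > 0) {
      lv_rows <- dplyr::bind_rows(
        tibble::tibble(covariate = cv, level = "Missing",
                       case_n = n_miss_case,
                       case_pct = 100 * n_miss_case / n_case,
                       control_n = n_miss_control,
                       control_pct = 100 * n_miss_control / n_control,
                       p_value = NA_real_, note = NA_character_),
        lv_rows)
    }
    rows[[cv]] <- lv_rows
  }
  dplyr::bind_rows(rows)
}
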