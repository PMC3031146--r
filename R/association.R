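# Per-CpG association testing: OLS on logit-scale methylation with the
# study covariates, a chip-constrained two-stage randomization null,
# empirical p-values, candidate selection, island enrichment and Q-Q data.

#' Design specification for the site-wise regression
#'
#' The default mirrors the emulated study's final model: case/control status
#' plus experimental batch (factor), both bisulfite-conversion efficiency
#' channels, age, BMI, race (factor, reference caucasian) and indicators of
#' vitamin use, alcohol and smoking.
#'
#' @param outcome Outcome term (only `"status"` is supported here; subtype
#'   indicator outcomes can be built by passing indicator columns as the
#'   outcome of a custom design).
#' @param covariates Ordered character vector of covariate column names.
#' @param reference Named list of reference levels for factor covariates.
#' @return A `design_spec` object.
#' @export
design_spec <- function(outcome = "status",
                        covariates = c("batch_id", "bsc_red", "bsc_green",
                                       "age_years", "bmi", "race",
                                       "vitamin_use", "alcohol", "smoker"),
                        reference = list(race = "caucasian")) {
  if (anyDuplicated(c(outcome, covariates))) {
    rlang::abort("duplicated terms in design", class = "methylwas_design_error")
  }
  structure(list(outcome = outcome, covariates = covariates,
                 reference = reference),
            class = "design_spec")
}

#' Build the regression design matrix
#'
#' Restricts to case/control samples, drops samples missing any model
#' covariate (complete-case), expands factors to indicator columns against
#' their reference level, drops single-level factors with a warning, and
#' requires full column rank.
#'
#' @param samples Sample tibble (QC-passing samples).
#' @param spec A [design_spec()].
#' @return A `methyl_design` object: `X` (model matrix), `outcome_column`
#'   (name of the case indicator column), `sample_id`, `status`, `chip`
#'   (chip id per analyzed sample), `df_residual_offset` (`ncol(X)`).
#' @export
build_design <- function(samples, spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  missing_cols <- setdiff(c(spec$outcome, spec$covariates), names(samples))
  if (length(missing_cols)) {
    rlang::abort(paste0("samples lack design column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "methylwas_design_error")
  }
  dat <- samples[samples[[spec$outcome]] %in% c("case", "control"), , drop = FALSE]
  used <- c(spec$outcome, spec$covariates)
  cc <- stats::complete.cases(dat[, used, drop = FALSE])
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) == 0L) {
    rlang::abort("no complete-case samples left for the design",
                 class = "methylwas_design_error")
  }
  dat[[spec$outcome]] <- factor(dat[[spec$outcome]], levels = c("control", "case"))

  keep <- character(0)
  for (v in spec$covariates) {
    x <- dat[[v]]
    if (is.character(x) || is.logical(x) || is.factor(x)) {
      lv <- unique(as.character(x))
      if (length(lv) < 2L) {
        rlang::warn(sprintf("covariate `%s` has a single level; dropped from design", v))
        next
      }
      ref <- spec$reference[[v]]
      levels_order <- if (!is.null(ref) && ref %in% lv) c(ref, sort(setdiff(lv, ref)))
                      else sort(lv)
      dat[[v]] <- factor(as.character(x), levels = levels_order)
    } else if (length(unique(x)) < 2L) {
      rlang::warn(sprintf("covariate `%s` is constant; dropped from design", v))
      next
    }
    keep <- c(keep, v)
  }
  fml <- stats::as.formula(paste("~", paste(c(spec$outcome, keep), collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    offending <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    rlang::abort(paste0("design matrix is rank deficient; offending column(s): ",
                        paste(offending, collapse = ", ")),
                 class = "methylwas_collinearity_error")
  }
  outcome_column <- paste0(spec$outcome, "case")
  structure(list(X = X, outcome_column = outcome_column,
                 sample_id = dat$sample_id, status = as.character(dat[[spec$outcome]]),
                 chip = dat$chip_id, spec = spec),
            class = "methyl_design")
}

#' @export
print.methyl_design <- function(x, ...) {
  cat(sprintf("<methyl_design> %d samples x %d columns (outcome `%s`)\n",
              nrow(x$X), ncol(x$X), x$outcome_column))
  invisible(x)
}

# Core OLS engine: X is n x p (full rank), Y is n x m (one column per probe).
# Returns the estimate, SE and t of column `j_col` of X for every probe.
.ols_t <- function(X, Y, j_col) {
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    rlang::abort("fewer observations than parameters + 2",
                 class = "methylwas_insufficient_data_error")
  }
  qrX <- qr(X)
  coef <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - p
  s2 <- colSums(res^2) / df
  d_jj <- chol2inv(qr.R(qrX))[j_col, j_col]
  # qr in R pivots only when rank deficient; X is validated full rank, but be
  # safe with the pivot anyway
  if (!identical(qrX$pivot, seq_len(p))) {
    piv <- order(qrX$pivot)
    d_jj <- chol2inv(qr.R(qrX))[piv, piv][j_col, j_col]
  }
  est <- coef[j_col, ]
  se <- sqrt(s2 * d_jj)
  t <- est / se
  list(estimate = est, std_error = se, t_statistic = t, df = df)
}

#' Fit the site-wise regressions
#'
#' Ordinary least squares of each probe's M-values on the design; the
#' reported statistic is the case/control coefficient divided by its
#' standard error, with `n - p` residual degrees of freedom.
#'
#' @param m Probes x samples M-value matrix; column names must cover the
#'   design's sample ids.
#' @param design A `methyl_design` from [build_design()].
#' @return Tibble with `probe_id`, `estimate`, `std_error`, `t_statistic`,
#'   `df`, `p_theoretical` (two-sided t-distribution p-value).
#' @export
fit_site_regressions <- function(m, design) {
  stopifnot(is.matrix(m), inherits(design, "methyl_design"))
  if (!all(design$sample_id %in% colnames(m))) {
    rlang::abort("M-value matrix lacks columns for some design samples",
                 class = "methylwas_input_error")
  }
  Y <- t(m[, design$sample_id, drop = FALSE])
  j <- match(design$outcome_column, colnames(design$X))
  fit <- .ols_t(design$X, Y, j)
  tibble::tibble(
    probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    estimate = unname(fit$estimate),
    std_error = unname(fit$std_error),
    t_statistic = unname(fit$t_statistic),
    df = fit$df,
    p_theoretical = 2 * stats::pt(-abs(fit$t_statistic), fit$df)
  )
}

# Deterministic core of the two-stage chip randomization: permute labels
# within the chip, then flip every case/control label when `flip` is TRUE.
.apply_chip_randomization <- function(status, perm, flip) {
  s <- status[perm]
  if (flip) {
    flipped <- s
    flipped[s == "case"] <- "control"
    flipped[s == "control"] <- "case"
    s <- flipped
  }
  s
}

#' Chip-constrained two-stage status randomization
#'
#' Stage 1 permutes the observed case/control labels independently within
#' each chip; stage 2 flips every label on a chip (case <-> control) with
#' probability 1/2, independently per chip. Each subject is therefore
#' equally likely to be labelled case or control in a pseudo-dataset, while
#' the chip structure of the design - and with it any chip-driven spurious
#' association - is retained. Reproducible from `(seed, draw)`.
#'
#' @param status Character vector of `"case"`/`"control"` labels.
#' @param chip Chip id per subject (same length as `status`).
#' @param seed Integer seed of the randomization plan.
#' @param draw Draw index (1-based).
#' @return Permuted status vector.
#' @export
randomize_status <- function(status, chip, seed, draw = 1L) {
  stopifnot(length(status) == length(chip))
  draw_seed <- as.integer((as.numeric(seed) + 48271 * as.numeric(draw)) %% 2147483647)
  withr::with_seed(draw_seed, {
    out <- status
    for (cp in unique(chip)) {
      idx <- which(chip == cp)
      perm <- if (length(idx) > 1L) sample.int(length(idx)) else 1L
      flip <- stats::runif(1L) < 0.5
      out[idx] <- .apply_chip_randomization(status[idx], perm, flip)
    }
    out
  })
}

#' Empirical p-values from randomization null draws
#'
#' Two-sided with the +1 correction:
#' `p = (1 + #draws with |t*| >= |t_obs|) / (R + 1)`, so p is never zero and
#' ties count as extreme. By default each probe is compared against its own
#' null draws; with `pooled = TRUE` every probe is compared against the
#' pooled draws of all probes.
#'
#' @param t_obs Numeric vector of observed t-statistics (one per probe).
#' @param null_t R x m matrix of null t-statistics (draws in rows, probes in
#'   columns, column order matching `t_obs`).
#' @param pooled Pool null draws across probes?
#' @return Numeric vector of empirical p-values in `[1/(R+1), 1]`.
#' @export
empirical_pvalues <- function(t_obs, null_t, pooled = FALSE) {
  if (is.null(dim(null_t))) null_t <- matrix(null_t, ncol = length(t_obs))
  R <- nrow(null_t)
  if (is.null(R) || R < 1L) {
    rlang::abort("at least one randomization draw is required",
                 class = "methylwas_plan_error")
  }
  if (ncol(null_t) != length(t_obs)) {
    rlang::abort("`null_t` must have one column per observed statistic",
                 class = "methylwas_input_error")
  }
  a_obs <- abs(t_obs)
  a_null <- abs(null_t)
  if (pooled) {
    st <- sort(as.numeric(a_null))
    cnt <- length(st) - findInterval(a_obs, st, left.open = TRUE)
    (1 + cnt) / (length(st) + 1)
  } else {
    cnt <- colSums(sweep(a_null, 2L, a_obs, ">=") * 1L)
    (1 + cnt) / (R + 1)
  }
}

#' Run the chip-constrained randomization null
#'
#' Refits the site-wise regressions for `R` pseudo-datasets in which status
#' is randomized by [randomize_status()] (all covariates unchanged) and
#' converts the observed t-statistics to empirical p-values.
#'
#' @inheritParams fit_site_regressions
#' @param R Number of randomization draws.
#' @param seed Integer seed.
#' @param pooled Pool null draws across probes (see [empirical_pvalues()]).
#' @param keep_null Keep the full R x m null t matrix (memory permitting)?
#' @return A list: `fit` (observed per-probe tibble), `p_empirical`,
#'   `null_quantiles` (pooled |t*| quantiles), `null_t` (if kept), `R`,
#'   `seed`.
#' @export
run_randomization_null <- function(m, design, R = 999, seed = 1,
                                   pooled = FALSE, keep_null = FALSE) {
  if (R < 1L) {
    rlang::abort("`R` must be >= 1", class = "methylwas_plan_error")
  }
  fit <- fit_site_regressions(m, design)
  Y <- t(m[, design$sample_id, drop = FALSE])
  X <- design$X
  j <- match(design$outcome_column, colnames(X))
  a_obs <- abs(fit$t_statistic)
  n_probe <- length(a_obs)
  cnt <- integer(n_probe)
  pooled_cnt <- integer(n_probe)
  abs_sorted_all <- NULL
  null_t <- if (keep_null) matrix(NA_real_, R, n_probe) else NULL
  null_abs_sample <- numeric(0)
  for (r in seq_len(R)) {
    st_r <- randomize_status(design$status, design$chip, seed, r)
    X[, j] <- as.numeric(st_r == "case")
    t_r <- .ols_t(X, Y, j)$t_statistic
    a_r <- abs(t_r)
    cnt <- cnt + (a_r >= a_obs)
    if (pooled) {
      s <- sort(a_r)
      pooled_cnt <- pooled_cnt + (n_probe - findInterval(a_obs, s, left.open = TRUE))
    }
    if (keep_null) null_t[r, ] <- t_r
    if (r <= max(1L, ceiling(200L / n_probe)) || keep_null) {
      null_abs_sample <- c(null_abs_sample, a_r)
    }
  }
  p_emp <- if (pooled) {
    (1 + pooled_cnt) / (as.numeric(R) * n_probe + 1)
  } else {
    (1 + cnt) / (R + 1)
  }
  qs <- if (keep_null) {
    stats::quantile(abs(null_t), c(0.5, 0.9, 0.95, 0.975, 0.99))
  } else {
    stats::quantile(null_abs_sample, c(0.5, 0.9, 0.95, 0.975, 0.99))
  }
  list(fit = fit, p_empirical = p_emp, null_quantiles = qs,
       null_t = null_t, R = R, seed = seed, pooled = pooled)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the grid
#' `lambda = 0, 0.05, ..., 0.90` as `#{p > lambda} / (m (1 - lambda))`,
#' smooths the estimates with a cubic smoothing spline (df = 3) and takes
#' the value at the largest lambda (clamped into (0, 1]); q-values are the
#' step-up minima `q_(i) = min_{j >= i} pi0 m p_(j) / j`. With `pi0 = 1`
#' this reduces exactly to the Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param lambda Tuning grid for the pi0 estimator.
#' @param pi0 Optional fixed pi0 (overrides estimation).
#' @return Numeric vector of q-values with attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    rlang::abort("p-values must lie in (0, 1]", class = "methylwas_input_error")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p, decreasing = TRUE)
  i <- m:1L
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * (m / i) * p[o]))
  attr(q, "pi0") <- pi0
  q
}

#' Estimate the null proportion pi0
#'
#' @inheritParams storey_qvalues
#' @param df Degrees of freedom of the smoothing spline.
#' @return Scalar pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0, 0.90, by = 0.05), df = 3) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    rlang::abort("p-values must lie in (0, 1]", class = "methylwas_input_error")
  }
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = df)
  min(max(stats::predict(fit, x = max(lambda))$y, .Machine$double.eps), 1)
}

#' Select candidate differentially methylated sites
#'
#' Keeps probes with empirical p strictly below the threshold, sorted by
#' ascending p, with direction (+ hypermethylated in cases) from the sign of
#' the estimate.
#'
#' @param results Per-probe results tibble (must contain `p_empirical` and
#'   `estimate`; annotation columns are carried through).
#' @param p_threshold Strict upper bound on empirical p (default 0.005).
#' @return Candidate tibble sorted by `p_empirical`, with a `direction`
#'   column and attributes `n_candidates`, `n_island` (if island flags are
#'   present) and `n_hyper`.
#' @export
select_candidates <- function(results, p_threshold = 0.005) {
  out <- results |>
    dplyr::filter(.data$p_empirical < p_threshold) |>
    dplyr::arrange(.data$p_empirical) |>
    dplyr::mutate(direction = ifelse(.data$estimate > 0, "+", "-"))
  attr(out, "n_candidates") <- nrow(out)
  attr(out, "n_hyper") <- sum(out$direction == "+")
  if ("cpg_island" %in% names(out)) {
    attr(out, "n_island") <- sum(out$cpg_island)
  }
  out
}

#' CpG-island enrichment of the candidate set
#'
#' Two-sided exact binomial test of the number of island candidates against
#' the array's island background fraction.
#'
#' @param x Candidate tibble with a logical `cpg_island` column, or the
#'   island count (scalar).
#' @param n Number of candidates (only when `x` is a count).
#' @param background_fraction Array-wide island fraction (default 0.76).
#' @return One-row tibble: `n_island`, `n_candidates`, `fraction`,
#'   `background_fraction`, `p_value`.
#' @export
island_enrichment <- function(x, n = NULL, background_fraction = 0.76) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) {
      rlang::abort("island enrichment is undefined for an empty candidate set",
                   class = "methylwas_undefined_test_error")
    }
    k <- sum(x$cpg_island)
    n <- nrow(x)
  } else {
    k <- x
    if (is.null(n) || n < 1L) {
      rlang::abort("island enrichment is undefined for an empty candidate set",
                   class = "methylwas_undefined_test_error")
    }
  }
  bt <- stats::binom.test(k, n, p = background_fraction)
  tibble::tibble(n_island = as.integer(k), n_candidates = as.integer(n),
                 fraction = k / n, background_fraction = background_fraction,
                 p_value = bt$p.value)
}

#' Observed-vs-expected quantiles of -log10(p)
#'
#' @param p Non-empty vector of p-values.
#' @return Tibble with `expected` (`-log10((i - 0.5)/m)`) and `observed`
#'   (sorted `-log10(p)`), both in order of decreasing significance.
#' @export
qq_data <- function(p) {
  if (!length(p)) {
    rlang::abort("`p` must be non-empty", class = "methylwas_input_error")
  }
  m <- length(p)
  i <- seq_len(m)
  tibble::tibble(expected = -log10((i - 0.5) / m),
                 observed = -log10(sort(p)))
}

#' Full association analysis of an M-value matrix
#'
#' Builds the design, fits the site-wise regressions, runs the
#' chip-constrained randomization null, computes Storey q-values on the
#' empirical p-values, and annotates results with the manifest.
#'
#' @inheritParams run_randomization_null
#' @param samples QC-passing sample tibble.
#' @param manifest Probe annotation tibble (`probe_id`, `gene_symbol`,
#'   `chromosome`, `cpg_island`, ...).
#' @param spec A [design_spec()].
#' @param p_threshold Candidate threshold passed to [select_candidates()].
#' @return A `methyl_ewas` object; see [tidy.methyl_ewas()] and
#'   [glance.methyl_ewas()].
#' @export
run_association <- function(m, samples, manifest = NULL, spec = design_spec(),
                            R = 999, seed = 1, p_threshold = 0.005,
                            pooled = FALSE, keep_null = FALSE) {
  # restrict to samples that survived QC (columns of the M-value matrix)
  samples <- samples[samples$sample_id %in% colnames(m), , drop = FALSE]
  design <- build_design(samples, spec)
  null <- run_randomization_null(m, design, R = R, seed = seed,
                                 pooled = pooled, keep_null = keep_null)
  q <- storey_qvalues(null$p_empirical)
  pi0 <- attr(q, "pi0")
  results <- null$fit |>
    dplyr::mutate(p_empirical = null$p_empirical,
                  q_value = as.numeric(q),
                  direction = ifelse(.data$estimate > 0, "+", "-"))
  if (!is.null(manifest)) {
    results <- dplyr::left_join(
      results,
      manifest[, intersect(c("probe_id", "gene_symbol", "chromosome",
                             "cpg_island", "mirna_tags", "imprinted"),
                           names(manifest))],
      by = "probe_id")
  }
  candidates <- select_candidates(results, p_threshold)
  structure(list(
    results = results, candidates = candidates,
    qq = qq_data(results$p_empirical),
    pi0 = pi0, null_quantiles = null$null_quantiles, null_t = null$null_t,
    R = R, seed = seed, p_threshold = p_threshold, pooled = pooled,
    n_samples = nrow(design$X), n_probes = nrow(results),
    design = design
  ), class = "methyl_ewas")
}

#' @export
print.methyl_ewas <- function(x, ...) {
  cat(sprintf(paste0(
    "<methyl_ewas> %d probes x %d analyzed samples, R = %d randomizations\n",
    "  pi0 = %.3f; %d candidate site(s) at p < %g\n"),
    x$n_probes, x$n_samples, x$R, x$pi0, nrow(x$candidates), x$p_threshold))
  invisible(x)
}
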