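# PCA of the M-value matrix and the PC-vs-factor screen used to choose
# model covariates.

#' Principal component analysis of M-values
#'
#' Samples are observations and probes variables; variables are centered but
#' not scaled (M-values share a scale). Component signs are fixed by making
#' each component's largest-magnitude loading positive, so results are
#' deterministic.
#'
#' @param m Complete probes x samples M-value matrix (post-imputation).
#' @param n_components Number of components to keep (default 20).
#' @return A `methyl_pca` object: `scores` (samples x components),
#'   `variance_explained` (per kept component, as a share of total variance),
#'   `n_components`, `total_variance`.
#' @export
run_pca <- function(m, n_components = 20) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) {
    rlang::abort("PCA requires a complete matrix; impute first",
                 class = "methylwas_input_error")
  }
  x <- t(m)
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(x))) {
    rlang::abort(sprintf("`n_components` must be in [1, %d]", min(dim(x))),
                 class = "methylwas_parameter_error")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(min(k, ncol(pr$rotation)))) {
    l <- pr$rotation[, j]
    if (l[which.max(abs(l))] < 0) {
      pr$rotation[, j] <- -l
      pr$x[, j] <- -pr$x[, j]
    }
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  ve <- if (total_var > 0) pr$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  structure(list(scores = scores,
                 variance_explained = ve,
                 n_components = k,
                 total_variance = total_var),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  cat(sprintf("<methyl_pca> %d samples, %d components explaining %.1f%% of variance\n",
              nrow(x$scores), x$n_components, 100 * sum(x$variance_explained)))
  invisible(x)
}

#' Screen principal components against experimental and phenotype factors
#'
#' Each kept PC is regressed on each factor singly: simple linear regression
#' for continuous factors, one-way ANOVA F-test for categorical ones, with
#' complete-case handling per factor. The screen is exploratory (it informs
#' covariate choice), so no multiplicity correction is applied.
#'
#' @param pca A `methyl_pca` object.
#' @param samples Sample tibble; rows must match the score rows (matched by
#'   `sample_id` against the score rownames when present).
#' @param factors Column names of `samples` to screen (default: status,
#'   chip, batch, BSC channels, and lifestyle covariates present in the
#'   tibble).
#' @return Tibble with one row per (component, factor): `component`,
#'   `factor`, `n_used`, `statistic` (F), `p_value`. Factors with fewer than
#'   two observed levels are skipped with a warning.
#' @export
screen_pcs <- function(pca, samples,
                       factors = intersect(
                         c("status", "batch_id", "chip_id", "bsc_red",
                           "bsc_green", "age_years", "race", "bmi", "smoker",
                           "alcohol", "vitamin_use"),
                         names(samples))) {
  stopifnot(inherits(pca, "methyl_pca"))
  scores <- pca$scores
  if (!is.null(rownames(scores)) && "sample_id" %in% names(samples)) {
    idx <- match(rownames(scores), samples$sample_id)
    if (anyNA(idx)) {
      rlang::abort("score rownames contain sample ids absent from `samples`",
                   class = "methylwas_input_error")
    }
    samples <- samples[idx, ]
  } else if (nrow(samples) != nrow(scores)) {
    rlang::abort("`samples` rows must match PCA scores",
                 class = "methylwas_input_error")
  }
  rows <- list()
  for (f in factors) {
    x <- samples[[f]]
    ok <- !is.na(x)
    if (is.character(x) || is.logical(x) || is.factor(x)) {
      xf <- factor(x[ok])
      if (nlevels(xf) < 2L) {
        rlang::warn(sprintf("factor `%s` has a single observed level; skipped", f))
        next
      }
      xx <- xf
    } else {
      if (length(unique(x[ok])) < 2L) {
        rlang::warn(sprintf("factor `%s` is constant; skipped", f))
        next
      }
      xx <- x[ok]
    }
    for (j in seq_len(pca$n_components)) {
      fit <- stats::lm(scores[ok, j] ~ xx)
      a <- stats::anova(fit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        component = colnames(scores)[j] %||% paste0("PC", j),
        factor = f, n_used = sum(ok),
        statistic = a$`F value`[1L], p_value = a$`Pr(>F)`[1L]
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(component = character(0), factor = character(0),
                          n_used = integer(0), statistic = numeric(0),
                          p_value = numeric(0)))
  }
  dplyr::bind_rows(rows)
}
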