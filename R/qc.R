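# Raw signal -> beta-value conversion, detection p-values, sample- and
# probe-level quality control, logit (M-value) transform and kNN imputation.

#' Compute beta-values from raw signals
#'
#' For each sample the background is estimated as the mean of that sample's
#' negative-control intensities and subtracted from both channels (negative
#' results clamped to zero). The beta-value is the methylated share of the
#' total corrected signal, `beta = M' / (M' + U')`, missing when the
#' corrected total is zero. When `mask = TRUE` (default), entries whose
#' detection p-value does not reach `detection_alpha` are also set missing.
#'
#' @param signals A `methyl_signals` object.
#' @param detection_alpha Detection significance cutoff; an entry is called
#'   only when its detection p-value is below this value.
#' @param mask If `FALSE`, skip detection masking (no detection p-values are
#'   computed; useful for noise-free reconstructions).
#' @return A `beta_matrix` object: list with `beta` (probes x samples, values
#'   in `[0,1]` or `NA`) and `detection_p` (same shape; `NA` if `mask=FALSE`).
#' @export
#' @examples
#' sig <- methyl_signals(matrix(3000, 1, 1), matrix(1000, 1, 1),
#'                       matrix(c(190, 210), 2, 1))
#' compute_beta(sig, mask = FALSE)$beta  # 2800/3600
compute_beta <- function(signals, detection_alpha = 0.05, mask = TRUE) {
  stopifnot(inherits(signals, "methyl_signals"))
  M <- signals$methylated
  U <- signals$unmethylated
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) ||
      any(signals$negative_controls < 0, na.rm = TRUE)) {
    rlang::abort("raw intensities must be non-negative",
                 class = "methylwas_input_error")
  }
  bg <- colMeans(signals$negative_controls)
  Mc <- pmax(sweep(M, 2L, bg), 0)
  Uc <- pmax(sweep(U, 2L, bg), 0)
  denom <- Mc + Uc
  beta <- Mc / denom
  beta[denom <= 0] <- NA_real_
  detection_p <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  if (mask) {
    detection_p <- detection_pvalues(signals)
    beta[!(detection_p < detection_alpha)] <- NA_real_
  }
  structure(list(beta = beta, detection_p = detection_p,
                 detection_alpha = if (mask) detection_alpha else NA_real_),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %.2f%% missing\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' Detection p-values against negative controls
#'
#' Per sample, the negative-control intensities define a Normal background
#' distribution with mean `mu_s` and standard deviation `sigma_s`; the
#' detection p-value of a probe is the upper-tail probability of that Normal
#' at the probe's total signal `M + U`. Small p-values mean the probe's
#' signal is clearly above background.
#'
#' @param signals A `methyl_signals` object with at least two negative
#'   controls per sample.
#' @return Probes x samples matrix of p-values in `[0, 1]`.
#' @export
detection_pvalues <- function(signals) {
  stopifnot(inherits(signals, "methyl_signals"))
  nc <- signals$negative_controls
  if (nrow(nc) < 2L) {
    rlang::abort("at least 2 negative controls per sample are required",
                 class = "methylwas_input_error")
  }
  mu <- colMeans(nc)
  sigma <- apply(nc, 2L, stats::sd)
  if (any(sigma <= 0)) {
    rlang::abort("negative controls have zero variance for at least one sample",
                 class = "methylwas_degenerate_controls_error")
  }
  total <- signals$methylated + signals$unmethylated
  z <- sweep(sweep(total, 2L, mu), 2L, sigma, "/")
  p <- stats::pnorm(z, lower.tail = FALSE)
  dimnames(p) <- dimnames(total)
  p
}

#' Minimum called sites for a given call rate
#'
#' @param n_probes Number of probes on the array.
#' @param call_rate Required proportion of called sites (default 0.95).
#' @return Integer floor: the smallest number of called sites that satisfies
#'   the call rate, `ceiling(call_rate * n_probes)`.
#' @export
call_rate_floor <- function(n_probes, call_rate = 0.95) {
  as.integer(ceiling(call_rate * n_probes))
}

#' Sample-level quality control
#'
#' A sample passes when (a) its number of called (non-missing) sites reaches
#' the call-rate floor, (b) its background level (mean negative-control
#' intensity) is strictly below `max_background`, and (c) the separation
#' between its probe signals and its background,
#' `(mean(M+U) - mean(controls)) / pooled SD`, exceeds `min_separation`
#' (a quantified stand-in for "clear separation in the non-polymorphic
#' controls"; see the methods vignette).
#'
#' @param bm A `beta_matrix` from [compute_beta()].
#' @param signals The `methyl_signals` the betas were computed from.
#' @param call_rate Required call rate (default 0.95).
#' @param max_background Background ceiling in intensity units (default 1000,
#'   strict inequality).
#' @param min_separation Minimum signal/background separation (default 5).
#' @return A list with `samples` (character vector of passing sample ids) and
#'   `report` (per-sample tibble: `sample_id`, `called`, `call_rate`,
#'   `background_level`, `nonpoly_separation`, `pass`, `reasons`).
#' @export
filter_samples <- function(bm, signals, call_rate = 0.95,
                           max_background = 1000, min_separation = 5) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(signals, "methyl_signals"))
  beta <- bm$beta
  n_probes <- nrow(beta)
  floor_n <- call_rate_floor(n_probes, call_rate)
  called <- colSums(!is.na(beta))
  nc <- signals$negative_controls
  background <- colMeans(nc)
  total <- signals$methylated + signals$unmethylated
  sig_mean <- colMeans(total)
  s_sig <- apply(total, 2L, stats::sd)
  s_bg <- apply(nc, 2L, stats::sd)
  n1 <- nrow(total); n2 <- nrow(nc)
  pooled <- sqrt(((n1 - 1) * s_sig^2 + (n2 - 1) * s_bg^2) / (n1 + n2 - 2))
  separation <- (sig_mean - background) / pooled
  ok_call <- called >= floor_n
  ok_bg <- background < max_background
  ok_sep <- separation > min_separation
  pass <- ok_call & ok_bg & ok_sep
  reasons <- purrr::pmap_chr(list(ok_call, ok_bg, ok_sep), function(a, b, c) {
    r <- c(if (!a) "call_rate", if (!b) "background", if (!c) "separation")
    if (length(r)) paste(r, collapse = ";") else ""
  })
  report <- tibble::tibble(
    sample_id = colnames(beta),
    called = unname(called),
    call_rate = unname(called) / n_probes,
    background_level = unname(background),
    nonpoly_separation = unname(separation),
    pass = unname(pass),
    reasons = reasons
  )
  list(samples = report$sample_id[report$pass], report = report)
}

#' Probe-level filter on missingness
#'
#' Drops every probe whose beta-value is missing or invalid in
#' `max_bad_samples` or more samples (applied after sample QC); order of the
#' kept probes is preserved.
#'
#' @param x A `beta_matrix` or a plain beta matrix (probes x samples).
#' @param max_bad_samples Drop threshold: a probe is dropped when its count
#'   of missing entries is greater than or equal to this value (default 10).
#' @return List with character vectors `kept` and `dropped` (probe ids), and
#'   `bad_counts` (named integer vector of per-probe missing counts).
#' @export
filter_probes <- function(x, max_bad_samples = 10) {
  beta <- if (inherits(x, "beta_matrix")) x$beta else x
  stopifnot(is.matrix(beta))
  bad <- rowSums(is.na(beta))
  ids <- rownames(beta)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(beta)))
  drop <- bad >= max_bad_samples
  list(kept = ids[!drop], dropped = ids[drop],
       bad_counts = stats::setNames(as.integer(bad), ids))
}

#' Logit (M-value) transform and its inverse
#'
#' `m = log(b / (1 - b))` with beta clamped into `[eps, 1 - eps]` so the
#' transform stays finite at the boundaries; missing values propagate.
#'
#' @param beta A `beta_matrix`, or a numeric matrix/vector of beta-values.
#' @param eps Clamping constant, must lie in (0, 0.5).
#' @return Matrix/vector of M-values (same shape as input).
#' @export
#' @examples
#' logit_transform(0.5)      # 0
#' logit_transform(0.7778)   # ~1.2528
logit_transform <- function(beta, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5) {
    rlang::abort("`eps` must lie strictly between 0 and 0.5",
                 class = "methylwas_parameter_error")
  }
  b <- if (inherits(beta, "beta_matrix")) beta$beta else beta
  if (any(b < 0 | b > 1, na.rm = TRUE)) {
    rlang::abort("beta-values must lie in [0, 1]",
                 class = "methylwas_input_error")
  }
  stats::qlogis(pmin(pmax(b, eps), 1 - eps))
}

#' @rdname logit_transform
#' @param m M-values to map back to the beta scale.
#' @export
inv_logit_transform <- function(m) {
  stats::plogis(m)
}

#' k-nearest-neighbour imputation of M-values
#'
#' For every probe with missing entries, the `k` nearest fully observed
#' probes (Euclidean distance over the samples where the target probe is
#' observed) are found, and each missing entry is replaced by the unweighted
#' mean of the neighbours' values at that sample. Observed entries are never
#' changed.
#'
#' @param m Probes x samples matrix of M-values with `NA`s.
#' @param k Number of neighbours (default 10).
#' @return The completed matrix.
#' @export
knn_impute <- function(m, k = 10) {
  stopifnot(is.matrix(m))
  miss_rows <- which(rowSums(is.na(m)) > 0L)
  if (!length(miss_rows)) return(m)
  complete <- which(rowSums(is.na(m)) == 0L)
  if (length(complete) < k) {
    rlang::abort(sprintf(
      "kNN imputation needs >= %d fully observed probes (found %d)",
      k, length(complete)), class = "methylwas_impute_error")
  }
  cand <- m[complete, , drop = FALSE]
  for (i in miss_rows) {
    obs <- !is.na(m[i, ])
    if (!any(obs)) {
      rlang::abort(sprintf("probe '%s' has no observed entries; cannot impute",
                           rownames(m)[i] %||% i),
                   class = "methylwas_impute_error")
    }
    d2 <- rowSums(sweep(cand[, obs, drop = FALSE], 2L, m[i, obs])^2)
    nb <- order(d2)[seq_len(k)]
    miss <- which(!obs)
    m[i, miss] <- colMeans(cand[nb, miss, drop = FALSE])
  }
  m
}

#' Preprocess raw signals end to end
#'
#' Runs the full QC chain: beta computation with detection masking, sample
#' QC, probe filtering, logit transform and kNN imputation, returning a
#' complete M-value matrix ready for PCA and association testing.
#'
#' @inheritParams compute_beta
#' @inheritParams filter_samples
#' @inheritParams filter_probes
#' @param knn_k Neighbours for [knn_impute()].
#' @param logit_eps Clamping constant for [logit_transform()].
#' @return A `methyl_preprocess` list: `m` (complete M-value matrix), `beta`
#'   (masked beta matrix after filtering), `sample_qc` (QC report tibble),
#'   `samples` (passing ids), `kept_probes`, `dropped_probes`, `counts`
#'   (bookkeeping for logs).
#' @export
preprocess_signals <- function(signals, detection_alpha = 0.05,
                               call_rate = 0.95, max_background = 1000,
                               min_separation = 5, max_bad_samples = 10,
                               knn_k = 10, logit_eps = 1e-6) {
  bm <- compute_beta(signals, detection_alpha = detection_alpha)
  sqc <- filter_samples(bm, signals, call_rate = call_rate,
                        max_background = max_background,
                        min_separation = min_separation)
  beta <- bm$beta[, sqc$samples, drop = FALSE]
  pf <- filter_probes(beta, max_bad_samples = max_bad_samples)
  beta <- beta[pf$kept, , drop = FALSE]
  m <- logit_transform(beta, eps = logit_eps)
  if (anyNA(m)) m <- knn_impute(m, k = knn_k)
  structure(list(
    m = m, beta = beta, sample_qc = sqc$report, samples = sqc$samples,
    kept_probes = pf$kept, dropped_probes = pf$dropped,
    counts = list(
      n_samples_in = ncol(bm$beta), n_samples_kept = length(sqc$samples),
      n_probes_in = nrow(bm$beta), n_probes_kept = length(pf$kept),
      n_imputed = sum(is.na(beta))
    )
  ), class = "methyl_preprocess")
}

#' @export
print.methyl_preprocess <- function(x, ...) {
  cat(sprintf(
    "<methyl_preprocess> samples %d -> %d, probes %d -> %d, %d entries imputed\n",
    x$counts$n_samples_in, x$counts$n_samples_kept,
    x$counts$n_probes_in, x$counts$n_probes_kept, x$counts$n_imputed))
  invisible(x)
}
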