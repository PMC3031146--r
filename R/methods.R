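# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association fit
#'
#' @param x A `methyl_ewas` object.
#' @param ... Unused.
#' @return The per-probe results tibble (estimate, t, empirical p, q-value,
#'   direction and annotation columns).
#' @export
tidy.methyl_ewas <- function(x, ...) {
  x$results
}

#' One-row summary of an association fit
#'
#' @param x A `methyl_ewas` object.
#' @param ... Unused.
#' @return Tibble with `n_probes`, `n_samples`, `n_randomizations`, `pi0`,
#'   `n_candidates`, `n_island`, `n_hyper`, `p_threshold`.
#' @export
glance.methyl_ewas <- function(x, ...) {
  tibble::tibble(
    n_probes = x$n_probes,
    n_samples = x$n_samples,
    n_randomizations = x$R,
    pi0 = x$pi0,
    n_candidates = nrow(x$candidates),
    n_island = if ("cpg_island" %in% names(x$candidates))
      sum(x$candidates$cpg_island) else NA_integer_,
    n_hyper = sum(x$candidates$direction == "+"),
    p_threshold = x$p_threshold
  )
}

#' Tidy a PCA result
#'
#' @param x A `methyl_pca` object.
#' @param ... Unused.
#' @return Tibble with `component`, `variance_explained`.
#' @export
tidy.methyl_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 variance_explained = x$variance_explained)
}

#' One-row summary of a PCA result
#'
#' @param x A `methyl_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_components`, `total_variance_explained`.
#' @export
glance.methyl_pca <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 total_variance_explained = sum(x$variance_explained))
}

#' Q-Q plot of empirical p-values
#'
#' @param object A `methyl_ewas` object.
#' @param ... Unused.
#' @return A ggplot: observed vs expected -log10(p) with the identity line.
#' @export
autoplot.methyl_ewas <- function(object, ...) {
  ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = "Q-Q plot of empirical p-values") +
    ggplot2::theme_minimal()
}

#' Scree plot
#'
#' @param object A `methyl_pca` object.
#' @param ... Unused.
#' @return A ggplot of per-component variance explained.
#' @export
autoplot.methyl_pca <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$component, y = .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Principal component", y = "Proportion of variance") +
    ggplot2::theme_minimal()
}

#' Histogram of beta-values per sample
#'
#' Displays the characteristic bimodal beta distribution (a high peak of
#' hypomethylated sites, a lower peak of hypermethylated sites).
#'
#' @param beta A `beta_matrix` or plain probes x samples beta matrix.
#' @param n_samples Number of samples to facet (default 4).
#' @return A ggplot.
#' @export
plot_beta_distribution <- function(beta, n_samples = 4) {
  b <- if (inherits(beta, "beta_matrix")) beta$beta else beta
  keep <- colnames(b)[seq_len(min(n_samples, ncol(b)))]
  df <- tibble::as_tibble(b[, keep, drop = FALSE], rownames = "probe_id") |>
    tidyr::pivot_longer(!"probe_id", names_to = "sample_id", values_to = "beta") |>
    dplyr::filter(!is.na(.data$beta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = expression(beta ~ value), y = "CpG sites") +
    ggplot2::theme_minimal()
}

#' Bar chart of top gene-set overlaps
#'
#' @param overlaps Result of [overlap_test()].
#' @param top Number of sets to display (default 10).
#' @return A ggplot of -log10(p) per set.
#' @export
plot_enrichment <- function(overlaps, top = 10) {
  df <- dplyr::slice_min(overlaps, .data$p_value, n = top, with_ties = FALSE)
  df$set_name <- stats::reorder(df$set_name, df$neg_log10_p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_log10_p, y = .data$set_name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Top gene-set overlaps") +
    ggplot2::theme_minimal()
}
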