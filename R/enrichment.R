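# Gene-set over-representation: map candidate CpG sites to genes and test
# overlaps with user-supplied GMT collections by the one-sided
# hypergeometric test, the programmatic equivalent of the GSEA web
# "compute overlaps" tool.

#' Map candidate probes to unique genes
#'
#' Uppercases symbols, drops empty ones, deduplicates (several probes can
#' interrogate the same gene), and orders genes by their best (smallest)
#' empirical p-value.
#'
#' @param candidates Candidate tibble with `probe_id` and `p_empirical`.
#' @param manifest Probe annotation tibble supplying `gene_symbol`.
#' @return Tibble: `gene_symbol`, `best_p`, `n_probes`, ordered by
#'   ascending `best_p`.
#' @export
map_probes_to_genes <- function(candidates, manifest) {
  if (nrow(candidates) == 0L) {
    return(tibble::tibble(gene_symbol = character(0), best_p = numeric(0),
                          n_probes = integer(0)))
  }
  absent <- setdiff(candidates$probe_id, manifest$probe_id)
  if (length(absent)) {
    rlang::abort(sprintf("probe '%s' is absent from the manifest", absent[1]),
                 class = "methylwas_input_error")
  }
  candidates |>
    dplyr::select(!dplyr::any_of(c("gene_symbol", "chromosome", "cpg_island"))) |>
    dplyr::left_join(manifest[, c("probe_id", "gene_symbol")], by = "probe_id") |>
    dplyr::mutate(gene_symbol = toupper(.data$gene_symbol)) |>
    dplyr::filter(!is.na(.data$gene_symbol), nzchar(.data$gene_symbol)) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(best_p = min(.data$p_empirical), n_probes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$best_p)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the overlap between the query gene list
#' and the set (both intersected with the universe) is larger than expected
#' by chance: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` where `N` is
#' the universe size, `K` the set size within the universe, `n` the query
#' size and `k` the overlap. The universe should be the genes actually
#' assayed (candidates can only arise from them). Benjamini-Hochberg FDR is
#' applied across sets.
#'
#' @param genes Character vector of query gene symbols (or a tibble with a
#'   `gene_symbol` column, e.g. from [map_probes_to_genes()]).
#' @param gene_sets Gene-set tibble from [read_gmt()] (columns `name`,
#'   `members`).
#' @param universe Character vector of all assayed gene symbols.
#' @return Tibble ranked by ascending p: `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr_q`, `neg_log10_p`, `overlap` (semicolon-joined
#'   symbols).
#' @export
overlap_test <- function(genes, gene_sets, universe) {
  if (is.data.frame(genes)) genes <- genes$gene_symbol
  genes <- unique(toupper(genes))
  universe <- unique(toupper(universe))
  if (!length(universe)) {
    rlang::abort("the gene universe is empty",
                 class = "methylwas_undefined_test_error")
  }
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    rlang::warn(sprintf("%d query gene(s) outside the universe dropped",
                        length(outside)))
    genes <- intersect(genes, universe)
  }
  if (!length(genes)) {
    rlang::abort("the query gene list is empty",
                 class = "methylwas_undefined_test_error")
  }
  N <- length(universe)
  n <- length(genes)
  rows <- purrr::map2(gene_sets$name, gene_sets$members, function(nm, mem) {
    set_in_universe <- intersect(unique(toupper(mem)), universe)
    K <- length(set_in_universe)
    hit <- intersect(genes, set_in_universe)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
                   overlap = paste(sort(hit), collapse = ";"))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out$neg_log10_p <- -log10(out$p_value)
  dplyr::arrange(out, .data$p_value)
}
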