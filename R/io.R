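# Readers and writers for every external artifact: probe manifests and sample
# sheets (CSV), beta/signal matrices and result tables (TSV), gene sets (GMT)
# and ground truth / run metadata (JSON).
#
# Conventions: matrices are probes-in-rows, samples-in-columns (vendor export
# orientation); "NA" (case-sensitive) is the only recognized missing token;
# readers reject malformed input with the offending row/line in the message.

.manifest_cols <- c("probe_id", "gene_symbol", "gene_id", "chromosome",
                    "cpg_island", "mirna_tags", "imprinted")

.parse_flag <- function(x, col) {
  out <- rep(NA, length(x))
  x0 <- trimws(as.character(x))
  out[x0 %in% c("Yes", "TRUE", "1", "yes", "true")] <- TRUE
  out[x0 %in% c("No", "FALSE", "0", "no", "false", "")] <- FALSE
  bad <- which(is.na(out) & !is.na(x0) & x0 != "NA")
  if (length(bad)) {
    rlang::abort(sprintf("column `%s`: unrecognized flag value '%s' at row %d",
                         col, x0[bad[1]], bad[1]),
                 class = "methylwas_format_error")
  }
  out
}

#' Read a probe manifest
#'
#' Expects a CSV with columns `probe_id`, `gene_symbol`, `chromosome`,
#' `cpg_island` (one of Yes/No/TRUE/FALSE/1/0) and optionally `gene_id`,
#' `mirna_tags`, `imprinted`.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one row per probe.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("probe_id", "gene_symbol", "chromosome", "cpg_island")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("manifest is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "methylwas_format_error")
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) {
    rlang::abort(sprintf("duplicate probe_id in manifest: %s", dup[1]),
                 class = "methylwas_format_error")
  }
  tibble::tibble(
    probe_id = df$probe_id,
    gene_symbol = dplyr::coalesce(df$gene_symbol, ""),
    gene_id = if ("gene_id" %in% names(df)) dplyr::coalesce(df$gene_id, "") else "",
    chromosome = df$chromosome,
    cpg_island = .parse_flag(df$cpg_island, "cpg_island"),
    mirna_tags = if ("mirna_tags" %in% names(df)) dplyr::coalesce(df$mirna_tags, "") else "",
    imprinted = if ("imprinted" %in% names(df)) {
      dplyr::coalesce(.parse_flag(df$imprinted, "imprinted"), FALSE)
    } else FALSE
  )
}

#' Write a probe manifest
#'
#' @param manifest Tibble as returned by [read_manifest()] or
#'   [simulate_signals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$cpg_island <- ifelse(out$cpg_island, "Yes", "No")
  if ("imprinted" %in% names(out)) {
    out$imprinted <- ifelse(out$imprinted, "Yes", "No")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' @param path CSV path.
#' @return `read_sample_sheet()`: a tibble of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), status = readr::col_character(),
    chip_id = readr::col_character(), batch_id = readr::col_character(),
    position_on_chip = readr::col_integer(), bsc_red = readr::col_double(),
    bsc_green = readr::col_double(), age_years = readr::col_double(),
    race = readr::col_character(), bmi = readr::col_double(),
    smoker = readr::col_logical(), alcohol = readr::col_logical(),
    vitamin_use = readr::col_logical(), education = readr::col_character(),
    income_bracket = readr::col_integer(), subtype = readr::col_character(),
    replicate_of = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  if (!all(c("sample_id", "status") %in% names(df))) {
    rlang::abort("sample sheet needs `sample_id` and `status` columns",
                 class = "methylwas_format_error")
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    rlang::abort(sprintf("duplicate sample_id in sample sheet: %s", dup[1]),
                 class = "methylwas_format_error")
  }
  df
}

#' @rdname read_sample_sheet
#' @param samples Sample tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each tab-separated line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate member symbols within a set are counted once.
#'
#' @param path GMT file path.
#' @return A tibble with columns `name`, `description` and a list-column
#'   `members` (character vectors of unique gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    bad <- which(nfield < 3L)[1]
    rlang::abort(sprintf("GMT line %d has %d field(s); at least 3 required",
                         bad, nfield[bad]),
                 class = "methylwas_format_error")
  }
  tibble::tibble(
    name = vapply(parts, `[[`, character(1), 1L),
    description = vapply(parts, `[[`, character(1), 2L),
    members = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
}

.read_matrix_tsv <- function(path, what = "matrix") {
  df <- readr::read_tsv(path, na = "NA", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(df) < 2L) {
    rlang::abort(sprintf("%s file must have an id column plus sample columns", what),
                 class = "methylwas_format_error")
  }
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) & !(vals == "NA" | is.na(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    rlang::abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                         vals[bad[1, 1], bad[1, 2]], bad[1, 1],
                         colnames(vals)[bad[1, 2]], what),
                 class = "methylwas_format_error")
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

.write_matrix_tsv <- function(x, path, id_col) {
  df <- tibble::as_tibble(x, rownames = id_col)
  num_cols <- setdiff(names(df), id_col)
  for (cc in num_cols) {
    v <- df[[cc]]
    df[[cc]] <- ifelse(is.na(v), "NA", sprintf("%.10g", v))
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a beta-value (or M-value) matrix
#'
#' Matrices are stored as TSV with probes in rows (first column `probe_id`)
#' and samples in columns; values round-trip at 10 significant digits and
#' missing entries are encoded as the literal token `NA`.
#'
#' @param path TSV path.
#' @return `read_beta_matrix()`: a numeric probes x samples matrix.
#' @export
read_beta_matrix <- function(path) {
  m <- .read_matrix_tsv(path, "beta matrix")
  out_of_range <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(out_of_range)) {
    rlang::abort("beta matrix contains values outside [0, 1]",
                 class = "methylwas_format_error")
  }
  m
}

#' @rdname read_beta_matrix
#' @param beta Numeric matrix (probes x samples) with dimnames.
#' @export
write_beta_matrix <- function(beta, path) {
  .write_matrix_tsv(beta, path, "probe_id")
}

#' Write raw signal matrices
#'
#' Emits `methylated.tsv`, `unmethylated.tsv` and `negative_controls.tsv`
#' under `dir`.
#'
#' @param signals A `methyl_signals` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_signals <- function(signals, dir) {
  stopifnot(inherits(signals, "methyl_signals"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv(signals$methylated, file.path(dir, "methylated.tsv"), "probe_id")
  .write_matrix_tsv(signals$unmethylated, file.path(dir, "unmethylated.tsv"), "probe_id")
  nc <- signals$negative_controls
  rownames(nc) <- sprintf("neg%03d", seq_len(nrow(nc)))
  .write_matrix_tsv(nc, file.path(dir, "negative_controls.tsv"), "control_id")
  invisible(dir)
}

#' Read raw signal matrices written by [write_signals()]
#'
#' @param dir Directory containing the three TSV files.
#' @return A `methyl_signals` object.
#' @export
read_signals <- function(dir) {
  methyl_signals(
    .read_matrix_tsv(file.path(dir, "methylated.tsv"), "methylated"),
    .read_matrix_tsv(file.path(dir, "unmethylated.tsv"), "unmethylated"),
    .read_matrix_tsv(file.path(dir, "negative_controls.tsv"), "negative controls")
  )
}

.results_cols <- c("probe_id", "gene_symbol", "estimate", "t_statistic",
                   "p_empirical", "q_value", "direction", "cpg_island",
                   "chromosome")

#' Write / read per-probe association results
#'
#' The TSV column order is stable: probe_id, gene_symbol, estimate, t,
#' empirical p, q, direction (+/-), CpG-island flag, chromosome.
#'
#' @param results Association results tibble (from [run_association()] /
#'   [tidy()]).
#' @param path TSV path.
#' @return `path` (writer, invisibly) or the results tibble (reader).
#' @export
write_association_results <- function(results, path) {
  missing_cols <- setdiff(.results_cols, names(results))
  if (length(missing_cols)) {
    rlang::abort(paste0("results are missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "methylwas_format_error")
  }
  out <- results[, c(.results_cols, setdiff(names(results), .results_cols))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_association_results
#' @export
read_association_results <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), gene_symbol = readr::col_character(),
    estimate = readr::col_double(), t_statistic = readr::col_double(),
    p_empirical = readr::col_double(), q_value = readr::col_double(),
    direction = readr::col_character(), cpg_island = readr::col_logical(),
    chromosome = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  missing_cols <- setdiff(.results_cols, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("results file is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "methylwas_format_error")
  }
  df
}

#' Write the candidate-site table
#'
#' Candidates are written sorted by ascending empirical p-value.
#'
#' @param candidates Candidate tibble from [select_candidates()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- dplyr::arrange(candidates, .data$p_empirical)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Stores the spiked site ids, their effect signs, and per-chip mean
#' technical effects (the full probes x chips matrix is omitted for size).
#'
#' @param truth Ground-truth list from [simulate_signals()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    true_sites = truth$true_sites,
    effect_sign = as.list(truth$effect_sign),
    chip_mean_effects = as.list(round(colMeans(truth$chip_effects), 6))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
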