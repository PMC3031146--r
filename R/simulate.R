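# Synthetic Infinium-27K-like cohort and signal generator.
#
# The generator produces (i) a sample sheet with case/control status, chip and
# batch placement and lifestyle covariates distributed like a real pregnancy
# cohort, and (ii) raw methylated/unmethylated intensities plus negative
# controls from which the full pipeline recovers beta-values. Ground truth
# (spiked sites, per-probe chip effects, intended beta matrix) is returned so
# that downstream stages can be tested for parameter recovery.

# Marginal covariate distributions (per status) used by simulate_cohort().
# Category probabilities are empirical frequencies from a 180-case/187-control
# congenital heart defect cohort, with "missing" carried as its own category
# to exercise complete-case handling downstream.
.cohort_margins <- list(
  age_ge30   = list(case = 69 / 180, control = 74 / 187),
  race       = list(
    levels  = c("caucasian", "african_american", "other"),
    case    = c(136, 32, 12) / 180,
    control = c(148, 22, 17) / 187
  ),
  smoker     = list(case = c(no = 126, yes = 54, missing = 0) / 180,
                    control = c(no = 151, yes = 35, missing = 1) / 187),
  alcohol    = list(case = c(no = 93, yes = 86, missing = 1) / 180,
                    control = c(no = 85, yes = 100, missing = 2) / 187),
  vitamin    = list(case = c(no = 99, yes = 81, missing = 0) / 180,
                    control = c(no = 111, yes = 75, missing = 1) / 187),
  education  = list(case = c(hs_or_lower = 83, college_plus = 92, missing = 5) / 180,
                    control = c(hs_or_lower = 79, college_plus = 108, missing = 0) / 187),
  income     = list(case = c(34, 60, 39, 34, 13) / 180,      # brackets 1..4 + missing
                    control = c(23, 55, 51, 46, 12) / 187),
  bmi        = list(case = c(under = 3, normal = 57, over = 44, obese = 68, missing = 8) / 180,
                    control = c(under = 6, normal = 78, over = 34, obese = 60, missing = 9) / 187),
  subtype    = list(none = 14 / 180, weights = c(septal = 85, obstructive = 63, conotruncal = 30))
)

#' Simulation configuration
#'
#' Collects and validates every free parameter of the synthetic cohort and
#' signal generator. Defaults describe the emulated study: chips of 12
#' samples processed in batches of up to 4 chips, 76% of probes inside CpG
#' islands, and a bimodal baseline beta distribution.
#'
#' @param n_cases,n_controls Number of case and control mothers.
#' @param n_probes Number of CpG probes on the simulated array.
#' @param island_fraction Proportion of probes flagged as CpG island.
#' @param samples_per_chip Arrays per BeadChip (12 on the 27K platform).
#' @param chips_per_batch Chips processed together in one batch (up to 4).
#' @param n_true_sites Number of probes receiving a spiked case effect.
#' @param effect_size_logit Mean case-control shift, on the logit scale, at
#'   spiked sites.
#' @param chip_effect_sd Standard deviation of per-probe, per-chip technical
#'   effects on the logit scale (the confounder the randomization null is
#'   designed to absorb).
#' @param residual_sd Biological/technical residual SD on the logit scale.
#' @param missing_rate Proportion of (probe, sample) entries whose signal is
#'   degraded to background level so that detection fails.
#' @param n_negative_controls Negative-control beads per sample.
#' @param signal_gain Expected total intensity of a fully driven probe.
#' @param background_mean,background_sd Location/scale of the half-normal
#'   background noise added to each channel and used for negative controls.
#' @param mixture_weights Length-3 weights of the hypomethylated,
#'   hypermethylated and intermediate baseline components.
#' @param hyper_fraction Probability that a spiked site is hypermethylated in
#'   cases (positive logit shift).
#' @param covariate_missingness If `TRUE`, lifestyle covariates are missing at
#'   the emulated cohort's rates; set `FALSE` for fully observed covariates.
#' @param replicates If `TRUE`, one technical replicate per batch is added
#'   (duplicated methylation profile with independent signal noise).
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 10, n_controls = 10, n_probes = 100, seed = 1)
sim_config <- function(n_cases = 180L, n_controls = 187L, n_probes = 2000L,
                       island_fraction = 0.76, samples_per_chip = 12L,
                       chips_per_batch = 4L, n_true_sites = 0L,
                       effect_size_logit = 0, chip_effect_sd = 0.3,
                       residual_sd = 0.5, missing_rate = 0.01,
                       n_negative_controls = 32L, signal_gain = 5000,
                       background_mean = 200, background_sd = 50,
                       mixture_weights = c(hypo = 0.62, hyper = 0.20, mid = 0.18),
                       hyper_fraction = 0.892,
                       covariate_missingness = TRUE, replicates = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_probes = as.integer(n_probes), island_fraction = island_fraction,
    samples_per_chip = as.integer(samples_per_chip),
    chips_per_batch = as.integer(chips_per_batch),
    n_true_sites = as.integer(n_true_sites),
    effect_size_logit = effect_size_logit, chip_effect_sd = chip_effect_sd,
    residual_sd = residual_sd, missing_rate = missing_rate,
    n_negative_controls = as.integer(n_negative_controls),
    signal_gain = signal_gain, background_mean = background_mean,
    background_sd = background_sd,
    mixture_weights = mixture_weights / sum(mixture_weights),
    hyper_fraction = hyper_fraction,
    covariate_missingness = isTRUE(covariate_missingness),
    replicates = isTRUE(replicates), seed = as.integer(seed)
  )
  counts <- c("n_cases", "n_controls", "n_probes", "n_true_sites",
              "samples_per_chip", "chips_per_batch", "n_negative_controls")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      rlang::abort(sprintf("`%s` must be a non-negative count", nm),
                   class = "methylwas_config_error")
    }
  }
  props <- c(island_fraction = cfg$island_fraction,
             missing_rate = cfg$missing_rate,
             hyper_fraction = cfg$hyper_fraction)
  if (any(props < 0 | props > 1)) {
    rlang::abort("proportions must lie in [0, 1]",
                 class = "methylwas_config_error")
  }
  if (cfg$chip_effect_sd < 0 || cfg$background_sd < 0) {
    rlang::abort("standard deviations must be >= 0",
                 class = "methylwas_config_error")
  }
  if (cfg$residual_sd <= 0) {
    rlang::abort("`residual_sd` must be > 0", class = "methylwas_config_error")
  }
  if (cfg$n_true_sites > cfg$n_probes) {
    rlang::abort("`n_true_sites` must not exceed `n_probes`",
                 class = "methylwas_config_error")
  }
  if (cfg$samples_per_chip < 1 || cfg$chips_per_batch < 1) {
    rlang::abort("chip layout counts must be >= 1",
                 class = "methylwas_config_error")
  }
  structure(cfg, class = "sim_config")
}

.draw_cat <- function(n, levels, prob) {
  if (n == 0L) return(character(0))
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

.yesno_to_lgl <- function(x) {
  out <- rep(NA, length(x))
  out[x == "yes"] <- TRUE
  out[x == "no"] <- FALSE
  out
}

#' Simulate a case-control cohort with chip placement
#'
#' Draws `n_cases + n_controls` subjects with lifestyle covariates matching
#' the emulated cohort's marginal frequencies, randomly interleaves cases and
#' controls onto chips of `samples_per_chip` arrays, groups chips into batches
#' of up to `chips_per_batch`, and draws two correlated bisulfite-conversion
#' efficiency channels per subject.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per subject (plus technical replicates when
#'   `config$replicates` is set): `sample_id`, `status`, `chip_id`,
#'   `batch_id`, `position_on_chip`, `bsc_red`, `bsc_green`, `age_years`,
#'   `race`, `bmi`, `smoker`, `alcohol`, `vitamin_use`, `education`,
#'   `income_bracket`, `subtype`, `replicate_of`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  if (n == 0L && config$n_true_sites > 0L) {
    rlang::abort("cannot spike true sites into an empty cohort",
                 class = "methylwas_config_error")
  }
  cols <- c("sample_id", "status", "chip_id", "batch_id", "position_on_chip",
            "bsc_red", "bsc_green", "age_years", "race", "bmi", "smoker",
            "alcohol", "vitamin_use", "education", "income_bracket",
            "subtype", "replicate_of")
  if (n == 0L) {
    out <- tibble::tibble(
      sample_id = character(0), status = character(0), chip_id = character(0),
      batch_id = character(0), position_on_chip = integer(0),
      bsc_red = numeric(0), bsc_green = numeric(0), age_years = numeric(0),
      race = character(0), bmi = numeric(0), smoker = logical(0),
      alcohol = logical(0), vitamin_use = logical(0), education = character(0),
      income_bracket = integer(0), subtype = character(0),
      replicate_of = character(0)
    )
    return(out[cols])
  }
  withr::with_seed(config$seed, {
    status <- c(rep("case", config$n_cases), rep("control", config$n_controls))
    mg <- .cohort_margins

    by_status <- function(fn) {
      out <- vector("list", n)
      for (st in c("case", "control")) {
        idx <- which(status == st)
        out[idx] <- as.list(fn(length(idx), st))
      }
      out
    }

    age_cat <- unlist(by_status(function(k, st) {
      stats::runif(k) < mg$age_ge30[[st]]
    }))
    age <- ifelse(age_cat, stats::runif(n, 30, 42), stats::runif(n, 18, 30))
    race <- unlist(by_status(function(k, st) {
      .draw_cat(k, mg$race$levels, mg$race[[st]])
    }))
    smoker <- .yesno_to_lgl(unlist(by_status(function(k, st) {
      .draw_cat(k, names(mg$smoker[[st]]), mg$smoker[[st]])
    })))
    alcohol <- .yesno_to_lgl(unlist(by_status(function(k, st) {
      .draw_cat(k, names(mg$alcohol[[st]]), mg$alcohol[[st]])
    })))
    vitamin <- .yesno_to_lgl(unlist(by_status(function(k, st) {
      .draw_cat(k, names(mg$vitamin[[st]]), mg$vitamin[[st]])
    })))
    education <- unlist(by_status(function(k, st) {
      .draw_cat(k, names(mg$education[[st]]), mg$education[[st]])
    }))
    education[education == "missing"] <- NA_character_
    income <- unlist(by_status(function(k, st) {
      .draw_cat(k, c("1", "2", "3", "4", "missing"), mg$income[[st]])
    }))
    income_bracket <- suppressWarnings(as.integer(income))
    bmi_cat <- unlist(by_status(function(k, st) {
      .draw_cat(k, names(mg$bmi[[st]]), mg$bmi[[st]])
    }))
    bmi <- rep(NA_real_, n)
    bmi[bmi_cat == "under"]  <- stats::runif(sum(bmi_cat == "under"), 16, 18.5)
    bmi[bmi_cat == "normal"] <- stats::runif(sum(bmi_cat == "normal"), 18.5, 25)
    bmi[bmi_cat == "over"]   <- stats::runif(sum(bmi_cat == "over"), 25, 30)
    bmi[bmi_cat == "obese"]  <- stats::runif(sum(bmi_cat == "obese"), 30, 45)

    if (!config$covariate_missingness) {
      # re-draw missing entries from the observed category mix
      fill <- function(x, lv, pr) {
        miss <- is.na(x)
        x[miss] <- .draw_cat(sum(miss), lv, pr)
        x
      }
      smoker[is.na(smoker)] <- stats::runif(sum(is.na(smoker))) < 0.19
      alcohol[is.na(alcohol)] <- stats::runif(sum(is.na(alcohol))) < 0.5
      vitamin[is.na(vitamin)] <- stats::runif(sum(is.na(vitamin))) < 0.42
      education <- fill(education, c("hs_or_lower", "college_plus"), c(0.45, 0.55))
      ib <- is.na(income_bracket)
      income_bracket[ib] <- sample.int(4L, sum(ib), replace = TRUE)
      nb <- is.na(bmi)
      bmi[nb] <- stats::runif(sum(nb), 18.5, 35)
    }

    subtype <- rep(NA_character_, n)
    is_case <- status == "case"
    if (any(is_case)) {
      w <- mg$subtype$weights
      typed <- is_case & stats::runif(n) >= mg$subtype$none
      first <- .draw_cat(sum(typed), names(w), w)
      subtype[typed] <- first
      # a small fraction of typed cases carry a second defect type
      second <- which(typed)[stats::runif(sum(typed)) < 12 / 166]
      for (i in second) {
        rest <- setdiff(names(w), subtype[i])
        subtype[i] <- paste(sort(c(subtype[i], .draw_cat(1, rest, w[rest]))),
                            collapse = "+")
      }
    }

    # two highly correlated bisulfite-conversion efficiency channels
    z <- stats::rnorm(n)
    bsc_red <- pmin(pmax(0.95 + 0.02 * z, 0.5), 1)
    bsc_green <- pmin(pmax(0.93 + 0.02 * (0.9 * z +
                                            sqrt(1 - 0.9^2) * stats::rnorm(n)), 0.5), 1)

    # random interleaving onto chips, chips grouped into batches
    ord <- sample.int(n)
    chip_index <- integer(n)
    position <- integer(n)
    chip_index[ord] <- (seq_len(n) - 1L) %/% config$samples_per_chip + 1L
    position[ord] <- (seq_len(n) - 1L) %% config$samples_per_chip + 1L
    batch_index <- (chip_index - 1L) %/% config$chips_per_batch + 1L

    out <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      status = status,
      chip_id = sprintf("chip%03d", chip_index),
      batch_id = sprintf("batch%02d", batch_index),
      position_on_chip = position,
      bsc_red = bsc_red, bsc_green = bsc_green,
      age_years = age, race = race, bmi = bmi, smoker = smoker,
      alcohol = alcohol, vitamin_use = vitamin, education = education,
      income_bracket = income_bracket, subtype = subtype,
      replicate_of = NA_character_
    )

    if (config$replicates) {
      occupancy <- table(out$chip_id)
      reps <- list()
      for (b in unique(out$batch_id)) {
        chips_b <- unique(out$chip_id[out$batch_id == b])
        free <- chips_b[occupancy[chips_b] < config$samples_per_chip]
        if (length(free) == 0L) next
        src <- out[out$batch_id == b, ][sample.int(sum(out$batch_id == b), 1L), ]
        rec <- src
        rec$sample_id <- paste0(src$sample_id, "R")
        rec$status <- "replicate"
        rec$replicate_of <- src$sample_id
        rec$chip_id <- free[[1L]]
        rec$position_on_chip <- as.integer(occupancy[free[[1L]]] + 1L)
        occupancy[free[[1L]]] <- occupancy[free[[1L]]] + 1L
        rec$subtype <- NA_character_
        reps[[length(reps) + 1L]] <- rec
      }
      if (length(reps)) out <- dplyr::bind_rows(out, dplyr::bind_rows(reps))
    }
    out
  })
}

#' Simulate raw array signals with known ground truth
#'
#' Draws per-probe baseline methylation from a three-component Beta mixture
#' (bimodal: most probes hypomethylated, a smaller peak hypermethylated),
#' spikes `n_true_sites` probes with an additive `effect_size_logit` shift in
#' cases, adds per-probe per-chip technical effects and residual noise on the
#' logit scale, and synthesizes methylated/unmethylated channel intensities
#' (`signal_gain * beta` plus half-normal background) together with
#' negative-control intensities. Entries selected for missingness have their
#' signal degraded to background level so that the detection p-value fails.
#'
#' @param samples Cohort tibble from [simulate_cohort()].
#' @param config The same [sim_config()] used to generate `samples`.
#' @return A list with elements
#'   \describe{
#'     \item{signals}{a `methyl_signals` object (methylated, unmethylated,
#'       negative_controls matrices),}
#'     \item{manifest}{probe annotation tibble (`probe_id`, `gene_symbol`,
#'       `gene_id`, `chromosome`, `cpg_island`, `mirna_tags`, `imprinted`),}
#'     \item{truth}{ground truth: `true_sites`, `effect_sign`,
#'       `chip_effects` (probes x chips matrix), `beta` (intended beta
#'       matrix), `baseline_beta`.}
#'   }
#' @export
simulate_signals <- function(samples, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(samples) == 0L) {
    rlang::abort("`samples` must be non-empty", class = "methylwas_config_error")
  }
  if (config$n_probes == 0L) {
    rlang::abort("`n_probes` must be positive", class = "methylwas_config_error")
  }
  np <- config$n_probes
  ns <- nrow(samples)
  withr::with_seed(config$seed + 1L, {
    probe_id <- sprintf("cg%07d", seq_len(np))
    gene_idx <- (seq_len(np) - 1L) %/% 2L + 1L
    manifest <- tibble::tibble(
      probe_id = probe_id,
      gene_symbol = sprintf("GENE%05d", gene_idx),
      gene_id = as.character(10000L + gene_idx),
      chromosome = sample(c(as.character(1:22), "X"), np, replace = TRUE),
      cpg_island = stats::runif(np) < config$island_fraction,
      mirna_tags = ifelse(stats::runif(np) < 0.004,
                          sprintf("HSA-MIR-%03d;", sample.int(600L, np, replace = TRUE)),
                          ""),
      imprinted = stats::runif(np) < 0.005
    )

    comp <- sample.int(3L, np, replace = TRUE, prob = config$mixture_weights)
    baseline <- numeric(np)
    baseline[comp == 1L] <- stats::rbeta(sum(comp == 1L), 0.5, 8)
    baseline[comp == 2L] <- stats::rbeta(sum(comp == 2L), 8, 0.5)
    baseline[comp == 3L] <- stats::rbeta(sum(comp == 3L), 2, 2)
    baseline <- pmin(pmax(baseline, 1e-4), 1 - 1e-4)

    effect <- numeric(np)
    true_sites <- character(0)
    effect_sign <- integer(0)
    if (config$n_true_sites > 0L) {
      eligible <- which(baseline >= 0.05 & baseline <= 0.95)
      if (length(eligible) < config$n_true_sites) {
        eligible <- order(pmin(baseline, 1 - baseline),
                          decreasing = TRUE)[seq_len(config$n_true_sites)]
      }
      sites <- sort(sample(eligible, config$n_true_sites))
      effect_sign <- ifelse(stats::runif(config$n_true_sites) < config$hyper_fraction,
                            1L, -1L)
      effect[sites] <- effect_sign * config$effect_size_logit
      true_sites <- probe_id[sites]
      names(effect_sign) <- true_sites
    }

    chips <- unique(samples$chip_id)
    chip_effects <- matrix(stats::rnorm(np * length(chips), 0, config$chip_effect_sd),
                           nrow = np, dimnames = list(probe_id, chips))

    is_case <- as.numeric(samples$status == "case")
    m <- matrix(stats::qlogis(baseline), np, ns) +
      outer(effect, is_case) +
      chip_effects[, match(samples$chip_id, chips), drop = FALSE] +
      matrix(stats::rnorm(np * ns, 0, config$residual_sd), np, ns)

    # technical replicates copy the source sample's methylation profile
    rep_idx <- which(samples$status == "replicate")
    if (length(rep_idx)) {
      src <- match(samples$replicate_of[rep_idx], samples$sample_id)
      m[, rep_idx] <- m[, src, drop = FALSE]
    }

    beta_true <- stats::plogis(m)
    dimnames(beta_true) <- list(probe_id, samples$sample_id)

    half_norm <- function(k) {
      if (config$background_mean == 0 && config$background_sd == 0) {
        numeric(k)
      } else {
        abs(stats::rnorm(k, config$background_mean, config$background_sd))
      }
    }
    meth <- config$signal_gain * beta_true + matrix(half_norm(np * ns), np, ns)
    unmeth <- config$signal_gain * (1 - beta_true) + matrix(half_norm(np * ns), np, ns)

    if (config$missing_rate > 0) {
      fail <- which(matrix(stats::runif(np * ns) < config$missing_rate, np, ns))
      if (length(fail)) {
        # failed probes emit background-level light split across the channels
        delta <- pmin(half_norm(length(fail)), half_norm(length(fail)))
        u <- stats::runif(length(fail))
        meth[fail] <- delta * u
        unmeth[fail] <- delta * (1 - u)
      }
    }

    negc <- matrix(half_norm(config$n_negative_controls * ns),
                   nrow = config$n_negative_controls,
                   dimnames = list(NULL, samples$sample_id))
    dimnames(meth) <- dimnames(unmeth) <- list(probe_id, samples$sample_id)

    signals <- methyl_signals(meth, unmeth, negc)
    truth <- list(true_sites = true_sites, effect_sign = effect_sign,
                  chip_effects = chip_effects, beta = beta_true,
                  baseline_beta = stats::setNames(baseline, probe_id))
    list(signals = signals, manifest = manifest, truth = truth)
  })
}

#' Construct a raw signal container
#'
#' @param methylated,unmethylated Probes x samples matrices of non-negative
#'   intensities with matching dimensions and dimnames.
#' @param negative_controls Controls x samples matrix of non-negative
#'   intensities (column order matching the signal matrices).
#' @return A `methyl_signals` object.
#' @export
methyl_signals <- function(methylated, unmethylated, negative_controls) {
  stopifnot(is.matrix(methylated), is.matrix(unmethylated),
            is.matrix(negative_controls))
  if (!all(dim(methylated) == dim(unmethylated))) {
    rlang::abort("channel matrices must have identical dimensions",
                 class = "methylwas_input_error")
  }
  if (ncol(negative_controls) != ncol(methylated)) {
    rlang::abort("negative controls must cover every sample",
                 class = "methylwas_input_error")
  }
  if (nrow(negative_controls) == 0L) {
    rlang::abort("at least one negative control per sample is required",
                 class = "methylwas_input_error")
  }
  structure(list(methylated = methylated, unmethylated = unmethylated,
                 negative_controls = negative_controls),
            class = "methyl_signals")
}

#' @export
print.methyl_signals <- function(x, ...) {
  cat(sprintf("<methyl_signals> %d probes x %d samples, %d negative controls/sample\n",
              nrow(x$methylated), ncol(x$methylated), nrow(x$negative_controls)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d cases + %d controls, %d probes, %d spiked sites (effect %.2f logit), seed %d\n",
              x$n_cases, x$n_controls, x$n_probes, x$n_true_sites,
              x$effect_size_logit, x$seed))
  invisible(x)
}
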