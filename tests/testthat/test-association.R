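# Design construction, site-wise OLS, the chip-constrained randomization
# null, empirical p-values, Storey q-values, candidates, enrichment, Q-Q.

test_that("the design matrix expands factors and handles missingness", {
  study <- tiny_study(n_cases = 180, n_controls = 187, n_probes = 10,
                      seed = 31, covariate_missingness = FALSE)
  design <- build_design(study$cohort)
  n_batch <- length(unique(study$cohort$batch_id))
  n_race <- length(unique(study$cohort$race))
  # intercept + status + (batches-1) + (races-1) + 7 continuous/binary
  # (two BSC channels, age, BMI, vitamin, alcohol, smoking)
  expect_equal(ncol(design$X), 1 + 1 + (n_batch - 1) + (n_race - 1) + 7)
  expect_equal(nrow(design$X), 367)
  expect_true(design$outcome_column %in% colnames(design$X))
  # complete-case: a sample missing BMI is excluded
  cohort2 <- study$cohort
  cohort2$bmi[5] <- NA
  design2 <- build_design(cohort2)
  expect_equal(nrow(design2$X), 366)
  expect_false(cohort2$sample_id[5] %in% design2$sample_id)
  # single-level factor dropped with a warning
  cohort3 <- study$cohort
  cohort3$batch_id <- "batch01"
  expect_warning(design3 <- build_design(cohort3), "single level")
  expect_false(any(grepl("batch", colnames(design3$X))))
  # rank deficiency is reported with the offending column
  cohort4 <- study$cohort
  cohort4$bsc_green <- cohort4$bsc_red
  expect_error(build_design(cohort4), "bsc_green",
               class = "methylwas_collinearity_error")
})

test_that("site regressions recover group differences, including perfect fits", {
  study <- tiny_study(n_cases = 10, n_controls = 10, n_probes = 5,
                      missing_rate = 0, seed = 33, covariate_missingness = FALSE)
  spec <- design_spec(covariates = character(0))
  design <- build_design(study$cohort, spec)
  case_ind <- as.numeric(design$status == "case")
  m <- matrix(rep(case_ind, each = 2), 2, 20,
              dimnames = list(c("pA", "pB"), design$sample_id))
  fit <- fit_site_regressions(m, design)
  expect_equal(fit$estimate, c(1, 1))
  expect_true(all(!is.finite(fit$t_statistic) | abs(fit$t_statistic) > 1e7))
  # analytic check against lm() on noisy data
  set.seed(1)
  m2 <- matrix(stats::rnorm(3 * 20), 3, 20,
               dimnames = list(c("x", "y", "z"), design$sample_id))
  fit2 <- fit_site_regressions(m2, design)
  ref <- summary(stats::lm(m2[2, ] ~ case_ind))$coefficients
  expect_equal(fit2$estimate[2], ref["case_ind", "Estimate"], tolerance = 1e-10)
  expect_equal(fit2$t_statistic[2], ref["case_ind", "t value"], tolerance = 1e-10)
  expect_equal(unname(fit2$p_theoretical[2]), unname(ref["case_ind", "Pr(>|t|)"]),
               tolerance = 1e-10)
})

test_that("chip randomization preserves per-chip multisets and is fair", {
  status <- c(rep("case", 7), rep("control", 9))
  chip <- rep(c("c1", "c2"), each = 8)
  for (r in 1:50) {
    perm <- randomize_status(status, chip, seed = 5, draw = r)
    for (cp in unique(chip)) {
      s0 <- sort(status[chip == cp])
      s1 <- sort(perm[chip == cp])
      flip0 <- ifelse(s0 == "case", "control", "case")
      expect_true(identical(s1, s0) || identical(s1, sort(flip0)))
    }
  }
  # reproducible from (seed, draw); different draws differ
  expect_identical(randomize_status(status, chip, 5, 3),
                   randomize_status(status, chip, 5, 3))
  draws <- vapply(1:20, function(r)
    paste(randomize_status(status, chip, 5, r), collapse = ""), character(1))
  expect_gt(length(unique(draws)), 1)
  # all-control chip: flip makes all cases, otherwise all controls
  perm2 <- vapply(1:200, function(r) {
    out <- randomize_status(rep("control", 4), rep("c1", 4), seed = 9, draw = r)
    all(out == "case") || all(out == "control")
  }, logical(1))
  expect_true(all(perm2))
})

test_that("the two-stage law gives every subject P(case) = 1/2 exactly", {
  # exhaustive enumeration over (permutation, flip) for chips of size <= 4
  for (labels in list(c("case", "control"),
                      c("case", "case", "control"),
                      c("case", "control", "control", "case"))) {
    s <- length(labels)
    perms <- all_perms(s)
    total <- 0
    case_count <- numeric(s)
    for (perm in perms) {
      for (flip in c(FALSE, TRUE)) {
        out <- methylwas:::.apply_chip_randomization(labels, perm, flip)
        case_count <- case_count + (out == "case")
        total <- total + 1
      }
    }
    expect_equal(case_count / total, rep(0.5, s))
  }
})

test_that("empirical p-values count ties as extreme with the +1 rule", {
  null_t <- matrix(stats::rnorm(999 * 2), 999, 2)
  t_obs <- c(max(abs(null_t[, 1])) + 1, 0)
  p <- empirical_pvalues(t_obs, null_t)
  expect_equal(p[1], 1 / 1000)
  expect_equal(p[2], 1)
  # ties counted as extreme
  null_tie <- matrix(c(2, 1, 0.5, 1), 4, 1)
  expect_equal(empirical_pvalues(2, null_tie), 2 / 5)
  # pooled mode compares against all draws of all probes
  p_pool <- empirical_pvalues(t_obs, null_t, pooled = TRUE)
  expect_equal(p_pool[1], 1 / (2 * 999 + 1))
  expect_error(empirical_pvalues(1, matrix(numeric(0), 0, 1)),
               class = "methylwas_plan_error")
})

test_that("Storey q-values reduce to BH at pi0 = 1 and are monotone", {
  p10 <- c(0.001, 0.009, 0.04, 0.051, 0.1, 0.2, 0.35, 0.5, 0.75, 1)
  q <- storey_qvalues(p10, pi0 = 1)
  expect_identical(as.numeric(q), p.adjust(p10, method = "BH"))
  # permuted input maps back correctly
  o <- c(3, 1, 10, 5, 2, 8, 7, 4, 9, 6)
  q_perm <- storey_qvalues(p10[o], pi0 = 1)
  expect_identical(as.numeric(q_perm), p.adjust(p10[o], method = "BH"))
  # all-ones: q = pi0
  q1 <- storey_qvalues(rep(1, 20))
  expect_true(all(abs(q1 - attr(q1, "pi0")) < 1e-12))
  # monotone in p
  set.seed(3)
  pr <- stats::runif(500)^1.5
  qr <- storey_qvalues(pr)
  ord <- order(pr)
  expect_true(all(diff(qr[ord]) >= -1e-12))
  expect_true(all(qr >= 0 & qr <= 1))
  expect_error(storey_qvalues(c(0.5, 0)), class = "methylwas_input_error")
  expect_error(storey_qvalues(c(0.5, 1.2)), class = "methylwas_input_error")
})

test_that("candidate selection uses a strict threshold and carries direction", {
  res <- tibble::tibble(
    probe_id = sprintf("cg%d", 1:5),
    estimate = c(1, -2, 0.5, 3, -1),
    p_empirical = c(0.004, 0.005, 0.0049, 0.1, 0.001),
    cpg_island = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  cand <- select_candidates(res, p_threshold = 0.005)
  expect_equal(cand$probe_id, c("cg5", "cg1", "cg3"))  # sorted, 0.005 excluded
  expect_equal(cand$direction, c("-", "+", "+"))
  expect_equal(attr(cand, "n_candidates"), 3)
  expect_equal(attr(cand, "n_island"), 2)
  expect_equal(nrow(select_candidates(res[0, ], 0.005)), 0)
})

test_that("island enrichment matches closed-form binomial results", {
  # 10/10 islands against 0.5: two-sided p = 2 * 0.5^10
  expect_equal(island_enrichment(10, 10, 0.5)$p_value, 2 * 0.5^10,
               tolerance = 1e-12)
  # at the background fraction exactly, p is ~1
  expect_gt(island_enrichment(76, 100, 0.76)$p_value, 0.99)
  expect_error(island_enrichment(tibble::tibble()),
               class = "methylwas_undefined_test_error")
})

test_that("Q-Q data reproduces the uniform grid identity", {
  m <- 200
  p <- (seq_len(m) - 0.5) / m
  qq <- qq_data(sample(p))
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  expect_equal(nrow(qq_data(0.02)), 1)
  expect_error(qq_data(numeric(0)), class = "methylwas_input_error")
})

test_that("theoretical p-values are uniform under a clean null", {
  # no chip effects: the t-distribution reference is exact, so rejections
  # at 0.05 stay inside the exact binomial 99% CI
  study <- tiny_study(n_cases = 30, n_controls = 30, n_probes = 400,
                      chip_sd = 0, missing_rate = 0, seed = 41,
                      covariate_missingness = FALSE)
  prep <- preprocess_signals(study$signals)
  design <- build_design(study$cohort)
  fit <- fit_site_regressions(prep$m, design)
  rej <- sum(fit$p_theoretical < 0.05)
  expect_gte(rej, qbinom(0.005, 400, 0.05))
  expect_lte(rej, qbinom(0.995, 400, 0.05))
})

test_that("run_association ties the stages together and is reproducible", {
  study <- tiny_study(n_cases = 18, n_controls = 18, n_probes = 150,
                      n_true_sites = 5, effect = 1.8, seed = 47)
  prep <- preprocess_signals(study$signals)
  ew <- run_association(prep$m, study$cohort, study$manifest, R = 199,
                        seed = 7)
  expect_s3_class(ew, "methyl_ewas")
  res <- tidy(ew)
  expect_true(all(c("p_empirical", "q_value", "direction", "cpg_island")
                  %in% names(res)))
  expect_true(all(res$p_empirical >= 1 / 200 & res$p_empirical <= 1))
  expect_true(all(res$direction == ifelse(res$estimate > 0, "+", "-")))
  # spiked sites clearly enriched at the empirical-p floor
  spiked <- res$p_empirical[res$probe_id %in% study$truth$true_sites]
  expect_gte(mean(spiked == 1 / 200), 0.6)
  g <- glance(ew)
  expect_equal(g$n_probes, nrow(res))
  ew2 <- run_association(prep$m, study$cohort, study$manifest, R = 199,
                         seed = 7)
  expect_identical(tidy(ew2), res)
})
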