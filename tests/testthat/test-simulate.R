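# Synthetic cohort and signal generator.

test_that("cohort has the requested size and a valid chip layout", {
  cfg <- sim_config(n_cases = 180, n_controls = 187, n_probes = 50, seed = 11)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort), 367)
  expect_equal(sum(cohort$status == "case"), 180)
  expect_equal(sum(cohort$status == "control"), 187)
  # chips hold at most 12 samples, positions unique within a chip
  occ <- table(cohort$chip_id)
  expect_true(all(occ <= 12))
  by_chip <- split(cohort$position_on_chip, cohort$chip_id)
  expect_true(all(vapply(by_chip, anyDuplicated, integer(1)) == 0L))
  expect_true(all(cohort$position_on_chip >= 1 & cohort$position_on_chip <= 12))
  # batches group at most 4 chips
  chips_per_batch <- tapply(cohort$chip_id, cohort$batch_id,
                            function(x) length(unique(x)))
  expect_true(all(chips_per_batch <= 4))
  # cases and controls are interleaved: full chips are very unlikely to be
  # single-status under random placement
  mix <- vapply(split(cohort$status, cohort$chip_id),
                function(s) length(unique(s)), integer(1))
  expect_gt(mean(mix[occ == 12] == 2), 0.8)
  # subtype only for cases
  expect_true(all(is.na(cohort$subtype[cohort$status == "control"])))
  # BSC channels highly correlated and positive
  expect_true(all(cohort$bsc_red > 0 & cohort$bsc_green > 0))
  expect_gt(cor(cohort$bsc_red, cohort$bsc_green), 0.6)
})

test_that("empty cohorts and invalid configurations are rejected", {
  cfg0 <- sim_config(n_cases = 0, n_controls = 0, n_probes = 10,
                     n_true_sites = 0)
  expect_equal(nrow(simulate_cohort(cfg0)), 0)
  expect_error(sim_config(n_cases = -1), class = "methylwas_config_error")
  expect_error(sim_config(n_probes = 5, n_true_sites = 6),
               class = "methylwas_config_error")
  expect_error(sim_config(residual_sd = 0), class = "methylwas_config_error")
  expect_error(sim_config(missing_rate = 1.2), class = "methylwas_config_error")
  cfg_bad <- sim_config(n_cases = 0, n_controls = 0, n_probes = 10,
                        n_true_sites = 2)
  expect_error(simulate_cohort(cfg_bad), class = "methylwas_config_error")
  expect_error(simulate_signals(simulate_cohort(cfg0), cfg0),
               class = "methylwas_config_error")
})

test_that("case smoking frequency matches the cohort margin", {
  # exact binomial 99% CI for p = 0.30 at n = 1000: counts in [263, 338]
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_probes = 10, seed = 1)
  cohort <- simulate_cohort(cfg)
  n_smoke <- sum(cohort$smoker[cohort$status == "case"], na.rm = TRUE)
  expect_gte(n_smoke, 263)
  expect_lte(n_smoke, 338)
  # controls smoke less (0.187 margin): frequency clearly below cases
  p_ctrl <- mean(cohort$smoker[cohort$status == "control"], na.rm = TRUE)
  expect_lt(p_ctrl, 0.25)
})

test_that("identical configurations give bit-identical output", {
  cfg <- sim_config(n_cases = 12, n_controls = 12, n_probes = 80,
                    n_true_sites = 4, effect_size_logit = 1, seed = 99)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a, b)
  sa <- simulate_signals(a, cfg); sb <- simulate_signals(b, cfg)
  expect_identical(sa$signals, sb$signals)
  expect_identical(sa$manifest, sb$manifest)
  expect_identical(sa$truth, sb$truth)
})

test_that("island fraction and beta bimodality match the emulated platform", {
  study <- tiny_study(n_probes = 3000, seed = 7)
  # exact binomial 99% CI for 0.76 at n = 3000: [2219, 2340]
  n_island <- sum(study$manifest$cpg_island)
  expect_gte(n_island, 2219)
  expect_lte(n_island, 2340)
  bm <- compute_beta(study$signals)
  b <- bm$beta[!is.na(bm$beta)]
  lo <- sum(b < 0.2)
  hi <- sum(b > 0.8)
  mid <- sum(b >= 0.4 & b <= 0.6)
  expect_gt(lo, mid)
  expect_gt(hi, mid)
  expect_gt(lo, hi)  # hypomethylated peak dominates
})

test_that("beta recovery is exact when background noise is off", {
  cfg <- sim_config(n_cases = 6, n_controls = 6, n_probes = 40,
                    background_mean = 0, background_sd = 0,
                    missing_rate = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  sim <- simulate_signals(cohort, cfg)
  bm <- compute_beta(sim$signals, mask = FALSE)
  expect_lt(max(abs(bm$beta - sim$truth$beta)), 1e-9)
})

test_that("spiked sites shift cases on the logit scale with known sign", {
  study <- tiny_study(n_cases = 40, n_controls = 40, n_probes = 400,
                      n_true_sites = 10, effect = 2, chip_sd = 0,
                      missing_rate = 0, seed = 21)
  expect_length(study$truth$true_sites, 10)
  expect_true(all(study$truth$true_sites %in% study$manifest$probe_id))
  m <- logit_transform(study$truth$beta)
  case <- study$cohort$status == "case"
  diffs <- rowMeans(m[study$truth$true_sites, case, drop = FALSE]) -
    rowMeans(m[study$truth$true_sites, !case, drop = FALSE])
  expect_true(all(sign(diffs) == study$truth$effect_sign))
  expect_true(all(abs(diffs) > 1))
  # no spiking when effect or count is zero
  study0 <- tiny_study(n_true_sites = 0, seed = 3)
  expect_length(study0$truth$true_sites, 0)
})

test_that("without chip effects, per-chip means are balanced (ANOVA screen)", {
  # at alpha = 0.01 the per-chip ANOVA should not reject for the vast
  # majority of independent simulations
  n_seeds <- 60
  ok <- 0L
  for (s in seq_len(n_seeds)) {
    study <- tiny_study(n_cases = 18, n_controls = 18, n_probes = 120,
                        chip_sd = 0, missing_rate = 0, seed = 1000 + s)
    bm <- compute_beta(study$signals)
    m <- logit_transform(bm$beta)
    sample_means <- colMeans(m, na.rm = TRUE)
    p <- anova(lm(sample_means ~ factor(study$cohort$chip_id)))$`Pr(>F)`[1]
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, ceiling(0.95 * n_seeds))
})

test_that("technical replicates duplicate the source methylation profile", {
  cfg <- sim_config(n_cases = 20, n_controls = 19, n_probes = 150,
                    replicates = TRUE, missing_rate = 0, seed = 13)
  cohort <- simulate_cohort(cfg)
  reps <- cohort[cohort$status == "replicate", ]
  expect_gt(nrow(reps), 0)
  sim <- simulate_signals(cohort, cfg)
  bm <- compute_beta(sim$signals)
  for (i in seq_len(nrow(reps))) {
    r <- bm$beta[, reps$sample_id[i]]
    s <- bm$beta[, reps$replicate_of[i]]
    expect_identical(sim$truth$beta[, reps$sample_id[i]],
                     sim$truth$beta[, reps$replicate_of[i]])
    expect_gt(cor(r, s, use = "complete.obs"), 0.985)
  }
})
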