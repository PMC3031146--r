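# Beta computation, detection, QC filters, logit transform, kNN imputation.

test_that("compute_beta subtracts background and clamps into [0, 1]", {
  # hand arithmetic: M = 3000, U = 1000, background 200 -> 2800/3600
  sig <- make_signals(3000, 1000, c(190, 210))
  expect_equal(compute_beta(sig, mask = FALSE)$beta[1, 1], 2800 / 3600,
               tolerance = 1e-12)
  # symmetry: M = U -> 0.5 whatever the background below the signal
  sig <- make_signals(2500, 2500, c(100, 140))
  expect_equal(compute_beta(sig, mask = FALSE)$beta[1, 1], 0.5)
  # degenerate: both channels at background -> zero denominator -> missing
  sig <- make_signals(200, 200, c(200, 200))
  expect_true(is.na(compute_beta(sig, mask = FALSE)$beta[1, 1]))
  # monotone in M for fixed U and background
  M <- matrix(seq(500, 4000, length.out = 8), 8, 1)
  sig <- make_signals(M, matrix(1000, 8, 1), c(190, 210))
  bvals <- compute_beta(sig, mask = FALSE)$beta[, 1]
  expect_true(all(diff(bvals) > 0))
  expect_true(all(bvals >= 0 & bvals <= 1))
  # negative intensities rejected
  expect_error(compute_beta(make_signals(-1, 10, c(1, 2))),
               class = "methylwas_input_error")
})

test_that("detection p-values follow the Normal background tail", {
  # total at the background mean -> p = 0.5
  neg <- c(150, 250, 200, 180, 220)  # mean 200
  sig <- make_signals(120, 80, neg)  # total = 200
  p <- detection_pvalues(sig)
  expect_equal(p[1, 1], 0.5, tolerance = 1e-12)
  # total 10 SDs above background -> vanishing p
  s <- sd(neg)
  sig10 <- make_signals(200 + 10 * s, 0, neg)
  expect_lt(detection_pvalues(sig10)[1, 1], 1e-15)
  # degenerate controls
  expect_error(detection_pvalues(make_signals(10, 10, c(5, 5))),
               class = "methylwas_degenerate_controls_error")
  # masking: a background-level probe is set missing at alpha = 0.05
  sig_mix <- make_signals(matrix(c(5000, 110), 2, 1), matrix(c(5000, 90), 2, 1),
                          neg)
  bm <- compute_beta(sig_mix)
  expect_false(is.na(bm$beta[1, 1]))
  expect_true(is.na(bm$beta[2, 1]))
})

test_that("sample QC applies call rate, background and separation rules", {
  expect_equal(call_rate_floor(1000), 950L)
  expect_equal(call_rate_floor(27578, 0.95), ceiling(0.95 * 27578))
  study <- tiny_study(n_cases = 8, n_controls = 8, n_probes = 200, seed = 6)
  bm <- compute_beta(study$signals)
  qc <- filter_samples(bm, study$signals)
  expect_equal(nrow(qc$report), 16)
  expect_true(all(qc$report$pass))      # clean simulation passes wholesale
  expect_setequal(qc$samples, colnames(bm$beta))
  # background at exactly the ceiling fails (strict inequality)
  sig_bad <- study$signals
  sig_bad$negative_controls[, 1] <- 1000
  sig_bad$negative_controls[1:2, 1] <- c(900, 1100)  # keep variance, mean 1000
  bm_bad <- compute_beta(sig_bad)
  qc_bad <- filter_samples(bm_bad, sig_bad)
  expect_false(qc_bad$report$pass[1])
  expect_match(qc_bad$report$reasons[1], "background")
  # call-rate failure when most probes are missing
  bm2 <- bm
  bm2$beta[seq_len(150), 2] <- NA
  qc2 <- filter_samples(bm2, study$signals)
  expect_false(qc2$report$pass[2])
  expect_match(qc2$report$reasons[2], "call_rate")
})

test_that("probe filter drops exactly the >= threshold probes", {
  beta <- matrix(stats::runif(30 * 20), 30, 20,
                 dimnames = list(sprintf("p%02d", 1:30), NULL))
  beta[1, 1:9] <- NA    # 9 bad -> kept
  beta[2, 1:10] <- NA   # 10 bad -> dropped
  beta[3, 1:15] <- NA   # 15 bad -> dropped
  pf <- filter_probes(beta, max_bad_samples = 10)
  expect_true("p01" %in% pf$kept)
  expect_setequal(pf$dropped, c("p02", "p03"))
  # kept + dropped partition the input, order preserved
  expect_setequal(c(pf$kept, pf$dropped), rownames(beta))
  expect_identical(pf$kept, rownames(beta)[rownames(beta) %in% pf$kept])
  # fully observed matrix -> nothing dropped
  expect_length(filter_probes(matrix(1, 5, 5))$dropped, 0)
  # random fixture against a brute-force recount
  set.seed(42)
  b2 <- matrix(stats::runif(200 * 25), 200, 25,
               dimnames = list(sprintf("q%03d", 1:200), NULL))
  b2[sample(length(b2), 900)] <- NA
  pf2 <- filter_probes(b2, max_bad_samples = 10)
  recount <- rownames(b2)[apply(b2, 1, function(x) sum(is.na(x))) >= 10]
  expect_setequal(pf2$dropped, recount)
})

test_that("logit transform clamps, inverts and validates eps", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.7778), log(0.7778 / 0.2222), tolerance = 1e-12)
  expect_equal(logit_transform(2800 / 3600), log(3.5), tolerance = 1e-12)
  # boundary clamped but finite
  expect_equal(logit_transform(1), stats::qlogis(1 - 1e-6))
  expect_equal(logit_transform(0), stats::qlogis(1e-6))
  expect_true(is.na(logit_transform(c(0.5, NA))[2]))
  expect_error(logit_transform(0.5, eps = 0), class = "methylwas_parameter_error")
  expect_error(logit_transform(0.5, eps = 0.5), class = "methylwas_parameter_error")
  expect_error(logit_transform(1.5), class = "methylwas_input_error")
  # round trip within 1e-9 for interior values
  b <- seq(1e-5, 1 - 1e-5, length.out = 101)
  expect_lt(max(abs(inv_logit_transform(logit_transform(b)) - b)), 1e-9)
})

test_that("kNN imputation matches its definition and leaves observed data alone", {
  # duplicate neighbours: imputed value equals the duplicates' value
  base <- stats::rnorm(12)
  m <- matrix(rep(base, 11), nrow = 11, byrow = TRUE)  # 11 identical probes
  rownames(m) <- sprintf("p%02d", 1:11)
  m[1, 5] <- NA
  out <- knn_impute(m, k = 10)
  expect_equal(unname(out[1, 5]), base[5], tolerance = 1e-12)
  # k = 1 copies the nearest complete probe
  m2 <- rbind(a = c(1, 2, NA), b = c(1.1, 2.1, 3), c = c(9, 9, 9))
  out2 <- knn_impute(m2, k = 1)
  expect_equal(unname(out2["a", 3]), 3)
  # 50 x 20 with 5% missing equals the brute-force all-pairs oracle
  set.seed(7)
  m3 <- matrix(stats::rnorm(50 * 20), 50, 20,
               dimnames = list(sprintf("p%02d", 1:50), NULL))
  m3[sample(length(m3), round(0.05 * length(m3)))] <- NA
  m3[1, ] <- stats::rnorm(20)  # guarantee some complete probes remain
  out3 <- knn_impute(m3, k = 10)
  expect_equal(out3, knn_oracle(m3, k = 10), tolerance = 1e-12)
  # observed entries unchanged
  obs <- !is.na(m3)
  expect_identical(out3[obs], m3[obs])
  expect_false(anyNA(out3))
  # a probe with no observed entries cannot be imputed
  m4 <- matrix(stats::rnorm(60), 6, 10)
  m4[1, ] <- NA
  expect_error(knn_impute(m4, k = 2), class = "methylwas_impute_error")
})

test_that("the preprocessing pipeline returns a complete M-value matrix", {
  study <- tiny_study(n_cases = 20, n_controls = 20, n_probes = 300, seed = 17)
  prep <- preprocess_signals(study$signals)
  expect_false(anyNA(prep$m))
  expect_equal(ncol(prep$m), 40)
  expect_true(all(rownames(prep$m) %in% study$manifest$probe_id))
  expect_equal(prep$counts$n_probes_kept, length(prep$kept_probes))
})
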