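# Shared fixtures and independent oracles used across test files.

# Tiny signal set from plain numbers: M, U are probes x samples, neg is
# controls x samples (recycled if a vector).
make_signals <- function(M, U, neg) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (is.null(dim(neg))) neg <- matrix(neg, ncol = ncol(M), nrow = length(neg))
  if (is.null(rownames(M))) {
    rownames(M) <- rownames(U) <- sprintf("p%03d", seq_len(nrow(M)))
  }
  if (is.null(colnames(M))) {
    colnames(M) <- colnames(U) <- sprintf("s%03d", seq_len(ncol(M)))
  }
  colnames(neg) <- colnames(M)
  methyl_signals(M, U, neg)
}

# Brute-force kNN imputation oracle following the documented definition:
# candidate neighbours are fully observed probes, distances are Euclidean
# over the target's observed samples, imputed value is the unweighted mean
# of the k nearest candidates at the missing sample.
knn_oracle <- function(m, k) {
  complete <- which(rowSums(is.na(m)) == 0L)
  out <- m
  for (i in which(rowSums(is.na(m)) > 0L)) {
    obs <- which(!is.na(m[i, ]))
    d <- vapply(complete, function(j) sqrt(sum((m[j, obs] - m[i, obs])^2)),
                numeric(1))
    nb <- complete[order(d)[seq_len(k)]]
    for (s in which(is.na(m[i, ]))) {
      out[i, s] <- mean(m[nb, s])
    }
  }
  out
}

# Exhaustive Freeman-Halton oracle: enumerate every table with the observed
# margins, sum the probabilities of tables whose probability does not exceed
# the observed table's (with a small tie tolerance).
fisher_enum_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  log_prob <- function(t) log_const - sum(lgamma(t + 1))
  r <- length(rs); cc <- length(cs)
  tables <- list()
  fill <- function(t, i, remaining_cols) {
    if (i == r) {
      last <- remaining_cols
      if (all(last >= 0) && sum(last) == rs[r]) {
        t[r, ] <- last
        tables[[length(tables) + 1L]] <<- t
      }
      return(invisible())
    }
    cells <- expand.grid(lapply(seq_len(cc), function(j)
      0:min(rs[i], remaining_cols[j])))
    cells <- cells[rowSums(cells) == rs[i], , drop = FALSE]
    for (kk in seq_len(nrow(cells))) {
      row <- as.numeric(cells[kk, ])
      t[i, ] <- row
      fill(t, i + 1L, remaining_cols - row)
    }
  }
  fill(matrix(0, r, cc), 1L, cs)
  lp_obs <- log_prob(tab)
  probs <- vapply(tables, function(t) exp(log_prob(t)), numeric(1))
  sum(probs[probs <= exp(lp_obs) * (1 + 1e-7)])
}

# All permutations of 1..n (n small), for exhaustive randomization checks.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Small fully observed cohort + M-values with optional spiked effects,
# used by association and PCA tests.
tiny_study <- function(n_cases = 24, n_controls = 24, n_probes = 200,
                       n_true_sites = 0, effect = 0, chip_sd = 0.3,
                       seed = 1, missing_rate = 0.01, ...) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_probes = n_probes, n_true_sites = n_true_sites,
                    effect_size_logit = effect, chip_effect_sd = chip_sd,
                    missing_rate = missing_rate, seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  sim <- simulate_signals(cohort, cfg)
  list(cfg = cfg, cohort = cohort, signals = sim$signals,
       manifest = sim$manifest, truth = sim$truth)
}
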