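# shared builders for the test suite; everything is generated in code

tiny_sternberg <- function(seed = 1, n_trials = 12, ...) {
  generate_sternberg_session(generator_config(n_trials = n_trials, seed = seed, ...))
}

test_config <- function(...) analysis_config(n_perm = 200, rng_seed = 42, ...)

# shift every timestamp of a session by a constant (clock-origin change)
shift_session <- function(session, dt) {
  s <- session
  s$events$timestamps <- s$events$timestamps + dt
  ts_cols <- grep("^ts_", names(s$trials), value = TRUE)
  for (cc in ts_cols) s$trials[[cc]] <- ifelse(s$trials[[cc]] == 0, 0,
                                               s$trials[[cc]] + dt)
  s$presentations$onset_time <- s$presentations$onset_time + dt
  s$units <- lapply(s$units, function(u) { u$spike_times <- u$spike_times + dt; u })
  s
}

# brute-force isolation distance: explicit inverse-covariance quadratic form
# and a full sort of all noise distances
oracle_isolation <- function(cluster, noise) {
  n <- nrow(cluster)
  if (nrow(noise) < n) return(NA_real_)
  mu <- colMeans(cluster)
  Sinv <- solve(cov(cluster))
  d2 <- apply(noise, 1, function(p) {
    v <- p - mu
    drop(t(v) %*% Sinv %*% v)
  })
  sort(d2)[n]
}

# direct sum-of-squares repeated-measures F, written with explicit loops
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - gm)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - gm)^2
  ss_tot <- sum((m - gm)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  list(F = (ss_cond / (k - 1)) / (ss_res / ((k - 1) * (n - 1))),
       df1 = k - 1, df2 = (k - 1) * (n - 1))
}

# exhaustive two-group permutation p for the mean-difference statistic
oracle_exact_ttest_p <- function(a, b, alternative = "greater") {
  pooled <- c(a, b); na <- length(a)
  obs <- mean(a) - mean(b)
  sets <- combn(length(pooled), na, simplify = FALSE)
  stats <- sapply(sets, function(ix)
    mean(pooled[ix]) - mean(pooled[-ix]))
  if (alternative == "greater") mean(stats >= obs - 1e-12)
  else mean(abs(stats) >= abs(obs) - 1e-12)
}
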