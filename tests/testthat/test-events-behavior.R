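# TTL parsing, trial reconciliation, behavioural statistics

ev <- function(codes, dt = 1) list(timestamps = seq_along(codes) * dt,
                                   codes = as.integer(codes))

test_that("Sternberg parser follows the event grammar", {
  p <- parse_sternberg_events(ev(c(61, 11, 1, 6, 7, 8, 60)))
  expect_identical(nrow(p), 1L)
  expect_identical(p$load, 1L)
  expect_identical(p$ts_maintenance, 4)   # timestamp of code 6
  expect_identical(p$ts_enc1_end, 4)      # encoding ends at the 6 marker

  p3 <- parse_sternberg_events(ev(c(11, 1, 5, 2, 5, 3, 6, 7, 8)))
  expect_identical(p3$load, 3L)
  expect_identical(c(p3$ts_enc1, p3$ts_enc2, p3$ts_enc3), c(2, 4, 6))
  expect_identical(c(p3$ts_enc1_end, p3$ts_enc2_end), c(3, 5))
})

test_that("grammar violations carry the zero-based stream offset", {
  expect_error(parse_sternberg_events(ev(c(11, 1, 7, 8))), "offset 2")
  expect_error(parse_sternberg_events(ev(c(11, 7))), "offset 1")
  expect_error(parse_sternberg_events(ev(c(11, 1, 6, 7))), "inside a trial")
})

test_that("screening parser pairs onsets with offsets", {
  r <- parse_screening_events(ev(c(61, 1, 3, 1, 3, 4, 60)))
  expect_identical(nrow(r$presentations), 2L)
  expect_length(r$responses, 1L)
  expect_true(all(r$presentations$offset > r$presentations$onset))
  expect_error(parse_screening_events(list(timestamps = numeric(0),
                                           codes = integer(0))), "empty")
  expect_error(parse_screening_events(ev(c(1, 1, 3))), "without preceding end")
})

test_that("generated event streams round-trip through the parser exactly", {
  for (seed in c(1, 2, 3)) {
    s <- tiny_sternberg(seed, n_trials = 20)
    parsed <- parse_sternberg_events(s$events, s$presentations)
    expect_identical(nrow(reconcile_trials(parsed, s$trials, tol = 1e-9)), 0L)
  }
})

test_that("reconcile_trials flags perturbations and count mismatches", {
  s <- tiny_sternberg(4, n_trials = 10)
  parsed <- parse_sternberg_events(s$events, s$presentations)
  st <- s$trials
  st$ts_probe[5] <- st$ts_probe[5] + 0.01
  d <- reconcile_trials(parsed, st, tol = 0.001)
  expect_identical(nrow(d), 1L)
  expect_identical(d$field, "ts_probe")
  expect_identical(d$trial, 5L)

  st2 <- rbind(s$trials, s$trials[10, ])
  d2 <- reconcile_trials(parsed, st2)
  expect_identical(d2$field, "n_trials")
})

test_that("behaviour summaries are consistent and weighted correctly", {
  s <- tiny_sternberg(5, n_trials = 30)
  tr <- s$trials
  tr$response_accuracy <- 1L
  b <- behavior_by_load(tr)
  expect_true(all(b$per_load$accuracy_pct[b$per_load$n_trials > 0] == 100))

  # constant RT
  tr$ts_response <- tr$ts_probe + 0.7
  b2 <- behavior_by_load(tr)
  expect_true(all(abs(b2$per_load$median_rt_s[b2$per_load$n_trials > 0] - 0.7) < 1e-12))

  # overall accuracy is the trial-count-weighted mean of per-load accuracies
  b3 <- behavior_by_load(s$trials)
  pl <- b3$per_load[b3$per_load$n_trials > 0, ]
  expect_equal(b3$overall_accuracy_pct,
               sum(pl$accuracy_pct * pl$n_trials) / sum(pl$n_trials))
})

test_that("generator accuracy converges to the configured p_correct", {
  s <- generate_sternberg_session(generator_config(
    n_trials = 1000, seed = 6, p_correct = 0.9,
    n_units = c(concept = 0L, maintenance = 0L, probe = 0L, null = 0L)))
  acc <- mean(s$trials$response_accuracy)
  band <- qbinom(c(0.025, 0.975), 1000, 0.9) / 1000
  expect_gte(acc, band[1]); expect_lte(acc, band[2])
})

test_that("repeated-measures ANOVA matches its oracles", {
  # identical values across loads: no condition effect
  m0 <- matrix(rep(c(0.5, 0.7, 0.9, 0.6, 0.8), 3), ncol = 3)
  expect_identical(rm_anova_rt(m0)$F, 0)

  set.seed(11)
  m <- matrix(rnorm(15, mean = rep(c(0.7, 0.8, 0.9), each = 5), sd = 0.05), 5)
  fit <- rm_anova_rt(m)
  orc <- oracle_rm_anova(m)
  expect_equal(fit$F, orc$F, tolerance = 1e-9)
  expect_equal(c(fit$df1, fit$df2), c(orc$df1, orc$df2))
  # cross-check against aov with a within-subject error stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:5, 3)), cond = factor(rep(1:3, each = 5)))
  a <- summary(aov(y ~ cond + Error(subj), data = df))
  f_aov <- a[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(fit$F, f_aov, tolerance = 1e-9)

  # the dataset's shape: 21 subjects x 3 loads
  m21 <- matrix(rnorm(63, rep(c(0.7, 0.8, 0.9), each = 21), 0.1), 21)
  fit21 <- rm_anova_rt(m21)
  expect_identical(c(fit21$df1, fit21$df2), c(2L, 40L))
})

test_that("rm ANOVA is invariant to subject order and constant shifts", {
  set.seed(12)
  m <- matrix(rnorm(24, rep(c(1, 1.2, 1.4, 1.1), each = 6), 0.2), 6)
  f1 <- rm_anova_rt(m)$F
  expect_equal(rm_anova_rt(m[sample(6), ])$F, f1, tolerance = 1e-12)
  expect_equal(rm_anova_rt(m + 5)$F, f1, tolerance = 1e-9)
  expect_error(rm_anova_rt(matrix(c(1, NA, 2, 3), 2)), "missing")
})
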