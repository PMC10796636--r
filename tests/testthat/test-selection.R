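# permutation tests and cell-selection procedures

test_that("permutation ANOVA handles degenerate and tiny cases", {
  expect_equal(permutation_anova(rep(3.2, 8), rep(1:2, 4), seed = 1)$p, 1)
  expect_error(permutation_anova(1:5, rep("a", 5)), "2 groups")

  # exhaustive enumeration on a 2+2 instance matches an independent oracle
  x <- c(1.3, 2.1, 8.9, 10.2); g <- c("a", "a", "b", "b")
  r <- permutation_anova(x, g, exact = TRUE)
  f_obs <- anova(lm(x ~ factor(g)))$`F value`[1]
  expect_equal(r$statistic, f_obs, tolerance = 1e-9)
  sets <- combn(4, 2, simplify = FALSE)
  f_all <- sapply(sets, function(ix)
    anova(lm(x[c(ix, setdiff(1:4, ix))] ~ factor(g)))$`F value`[1])
  expect_equal(r$p, mean(f_all >= f_obs - 1e-12))
  expect_identical(r$n_perm, as.integer(choose(4, 2)))
})

test_that("Monte-Carlo ANOVA p agrees with the exhaustive p within its SE", {
  set.seed(21)
  x <- rnorm(9); g <- rep(1:3, each = 3)
  p_ex <- permutation_anova(x, g, exact = TRUE)$p
  p_mc <- permutation_anova(x, g, n_perm = 4000, seed = 9)$p
  expect_lt(abs(p_mc - p_ex), 4 * sqrt(p_ex * (1 - p_ex) / 4000) + 2 / 4000)
  # deterministic given the seed
  expect_identical(permutation_anova(x, g, n_perm = 500, seed = 3)$p,
                   permutation_anova(x, g, n_perm = 500, seed = 3)$p)
})

test_that("permutation t-test matches exhaustive enumeration", {
  a <- c(5.2, 6.1, 7.3); b <- c(1.0, 2.2, 1.8)
  r <- permutation_ttest(a, b, "greater", exact = TRUE)
  expect_equal(r$statistic, mean(a) - mean(b))
  expect_equal(r$p, oracle_exact_ttest_p(a, b, "greater"))
  r2 <- permutation_ttest(a, b, "two.sided", exact = TRUE)
  expect_equal(r2$p, oracle_exact_ttest_p(a, b, "two.sided"))
  # Monte-Carlo consistency
  set.seed(22)
  a3 <- rnorm(5); b3 <- rnorm(5, 0.5)
  p_ex <- permutation_ttest(a3, b3, "greater", exact = TRUE)$p
  p_mc <- permutation_ttest(a3, b3, "greater", n_perm = 4000, seed = 5)$p
  expect_lt(abs(p_mc - p_ex), 4 * sqrt(p_ex * (1 - p_ex) / 4000) + 2 / 4000)

  expect_equal(permutation_ttest(rep(2, 4), rep(2, 4), "greater", seed = 1)$p, 1)
  expect_error(permutation_ttest(numeric(0), 1:3), "non-empty")
})

test_that("permutation p-values obey the add-one convention bounds", {
  # a huge observed effect still cannot give p below 1/(n_perm + 1)
  r <- permutation_ttest(rep(100, 5), rep(0, 5), "greater", n_perm = 199, seed = 2)
  expect_gte(r$p, 1 / 200)
  expect_lte(r$p, 1)
})

test_that("preferred_image takes the maximal mean with lowest-id tie-break", {
  resp <- data.frame(image = rep(1:5, each = 4),
                     rate_hz = c(rep(2, 8), rep(10, 4), rep(2, 8)))
  expect_identical(preferred_image(resp), 3L)
  tie <- data.frame(image = rep(c(4, 2), each = 3), rate_hz = rep(7, 6))
  expect_identical(preferred_image(tie), 2L)
  set.seed(23)
  rnd <- data.frame(image = sample(1:5, 60, TRUE), rate_hz = rexp(60))
  means <- tapply(rnd$rate_hz, rnd$image, mean)
  expect_identical(preferred_image(rnd),
                   as.integer(names(means)[which.max(means)]))
})

test_that("concept selection requires image-identity variation, not mere firing", {
  s <- tiny_sternberg(31, n_trials = 40, n_units = c(concept = 0L,
    maintenance = 0L, probe = 0L, null = 1L))
  # a noiseless unit with an identical burst for EVERY image: the ANOVA has
  # nothing to explain (p = 1) and the unit cannot be a concept cell
  tr <- s$trials
  burst <- function(t0) t0 + 0.2 + seq(0, 0.76, by = 0.04)   # 20 spikes
  sp <- numeric(0)
  for (i in seq_len(nrow(tr))) for (k in 1:3) {
    on <- tr[[paste0("ts_enc", k)]][i]
    if (on != 0) sp <- c(sp, burst(on))
  }
  sp <- c(sp, unlist(lapply(tr$ts_probe, burst)))
  s$units[[1]]$spike_times <- sort(sp)
  s$units[[1]]$waveforms <- NULL
  cl <- classify_concept_cells(s, test_config())
  expect_equal(cl$anova_p[1], 1)
  expect_false(cl$is_concept[1])
})

test_that("a unit responding equally to two images passes the pooled max-vs-rest test", {
  # the secondary test pools all non-preferred responses, so a cell selective
  # for two of five images still qualifies (it is visually selective)
  s <- tiny_sternberg(38, n_trials = 40, n_units = c(concept = 0L,
    maintenance = 0L, probe = 0L, null = 1L))
  tr <- s$trials
  burst <- function(t0) t0 + 0.2 + seq(0, 0.76, by = 0.04)
  sp <- numeric(0)
  for (i in seq_len(nrow(tr))) for (k in 1:3) {
    pic <- tr[[paste0("enc", k, "_pic")]][i]
    if (pic %in% 1:2) sp <- c(sp, burst(tr[[paste0("ts_enc", k)]][i]))
  }
  pr <- s$presentations
  probe_on <- pr$onset_time[seq(4, nrow(pr), by = 4)]
  sp <- c(sp, unlist(lapply(probe_on[tr$probe_pic %in% 1:2], burst)))
  s$units[[1]]$spike_times <- sort(sp)
  s$units[[1]]$waveforms <- NULL
  cl <- classify_concept_cells(s, test_config())
  expect_lt(cl$anova_p[1], 0.05)
  expect_identical(cl$preferred_image[1], 1L)   # tie resolves to lowest id
  expect_lt(cl$maxvsrest_p[1], 0.05)
  expect_true(cl$is_concept[1])
})

test_that("probe elevation equal to encoding elevation is not a probe cell", {
  s <- tiny_sternberg(32, n_trials = 40, n_units = c(concept = 0L,
    maintenance = 0L, probe = 0L, null = 1L))
  tr <- s$trials
  burst <- function(t0) t0 + 0.2 + seq(0, 0.76, by = 0.04)
  sp <- unlist(lapply(tr$ts_probe, burst))
  for (k in 1:3) {
    on <- tr[[paste0("ts_enc", k)]]
    sp <- c(sp, unlist(lapply(on[on != 0], burst)))
  }
  s$units[[1]]$spike_times <- sort(sp)
  s$units[[1]]$waveforms <- NULL
  cl <- classify_cells(s, test_config())
  expect_false(cl$is_probe[1])
  expect_gt(cl$probe_vs_enc_p[1], 0.05)
})

test_that("concept cells persistent only on preferred trials are not maintenance cells", {
  cfg <- generator_config(n_trials = 108, seed = 33,
                          n_units = c(concept = 4L, maintenance = 0L,
                                      probe = 0L, null = 0L),
                          concept_persistent = TRUE, persist_hz = 8,
                          with_waveforms = FALSE)
  s <- generate_sternberg_session(cfg)
  cl <- classify_cells(s, test_config())
  expect_true(all(cl$is_concept))
  # the overall maintenance-vs-baseline test fires on every unit ...
  expect_true(all(cl$maint_p < 0.05))
  # ... but the invariance requirement on non-preferred trials stops (nearly)
  # all of them; each exclusion test runs at level alpha
  expect_lte(sum(cl$is_maintenance), 1L)
})

test_that("screening image selection returns planted images, with fallback", {
  cfg <- generator_config(n_images = 54, seed = 34,
                          n_units = c(concept = 5L, maintenance = 0L,
                                      probe = 0L, null = 2L),
                          with_waveforms = FALSE)
  s <- generate_screening_session(cfg)
  planted <- sort(unique(unlist(lapply(s$units, `[[`, "preferred_image"))))
  sel <- screening_image_selection(s, test_config())
  expect_length(sel, 5L)
  expect_setequal(sel[seq_along(planted)], planted)
  expect_identical(sel, screening_image_selection(s, test_config()))

  cfg0 <- generator_config(n_images = 54, seed = 35,
                           n_units = c(concept = 0L, maintenance = 0L,
                                       probe = 0L, null = 3L),
                           with_waveforms = FALSE)
  s0 <- generate_screening_session(cfg0)
  sel0 <- screening_image_selection(s0, test_config())
  expect_length(unique(sel0), 5L)

  s_small <- s0; s_small$stimuli$images <- s_small$stimuli$images[1:3]
  expect_error(screening_image_selection(s_small, test_config()), "at least 5")
})

test_that("persistence contrast needs at least two concept cells", {
  s <- tiny_sternberg(36, n_trials = 20)
  cl <- classify_cells(s, test_config())
  cl$is_concept <- c(TRUE, rep(FALSE, nrow(cl) - 1))
  expect_error(persistence_contrast(s, cl, test_config()), "at least 2")
})

test_that("classification is invariant to unit order and global time shifts", {
  s <- tiny_sternberg(37, n_trials = 24)
  cfg <- test_config()
  cl <- classify_cells(s, cfg)

  s_rev <- s; s_rev$units <- rev(s$units)
  cl_rev <- classify_cells(s_rev, cfg)
  o <- order(cl$unit_id); orv <- order(cl_rev$unit_id)
  for (col in c("is_concept", "is_maintenance", "is_probe", "preferred_image",
                "anova_p", "maint_p", "probe_vs_enc_p"))
    expect_identical(cl[[col]][o], cl_rev[[col]][orv])

  s_sh <- shift_session(s, 1000)
  cl_sh <- classify_cells(s_sh, cfg)
  for (col in c("is_concept", "is_maintenance", "is_probe", "preferred_image"))
    expect_identical(cl[[col]], cl_sh[[col]])
})
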