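# synthetic-session generator: determinism, task structure, planted effects

test_that("generation is deterministic given the config", {
  cfg <- generator_config(n_trials = 10, seed = 123)
  expect_identical(generate_sternberg_session(cfg), generate_sternberg_session(cfg))
  cfg_s <- generator_config(n_images = 54, seed = 123)
  expect_identical(generate_screening_session(cfg_s), generate_screening_session(cfg_s))
})

test_that("Sternberg sessions have the task's trial structure", {
  s <- generate_sternberg_session(generator_config(n_trials = 108, seed = 1))
  expect_identical(nrow(s$trials), 108L)
  expect_true(all(s$trials$load %in% 1:3))
  expect_identical(nrow(s$presentations), 4L * 108L)
  # timing ranges: fixation 0.9-1.0 s, maintenance 2.5-2.8 s
  fix_dur <- s$trials$ts_enc1 - s$trials$ts_fixation
  expect_true(all(fix_dur >= 0.9 & fix_dur <= 1.0))
  maint_dur <- s$trials$ts_probe - s$trials$ts_maintenance
  expect_true(all(maint_dur >= 2.5 & maint_dur <= 2.8))
  # in-probes are members of the encoding set
  io <- s$trials$probe_in_out == 1
  enc <- cbind(s$trials$enc1_pic, s$trials$enc2_pic, s$trials$enc3_pic)
  expect_true(all(vapply(which(io), function(i)
    s$trials$probe_pic[i] %in% enc[i, ], logical(1))))
})

test_that("planted concept units recover the configured rate contrast", {
  cfg <- generator_config(n_trials = 250, seed = 77,
                          n_units = c(concept = 1L, maintenance = 0L,
                                      probe = 0L, null = 0L),
                          preferred_hz = 10, baseline_hz = 2,
                          with_waveforms = FALSE)
  s <- generate_sternberg_session(cfg)
  u <- s$units[[1]]
  resp <- stimulus_responses(u, s, analysis_config(), include_probe = TRUE)
  pref <- u$preferred_image
  m_pref <- mean(resp$rate_hz[resp$image == pref])
  m_rest <- mean(resp$rate_hz[resp$image != pref])
  expect_gt(sum(resp$image == pref), 100)
  # dead-time thinning shrinks each nominal rate r to about r/(1 + r*dt)
  expected <- 10 / (1 + 10 * 0.003) - 2 / (1 + 2 * 0.003)
  expect_lt(abs((m_pref - m_rest) - expected), 0.9)
})

test_that("screening sessions present each image exactly six times", {
  s <- generate_screening_session(generator_config(n_images = 54, seed = 4))
  expect_identical(nrow(s$presentations), 324L)
  expect_true(all(table(s$presentations$stimulus_index) == 6L))
  expect_error(generate_screening_session(generator_config(n_images = 30, seed = 1)),
               "54-64")
})

test_that("simulate_unit_spikes honours rate, span and dead time", {
  expect_length(simulate_unit_spikes(0, c(0, 100), seed = 1), 0L)
  st <- simulate_unit_spikes(10, c(0, 1000), dead_time = 0, seed = 2)
  expect_lt(abs(length(st) - 10000), 3 * sqrt(10000))
  expect_true(all(st >= 0 & st < 1000))
  expect_true(all(diff(st) > 0))
  st2 <- simulate_unit_spikes(40, c(0, 200), dead_time = 0.003, seed = 3)
  expect_true(all(diff(st2) >= 0.003))
  expect_error(simulate_unit_spikes(-1, c(0, 10)), "rates")
  # piecewise profile concentrates spikes where the rate is high
  prof <- data.frame(time = c(0, 10), rate_hz = c(0, 50))
  st3 <- simulate_unit_spikes(prof, c(0, 20), seed = 4)
  expect_true(all(st3 >= 10))
})

test_that("simulate_waveforms is template plus white noise", {
  w0 <- simulate_waveforms(6, template_id = 1, amplitude = 50, noise_sd = 0,
                           n_samples = 64, seed = 1)
  expect_identical(dim(w0), c(6L, 64L))
  expect_true(all(apply(w0, 1, function(r) identical(r, w0[1, ]))))
  expect_equal(max(abs(w0[1, ])), 50)
  w2 <- simulate_waveforms(6, template_id = 1, amplitude = 100, noise_sd = 0,
                           n_samples = 64)
  expect_equal(max(abs(colMeans(w2))), 2 * max(abs(colMeans(w0))))
  # CLT bound on column means against the noiseless template
  n <- 10000
  tmpl <- simulate_waveforms(1, template_id = 1, amplitude = 50, noise_sd = 0,
                             n_samples = 32)[1, ]
  wn <- simulate_waveforms(n, template_id = 1, amplitude = 50, noise_sd = 8,
                           n_samples = 32, seed = 5)
  expect_true(all(abs(colMeans(wn) - tmpl) < 4 * 8 / sqrt(n)))
})

test_that("gaussian feature clouds have the requested geometry", {
  cl <- make_gaussian_feature_clouds(4000, 4000, dim = 3,
                                     mean_offset = c(5, 0, 0), seed = 6)
  dmeans <- colMeans(cl$noise) - colMeans(cl$cluster)
  expect_true(all(abs(dmeans - c(5, 0, 0)) < 4 * sqrt(2 / 4000)))
  expect_identical(make_gaussian_feature_clouds(10, 10, 2, seed = 9),
                   make_gaussian_feature_clouds(10, 10, 2, seed = 9))
  bad <- matrix(c(1, 2, 2, 1), 2)  # not positive definite
  expect_error(make_gaussian_feature_clouds(5, 5, 2, cov_cluster = bad),
               "positive definite")
})
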