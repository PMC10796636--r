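# waveform features, isolation distance, projection test, SNR

test_that("waveform features have the defined shape and values", {
  set.seed(41)
  w <- simulate_waveforms(50, 1, 60, 10, n_samples = 48, seed = 41)
  fm <- waveform_features(w)
  expect_identical(dim(fm$features), c(50L, 8L))
  expect_identical(colnames(fm$features),
                   c("energy", "peak", "area", paste0("pc", 1:5)))
  expect_equal(fm$features[, "energy"], rowSums(w^2))
  expect_equal(fm$features[, "area"], rowSums(abs(w)))

  # single-sample impulse of height a
  a <- c(-7, 3, 5, -2, 8, 4)
  imp <- matrix(0, 6, 16)
  imp[cbind(1:6, 3:8)] <- a
  fi <- waveform_features(imp)
  expect_equal(unname(fi$features[, "energy"]), a^2)
  expect_equal(unname(fi$features[, "area"]), abs(a))
  expect_equal(unname(fi$features[, "peak"]), a)
})

test_that("waveform PCA matches an independent eigendecomposition", {
  set.seed(42)
  w <- simulate_waveforms(120, 2, 55, 12, n_samples = 40, seed = 42)
  fm <- waveform_features(w)
  expect_lt(max(abs(crossprod(fm$basis) - diag(5))), 1e-9)
  # oracle: eigenvectors of the covariance of the normalized, centred rows
  norm <- w / sqrt(rowSums(w^2))
  ctr <- scale(norm, center = TRUE, scale = FALSE)
  eig <- eigen(cov(ctr), symmetric = TRUE)
  scores_oracle <- ctr %*% eig$vectors[, 1:5]
  for (j in 1:5)
    expect_lt(min(max(abs(fm$features[, 3 + j] - scores_oracle[, j])),
                  max(abs(fm$features[, 3 + j] + scores_oracle[, j]))), 1e-8)
  # degenerate all-zero waveform is flagged, not fatal
  w2 <- rbind(w, 0)
  fm2 <- waveform_features(w2)
  expect_identical(fm2$flagged, 121L)
  expect_true(all(is.na(fm2$features[121, ])))
})

test_that("isolation distance follows its geometric definition", {
  set.seed(43)
  cl <- matrix(rnorm(100 * 3), 100, 3)
  # all noise at the cluster mean -> 0
  no0 <- matrix(rep(colMeans(cl), each = 120), 120, 3)
  expect_equal(isolation_distance(cl, no0), 0)

  # put the 100th-closest noise point at squared Mahalanobis radius 25
  S <- cov(cl); mu <- colMeans(cl)
  eg <- eigen(S, symmetric = TRUE)
  dir1 <- eg$vectors[, 1] * sqrt(eg$values[1])
  near <- matrix(rep(mu, each = 99), 99, 3) +
    outer(seq(0.01, 0.5, length.out = 99), dir1)
  far <- matrix(mu + 5 * dir1, 1, 3)
  d <- isolation_distance(cl, rbind(near, far))
  expect_equal(d, 25, tolerance = 1e-9)

  # fewer noise points than cluster spikes -> undefined
  expect_true(is.na(isolation_distance(cl, cl[1:50, ])))
})

test_that("isolation distance equals the brute-force oracle", {
  for (seed in 1:3) {
    clouds <- make_gaussian_feature_clouds(150, 500, dim = 10,
                                           mean_offset = rep(1.5, 10), seed = seed)
    expect_equal(isolation_distance(clouds$cluster, clouds$noise),
                 oracle_isolation(clouds$cluster, clouds$noise),
                 tolerance = 1e-9)
  }
})

test_that("isolation distance grows as the noise cloud moves away", {
  clouds <- make_gaussian_feature_clouds(80, 200, dim = 4, seed = 7)
  shift_dir <- c(1, 0, 0, 0)
  ds <- vapply(c(0, 1, 2, 4, 8), function(a)
    isolation_distance(clouds$cluster,
                       sweep(clouds$noise, 2, a * shift_dir, `+`)),
    numeric(1))
  expect_true(all(diff(ds) >= 0))
})

test_that("projection distance is symmetric, rigid-motion invariant, and scaled", {
  set.seed(44)
  a <- cbind(rnorm(200, 0, 1), rnorm(200, 0, 1))
  b <- cbind(rnorm(200, 6, 1), rnorm(200, 0, 1))
  d <- projection_distance(a, b)
  # direct oracle: project onto the mean-difference line
  u <- (colMeans(b) - colMeans(a)); u <- u / sqrt(sum(u^2))
  pa <- a %*% u; pb <- b %*% u
  pooled <- sqrt((sum((pa - mean(pa))^2) + sum((pb - mean(pb))^2)) /
                   (length(pa) + length(pb) - 2))
  expect_equal(d, abs(mean(pb) - mean(pa)) / pooled, tolerance = 1e-12)
  expect_lt(abs(d - 6), 0.5)

  expect_equal(projection_distance(b, a), d, tolerance = 1e-12)
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(projection_distance(a %*% R, b %*% R), d, tolerance = 1e-9)
  expect_equal(projection_distance(sweep(a, 2, c(3, -4), `+`),
                                   sweep(b, 2, c(3, -4), `+`)), d,
               tolerance = 1e-9)
  # identical distributions separate by ~0; coincident means exactly 0
  expect_lt(projection_distance(a, a[sample(200), ] + 0), 1e-9)
  expect_identical(projection_distance(rbind(a, a), rbind(a, a)), 0)
})

test_that("SNR metrics follow their definitions and the generator ground truth", {
  # constructed: mean waveform with peak 60, symmetric residuals of size 10
  k <- 64
  mw <- 60 * sin(seq(0, pi, length.out = k))
  r <- rep(10, k)
  w <- rbind(mw + r, mw - r, mw + r, mw - r)
  sn <- snr_metrics(w)
  noise_sd <- sd(as.vector(rbind(r, -r, r, -r)))
  expect_equal(sn$snr_peak, max(abs(mw)) / noise_sd, tolerance = 1e-12)
  expect_equal(sn$snr_mean, mean(abs(mw)) / noise_sd, tolerance = 1e-12)
  # doubling the signal (mean waveform) with the noise held fixed doubles both
  w2 <- rbind(2 * mw + r, 2 * mw - r, 2 * mw + r, 2 * mw - r)
  sn2 <- snr_metrics(w2)
  expect_equal(sn2$snr_peak, 2 * sn$snr_peak, tolerance = 1e-12)
  expect_equal(sn2$snr_mean, 2 * sn$snr_mean, tolerance = 1e-12)

  # generator ground truth: amplitude 66, noise 10 -> snr_peak ~ 6.6
  w3 <- simulate_waveforms(5000, 1, 66, 10, n_samples = 64, seed = 45)
  sn3 <- snr_metrics(w3)
  expect_lt(abs(sn3$snr_peak - 6.6), 0.2)
  expect_error(snr_metrics(w3[1, , drop = FALSE]), "2 spikes")
})

test_that("unit_quality assembles per-unit metrics with same-wire comparisons", {
  s <- tiny_sternberg(46, n_trials = 20)
  q <- unit_quality(s)
  expect_identical(nrow(q), length(s$units))
  expect_true(all(q$pct_isi_below_3ms == 0))       # generator enforces dead time
  expect_true(all(is.finite(q$snr_peak)))
  # two units per electrode: the smaller cluster of each pair has at least as
  # many noise events as members, so its isolation distance is defined; the
  # larger one is undefined by the noise-count contract
  for (el in unique(q$electrode_id)) {
    pair <- q[q$electrode_id == el, ]
    expect_true(is.finite(pair$isolation_distance[which.min(pair$n_spikes)]))
  }
  pw <- attr(q, "pairwise")
  expect_identical(nrow(pw), 4L)
  expect_true(all(pw$distance >= 0))
  # a unit alone on its wire has undefined isolation distance
  s2 <- s; s2$units <- s$units[1]
  q2 <- unit_quality(s2)
  expect_true(is.na(q2$isolation_distance[1]))
})
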