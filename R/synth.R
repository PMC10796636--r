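# Ground-truth-labelled synthetic sessions. The generator reproduces the
# task's trial grammar and TTL streams exactly, so parser round trips are
# testable, and plants units of four classes (concept, maintenance, probe,
# null) as inhomogeneous Poisson processes with an absolute dead time.

#' Sample an inhomogeneous Poisson spike train with refractory dead time
#'
#' Piecewise-constant rate; spikes closer than `dead_time` to the previous
#' accepted spike are removed (absolute refractory pruning), so the realized
#' rate is slightly below the nominal rate by a factor of roughly
#' `1/(1 + rate * dead_time)`.
#'
#' @param rate_profile either a single non-negative rate (Hz) or a
#'   data.frame with columns `time` and `rate_hz` giving a step function:
#'   rate is `rate_hz[i]` on `[time[i], time[i+1])` and the last value holds
#'   to the end of `span`.
#' @param span length-2 numeric, the half-open simulation interval (seconds).
#' @param dead_time minimum allowed ISI, seconds.
#' @param seed optional integer seed (current RNG stream if `NULL`).
#' @return strictly increasing spike times in `[span[1], span[2])` with all
#'   ISIs `>= dead_time`.
#' @export
#' @examples
#' simulate_unit_spikes(0, c(0, 10))          # empty
#' length(simulate_unit_spikes(10, c(0, 100), seed = 1))
simulate_unit_spikes <- function(rate_profile, span, dead_time = 0, seed = NULL) {
  if (length(span) != 2L || span[2] <= span[1]) stopf("span must satisfy t1 > t0")
  if (is.numeric(rate_profile) && length(rate_profile) == 1L)
    rate_profile <- data.frame(time = span[1], rate_hz = rate_profile)
  if (any(rate_profile$rate_hz < 0)) stopf("rates must be >= 0")
  if (is.unsorted(rate_profile$time, strictly = TRUE)) stopf("profile breakpoints must increase")
  with_seed(seed, {
    t0 <- c(rate_profile$time, span[2])
    t0[1] <- max(t0[1], span[1])
    spikes <- vector("list", nrow(rate_profile))
    for (i in seq_len(nrow(rate_profile))) {
      a <- max(t0[i], span[1]); b <- min(t0[i + 1], span[2])
      if (b <= a || rate_profile$rate_hz[i] == 0) next
      n <- stats::rpois(1, rate_profile$rate_hz[i] * (b - a))
      if (n) spikes[[i]] <- a + sort(stats::runif(n)) * (b - a)
    }
    st <- sort(unlist(spikes))
    if (dead_time > 0 && length(st) > 1) {
      keep <- logical(length(st)); keep[1] <- TRUE; last <- st[1]
      for (i in 2:length(st)) {
        if (st[i] - last >= dead_time) { keep[i] <- TRUE; last <- st[i] }
      }
      st <- st[keep]
    }
    st %||% numeric(0)
  })
}

# biphasic action-potential templates, peak-normalized to 1
spike_template <- function(n_samples, template_id = 1L) {
  t <- seq(0, 1, length.out = n_samples)
  y <- switch(as.integer(template_id),
    exp(-((t - 0.35) / 0.06)^2) - 0.45 * exp(-((t - 0.55) / 0.12)^2),
    exp(-((t - 0.40) / 0.09)^2) - 0.30 * exp(-((t - 0.62) / 0.15)^2),
    stopf("unknown template_id %s", template_id))
  y / max(abs(y))
}

#' Simulate spike waveforms as a scaled template plus white noise
#'
#' @param n number of spikes (rows).
#' @param template_id which built-in biphasic template (1 or 2).
#' @param amplitude template peak amplitude, microvolts.
#' @param noise_sd additive Gaussian noise SD, microvolts.
#' @param n_samples samples per waveform.
#' @param seed optional seed.
#' @return `n x n_samples` matrix; each sample has expectation
#'   `amplitude * template`.
#' @export
simulate_waveforms <- function(n, template_id = 1L, amplitude = 66,
                               noise_sd = 10, n_samples = 256L, seed = NULL) {
  if (n < 0) stopf("n must be >= 0")
  tmpl <- amplitude * spike_template(n_samples, template_id)
  with_seed(seed, {
    m <- matrix(tmpl, nrow = n, ncol = n_samples, byrow = TRUE)
    if (noise_sd > 0 && n > 0)
      m <- m + matrix(stats::rnorm(n * n_samples, sd = noise_sd), nrow = n)
    m
  })
}

#' Sample two labelled Gaussian point clouds
#'
#' Oracle inputs for the cluster-quality metrics: a "cluster" cloud and a
#' "noise" cloud from specified multivariate normals.
#'
#' @param n_cluster,n_noise point counts.
#' @param dim dimensionality.
#' @param mean_offset length-`dim` mean of the noise cloud relative to the
#'   cluster (cluster mean is the origin).
#' @param cov_cluster,cov_noise covariance matrices (default identity).
#' @param seed optional seed.
#' @return list with matrices `cluster` and `noise`.
#' @export
make_gaussian_feature_clouds <- function(n_cluster, n_noise, dim,
                                         mean_offset = rep(0, dim),
                                         cov_cluster = diag(dim),
                                         cov_noise = diag(dim), seed = NULL) {
  if (length(mean_offset) != dim) stopf("mean_offset must have length dim")
  chol_c <- tryCatch(chol(cov_cluster), error = function(e) stopf("cov_cluster is not positive definite"))
  chol_n <- tryCatch(chol(cov_noise), error = function(e) stopf("cov_noise is not positive definite"))
  with_seed(seed, {
    cl <- matrix(stats::rnorm(n_cluster * dim), n_cluster) %*% chol_c
    no <- matrix(stats::rnorm(n_noise * dim), n_noise) %*% chol_n
    no <- sweep(no, 2, mean_offset, `+`)
    list(cluster = cl, noise = no)
  })
}

# Merge a baseline rate with elevated intervals into a step profile.
# Overlapping elevations take the maximum rate.
make_rate_profile <- function(span, baseline_hz, elevated = NULL) {
  if (is.null(elevated) || nrow(elevated) == 0)
    return(data.frame(time = span[1], rate_hz = baseline_hz))
  brk <- sort(unique(c(span[1], elevated$start, elevated$end)))
  brk <- brk[brk >= span[1] & brk < span[2]]
  rate <- vapply(brk, function(t) {
    cov <- elevated$rate_hz[elevated$start <= t & elevated$end > t]
    if (length(cov)) max(baseline_hz, cov) else baseline_hz
  }, numeric(1))
  keep <- c(TRUE, diff(rate) != 0)
  data.frame(time = brk[keep], rate_hz = rate[keep])
}

synth_electrodes <- function(n_electrodes) {
  areas <- rep_len(c("Hipp", "Amg", "dACC", "preSMA", "vmPFC"), n_electrodes)
  data.frame(electrode_id = seq_len(n_electrodes), brain_area = areas,
             mni_x = round(stats::runif(n_electrodes, -35, 35), 1),
             mni_y = round(stats::runif(n_electrodes, -40, 20), 1),
             mni_z = round(stats::runif(n_electrodes, -30, 30), 1),
             orig_channel = seq_len(n_electrodes) + 16L,
             stringsAsFactors = FALSE)
}

# unit roster: class labels, preferred images for concept units, electrode
# assignment (two units per electrode so same-wire metrics are defined),
# alternating waveform templates within an electrode
synth_unit_plan <- function(config) {
  classes <- rep(names(config$n_units), config$n_units)
  n <- length(classes)
  if (n == 0) return(data.frame())
  data.frame(
    unit_id = seq_len(n), class = classes,
    preferred = ifelse(classes == "concept",
                       ((cumsum(classes == "concept") - 1L) %% config$n_images) + 1L,
                       NA_integer_),
    electrode_id = (((seq_len(n) - 1L) %/% 2L) %% config$n_electrodes) + 1L,
    template_id = ((seq_len(n) - 1L) %% 2L) + 1L,
    stringsAsFactors = FALSE)
}

synth_unit_record <- function(plan_row, elevated, span, config, trials = NULL) {
  useed <- derive_seed(config$seed, 1000L + plan_row$unit_id)
  st <- simulate_unit_spikes(
    make_rate_profile(span, config$baseline_hz, elevated),
    span, dead_time = config$dead_time, seed = useed)
  wf <- NULL
  if (config$with_waveforms) {
    amp <- config$waveform_amplitude *
      with_seed(derive_seed(config$seed, 2000L + plan_row$unit_id), stats::runif(1, 0.7, 1.3))
    wf <- simulate_waveforms(length(st), plan_row$template_id, amp,
                             config$waveform_noise_sd, config$n_samples,
                             seed = derive_seed(config$seed, 3000L + plan_row$unit_id))
  }
  make_unit(plan_row$unit_id, plan_row$electrode_id, st, wf,
            ground_truth = plan_row$class,
            preferred_image = if (is.na(plan_row$preferred)) NULL else plan_row$preferred)
}

#' Generate a synthetic Sternberg session
#'
#' Builds a full session: a trials table with the task's timing structure
#' (fixation 900--1000 ms, 1--3 one-second encoding images with 1--200 ms
#' blanks, 2.5--2.8 s maintenance, probe until response), the exact TTL event
#' stream for that structure, the stimulus presentation log (4 referenced
#' images per trial with the null image, id 5 zero-based, standing in for
#' absent encoding slots at +10 ms offsets), and ground-truth-labelled units.
#'
#' Concept units elevate to `preferred_hz` from `response_latency` after
#' every onset of their preferred image (encoding and probe); maintenance
#' units elevate during every delay period; probe units after every probe
#' onset; null units are homogeneous Poisson at `baseline_hz`. With
#' `concept_persistent = TRUE`, concept units additionally fire at
#' `persist_hz` during the delay of trials whose encoding set contains their
#' preferred image.
#'
#' @param config a [generator_config()].
#' @return a `wm_session` that passes [validate_session()].
#' @export
#' @examples
#' s <- generate_sternberg_session(generator_config(n_trials = 8, seed = 42))
#' nrow(s$trials)
generate_sternberg_session <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) stopf("config must be a generator_config")
  if (config$n_images != 5L) stopf("Sternberg sessions use 5 images")
  with_seed(config$seed, {
    nt <- config$n_trials
    loads <- sample(1:3, nt, replace = TRUE, prob = config$load_probabilities)
    enc <- matrix(0L, nt, 3)
    for (i in seq_len(nt)) {
      pics <- sample.int(config$n_images, loads[i],
                         replace = config$allow_encoding_repeats)
      enc[i, seq_len(loads[i])] <- pics
    }
    probe_in <- stats::rbinom(nt, 1, 0.5)
    probe <- integer(nt)
    for (i in seq_len(nt)) {
      inset <- unique(enc[i, enc[i, ] != 0])
      outset <- setdiff(seq_len(config$n_images), inset)
      if (length(outset) == 0) probe_in[i] <- 1L
      probe[i] <- if (probe_in[i] == 1) inset[sample.int(length(inset), 1)]
                  else outset[sample.int(length(outset), 1)]
    }
    acc <- stats::rbinom(nt, 1, config$p_correct)
    rt <- config$rt_shift + stats::rlnorm(
      nt, meanlog = log(config$rt_median[loads] - config$rt_shift),
      sdlog = config$rt_sdlog)

    trials <- empty_trials(nt)
    trials$load <- loads
    trials$enc1_pic <- enc[, 1]; trials$enc2_pic <- enc[, 2]; trials$enc3_pic <- enc[, 3]
    trials$probe_pic <- probe; trials$probe_in_out <- probe_in
    trials$response_accuracy <- acc

    ev_t <- 1.0; ev <- list(t = 1.0, c = 61L)
    add_ev <- function(t, code) { ev$t <<- c(ev$t, t); ev$c <<- c(ev$c, code) }
    pres_idx <- integer(0); pres_t <- numeric(0)
    t <- 2.0
    for (i in seq_len(nt)) {
      trials$ts_fixation[i] <- t; add_ev(t, 11L)
      t <- t + stats::runif(1, config$fixation_range[1], config$fixation_range[2])
      slot_t <- numeric(3)
      for (k in seq_len(loads[i])) {
        onset <- t
        trials[[paste0("ts_enc", k)]][i] <- onset
        add_ev(onset, as.integer(k))
        slot_t[k] <- onset
        t <- onset + config$image_duration
        trials[[paste0("ts_enc", k, "_end")]][i] <- t
        if (k < loads[i]) {
          add_ev(t, 5L)
          t <- t + stats::runif(1, config$blank_range[1], config$blank_range[2])
        }
      }
      trials$ts_maintenance[i] <- t; add_ev(t, 6L)
      t <- t + stats::runif(1, config$maintenance_range[1], config$maintenance_range[2])
      trials$ts_probe[i] <- t; add_ev(t, 7L)
      t <- t + rt[i]
      trials$ts_response[i] <- t; add_ev(t, 8L)
      # presentation log: 4 referenced images per trial, null at +10 ms steps
      last_t <- slot_t[loads[i]]
      for (k in 1:3) {
        if (k <= loads[i]) {
          pres_idx <- c(pres_idx, enc[i, k] - 1L); pres_t <- c(pres_t, slot_t[k])
        } else {
          last_t <- last_t + 0.010
          pres_idx <- c(pres_idx, 5L); pres_t <- c(pres_t, last_t)
        }
      }
      pres_idx <- c(pres_idx, probe[i] - 1L); pres_t <- c(pres_t, trials$ts_probe[i])
      t <- t + stats::runif(1, config$iti_range[1], config$iti_range[2])
    }
    add_ev(t + 1.0, 60L)
    events <- list(timestamps = ev$t, codes = ev$c)
    span <- c(0, t + 2.0)

    electrodes <- synth_electrodes(config$n_electrodes)
    plan <- synth_unit_plan(config)
    units <- list()
    if (nrow(plan)) units <- lapply(seq_len(nrow(plan)), function(j) {
      p <- plan[j, ]
      elev <- switch(p$class,
        null = NULL,
        maintenance = data.frame(start = trials$ts_maintenance,
                                 end = trials$ts_maintenance + 2.5,
                                 rate_hz = config$maintenance_hz),
        probe = data.frame(start = trials$ts_probe + config$response_latency,
                           end = trials$ts_probe + config$response_latency + 1.0,
                           rate_hz = config$probe_hz),
        concept = {
          on <- pres_t[pres_idx == p$preferred - 1L]
          e <- if (length(on))
            data.frame(start = on + config$response_latency,
                       end = on + config$response_latency + config$image_duration,
                       rate_hz = config$preferred_hz)
          else NULL
          if (config$concept_persistent) {
            pref_tr <- trials$enc1_pic == p$preferred |
              trials$enc2_pic == p$preferred | trials$enc3_pic == p$preferred
            if (any(pref_tr))
              e <- rbind(e, data.frame(start = trials$ts_maintenance[pref_tr],
                                       end = trials$ts_maintenance[pref_tr] + 2.5,
                                       rate_hz = config$persist_hz))
          }
          e
        })
      synth_unit_record(p, elev, span, config)
    })

    wm_session(
      subject = list(subject_id = sprintf("S%03d", config$seed %% 1000L),
                     native_id = sprintf("P%02dXX", config$seed %% 90L + 10L),
                     age = 35L, sex = "M", task = "sternberg"),
      electrodes = electrodes, units = units, events = events, trials = trials,
      stimuli = list(images = c(paste0("image_", 1:5), "null"), null_index = 5L),
      presentations = data.frame(stimulus_index = pres_idx, onset_time = pres_t)
    )
  })
}

#' Generate a synthetic screening session
#'
#' Presents each of `n_images` (54--64) images exactly six times in seeded
#' random order for 1 s each with a 16--200 ms inter-stimulus interval, with
#' occasional control-question responses, and the matching TTL stream
#' (start 61, picture on 1 / off 3, response 4, end 60). Concept units
#' elevate after onsets of their preferred image; maintenance/probe classes
#' have no substrate in this task and are generated as null units.
#'
#' @param config a [generator_config()] with `n_images` between 54 and 64.
#' @return a `wm_session` (empty trials table).
#' @export
generate_screening_session <- function(config = generator_config(n_images = 54L)) {
  if (!inherits(config, "generator_config")) stopf("config must be a generator_config")
  if (config$n_images < 54L || config$n_images > 64L)
    stopf("screening sessions use 54-64 images (got %d)", config$n_images)
  with_seed(config$seed, {
    order6 <- sample(rep(seq_len(config$n_images), 6L))
    n_pres <- length(order6)
    ev_t <- numeric(0); ev_c <- integer(0)
    add_ev <- function(t, code) { ev_t <<- c(ev_t, t); ev_c <<- c(ev_c, code) }
    add_ev(1.0, 61L)
    pres_t <- numeric(n_pres)
    next_q <- sample(config$control_question_every[1]:config$control_question_every[2], 1)
    t <- 2.0
    for (i in seq_len(n_pres)) {
      pres_t[i] <- t; add_ev(t, 1L)
      t <- t + config$image_duration; add_ev(t, 3L)
      if (i == next_q) {
        t <- t + stats::runif(1, 0.5, 1.5); add_ev(t, 4L)
        t <- t + stats::runif(1, 0.3, 0.8)
        next_q <- i + sample(config$control_question_every[1]:config$control_question_every[2], 1)
      }
      t <- t + stats::runif(1, config$isi_range[1], config$isi_range[2])
    }
    add_ev(t + 1.0, 60L)
    span <- c(0, t + 2.0)

    electrodes <- synth_electrodes(config$n_electrodes)
    plan <- synth_unit_plan(config)
    units <- list()
    if (nrow(plan)) units <- lapply(seq_len(nrow(plan)), function(j) {
      p <- plan[j, ]
      elev <- if (p$class == "concept") {
        on <- pres_t[order6 == p$preferred]
        if (length(on))
          data.frame(start = on + config$response_latency,
                     end = on + config$response_latency + config$image_duration,
                     rate_hz = config$preferred_hz)
      } else NULL
      synth_unit_record(p, elev, span, config)
    })

    wm_session(
      subject = list(subject_id = sprintf("S%03d", config$seed %% 1000L),
                     native_id = sprintf("P%02dXX", config$seed %% 90L + 10L),
                     age = 35L, sex = "F", task = "screening"),
      electrodes = electrodes, units = units,
      events = list(timestamps = ev_t, codes = ev_c),
      trials = empty_trials(),
      stimuli = list(images = paste0("image_", seq_len(config$n_images)),
                     null_index = NA_integer_),
      presentations = data.frame(stimulus_index = order6 - 1L, onset_time = pres_t)
    )
  })
}
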