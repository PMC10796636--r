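#' Analysis configuration
#'
#' Collects the constants used by the firing-rate, classification and quality
#' modules: the response windows for each trial period, the permutation-test
#' settings, PSTH parameters, and the ISI refractory-violation threshold.
#'
#' The defaults encode the conventions of the Sternberg task analysis:
#' stimulus responses are measured 200--1000 ms after image onset, maintenance
#' activity over the first 2500 ms of the delay, the baseline over 500 ms of
#' the fixation period, and probe responses 200--1000 ms after probe onset.
#'
#' @param window_stim_on two reals, seconds after stimulus onset bounding the
#'   encoding/screening response window (half-open).
#' @param window_maintenance two reals, seconds after maintenance onset.
#' @param window_baseline length of the baseline window in seconds, anchored
#'   at fixation onset (or ending at encoding onset when
#'   `baseline_last = TRUE`).
#' @param window_probe two reals, seconds after probe onset.
#' @param alpha per-test significance level for all cell-selection tests.
#' @param n_perm number of Monte-Carlo label permutations (at least 100).
#' @param psth_bin,psth_smooth PSTH bin width and Gaussian kernel width,
#'   seconds. The kernel width is interpreted as the SD unless
#'   `smooth_as_fwhm = TRUE`.
#' @param isi_violation_threshold ISIs below this (seconds) count as
#'   refractory-period violations.
#' @param rng_seed integer root seed; all permutation randomness in
#'   [classify_cells()] is derived from it deterministically.
#' @param baseline_last use the last `window_baseline` seconds of fixation
#'   instead of the first.
#' @param smooth_as_fwhm interpret `psth_smooth` as FWHM rather than SD.
#' @param concept_pool_probe pool probe-period presentations with encoding
#'   presentations in the concept-cell ANOVA (set `FALSE` for encoding-only).
#' @return an object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config(n_perm = 200, rng_seed = 7)
#' cfg$window_stim_on
analysis_config <- function(window_stim_on = c(0.200, 1.000),
                            window_maintenance = c(0.0, 2.500),
                            window_baseline = 0.500,
                            window_probe = c(0.200, 1.000),
                            alpha = 0.05,
                            n_perm = 1000L,
                            psth_bin = 0.050,
                            psth_smooth = 0.075,
                            isi_violation_threshold = 0.003,
                            rng_seed = 1L,
                            baseline_last = FALSE,
                            smooth_as_fwhm = FALSE,
                            concept_pool_probe = TRUE) {
  for (w in list(window_stim_on, window_maintenance, window_probe)) {
    if (length(w) != 2L || !all(is.finite(w)) || diff(w) <= 0)
      stopf("analysis windows must be length-2 with positive length")
  }
  if (!is.finite(window_baseline) || window_baseline <= 0)
    stopf("window_baseline must be a positive duration")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (!is_count(n_perm) || n_perm < 100) stopf("n_perm must be an integer >= 100")
  if (psth_bin <= 0 || psth_smooth < 0) stopf("psth_bin must be > 0 and psth_smooth >= 0")
  if (isi_violation_threshold <= 0) stopf("isi_violation_threshold must be > 0")
  structure(list(
    window_stim_on = as.numeric(window_stim_on),
    window_maintenance = as.numeric(window_maintenance),
    window_baseline = as.numeric(window_baseline),
    window_probe = as.numeric(window_probe),
    alpha = alpha, n_perm = as.integer(n_perm),
    psth_bin = psth_bin, psth_smooth = psth_smooth,
    isi_violation_threshold = isi_violation_threshold,
    rng_seed = as.integer(rng_seed),
    baseline_last = isTRUE(baseline_last),
    smooth_as_fwhm = isTRUE(smooth_as_fwhm),
    concept_pool_probe = isTRUE(concept_pool_probe)
  ), class = "analysis_config")
}

#' Synthetic-session generator configuration
#'
#' Parameters of the ground-truth-labelled session generator. Task timings
#' follow the Sternberg protocol: fixation 900--1000 ms, encoding images of
#' 1 s separated by 1--200 ms blanks, a 2.5--2.8 s maintenance delay, probe
#' until response; screening shows each image six times for 1 s with a
#' 16--200 ms inter-stimulus interval. Unit classes spike as inhomogeneous
#' Poisson processes with an absolute refractory dead time:
#' concept units elevate to `preferred_hz` 200 ms after onsets of their
#' preferred image, maintenance units to `maintenance_hz` throughout every
#' delay period, probe units to `probe_hz` after probe onset, and null units
#' stay at `baseline_hz`. When `concept_persistent = TRUE` concept units also
#' fire at `persist_hz` during the delay of trials holding their preferred
#' image (and only those), which is the substrate of the persistent-activity
#' contrast.
#'
#' @param n_trials number of Sternberg trials (sessions used 108 or 135).
#' @param n_images number of distinct images: 5 for Sternberg, 54--64 for
#'   screening.
#' @param load_probabilities sampling weights for memory loads 1--3.
#' @param n_units named integer vector with counts per ground-truth class
#'   (`concept`, `maintenance`, `probe`, `null`).
#' @param baseline_hz,preferred_hz,maintenance_hz,probe_hz,persist_hz firing
#'   rates (Hz) for the unit classes; see Details.
#' @param dead_time absolute refractory dead time, seconds.
#' @param fixation_range,blank_range,maintenance_range,isi_range,iti_range
#'   uniform sampling ranges (seconds) for the respective task intervals.
#' @param image_duration encoding/screening image duration, seconds.
#' @param response_latency visual response latency of concept/probe units,
#'   seconds.
#' @param p_correct per-trial probability of a correct behavioural response.
#' @param rt_median,rt_shift,rt_sdlog shifted-lognormal reaction-time model:
#'   per-load medians, common shift, and log-scale SD.
#' @param concept_persistent plant delay-period persistence in concept units.
#' @param allow_encoding_repeats allow the same image at several encoding
#'   positions within one trial.
#' @param with_waveforms attach template-plus-noise spike waveforms to units.
#' @param n_samples waveform samples per spike.
#' @param waveform_amplitude,waveform_noise_sd template peak amplitude and
#'   additive white-noise SD, microvolts.
#' @param n_electrodes number of simulated microwires.
#' @param control_question_every screening only: range of presentation counts
#'   between control questions.
#' @param seed integer seed; the whole session is a deterministic function of
#'   the config.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_trials = 108L,
                             n_images = 5L,
                             load_probabilities = c(1, 1, 1) / 3,
                             n_units = c(concept = 2L, maintenance = 2L, probe = 2L, null = 2L),
                             baseline_hz = 2,
                             preferred_hz = 10,
                             maintenance_hz = 8,
                             probe_hz = 8,
                             persist_hz = 6,
                             dead_time = 0.003,
                             fixation_range = c(0.900, 1.000),
                             image_duration = 1.0,
                             blank_range = c(0.001, 0.200),
                             maintenance_range = c(2.5, 2.8),
                             isi_range = c(0.016, 0.200),
                             iti_range = c(1.5, 2.5),
                             response_latency = 0.200,
                             p_correct = 0.89,
                             rt_median = c(0.70, 0.80, 0.90),
                             rt_shift = 0.20,
                             rt_sdlog = 0.30,
                             concept_persistent = FALSE,
                             allow_encoding_repeats = FALSE,
                             with_waveforms = TRUE,
                             n_samples = 256L,
                             waveform_amplitude = 66,
                             waveform_noise_sd = 10,
                             n_electrodes = 8L,
                             control_question_every = c(8L, 12L),
                             seed = 1L) {
  rates <- c(baseline_hz, preferred_hz, maintenance_hz, probe_hz, persist_hz)
  if (any(!is.finite(rates)) || any(rates < 0)) stopf("all rates must be finite and >= 0")
  if (dead_time < 0) stopf("dead_time must be >= 0")
  if (length(load_probabilities) != 3L || any(load_probabilities < 0) ||
      any(load_probabilities > 1) || abs(sum(load_probabilities) - 1) > 1e-9)
    stopf("load_probabilities must be 3 values in [0,1] summing to 1")
  if (!is_count(n_trials) || n_trials < 1) stopf("n_trials must be a positive integer")
  if (!is_count(n_images) || n_images < 1) stopf("n_images must be a positive integer")
  if (p_correct < 0 || p_correct > 1) stopf("p_correct must lie in [0,1]")
  need <- c("concept", "maintenance", "probe", "null")
  if (is.null(names(n_units)) || !all(need %in% names(n_units)))
    stopf("n_units must be named with classes %s", paste(need, collapse = ", "))
  if (any(rt_median - rt_shift <= 0)) stopf("rt_median must exceed rt_shift for every load")
  structure(list(
    n_trials = as.integer(n_trials), n_images = as.integer(n_images),
    load_probabilities = as.numeric(load_probabilities),
    n_units = vapply(n_units[need], as.integer, integer(1)),
    baseline_hz = baseline_hz, preferred_hz = preferred_hz,
    maintenance_hz = maintenance_hz, probe_hz = probe_hz, persist_hz = persist_hz,
    dead_time = dead_time,
    fixation_range = fixation_range, image_duration = image_duration,
    blank_range = blank_range, maintenance_range = maintenance_range,
    isi_range = isi_range, iti_range = iti_range,
    response_latency = response_latency,
    p_correct = p_correct, rt_median = rt_median, rt_shift = rt_shift,
    rt_sdlog = rt_sdlog,
    concept_persistent = isTRUE(concept_persistent),
    allow_encoding_repeats = isTRUE(allow_encoding_repeats),
    with_waveforms = isTRUE(with_waveforms), n_samples = as.integer(n_samples),
    waveform_amplitude = waveform_amplitude, waveform_noise_sd = waveform_noise_sd,
    n_electrodes = as.integer(n_electrodes),
    control_question_every = as.integer(control_question_every),
    seed = as.integer(seed)
  ), class = "generator_config")
}
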