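# Windowed firing rates, PSTHs, and ISI statistics. All windows are
# half-open [t0, t1), so adjacent windows partition time and each spike is
# counted exactly once.

#' Mean firing rate in a half-open window
#'
#' @param spikes spike times, seconds.
#' @param t0,t1 window bounds; the window is `[t0, t1)`.
#' @return rate in Hz.
#' @export
rate_in_window <- function(spikes, t0, t1) {
  if (t1 <= t0) stopf("window must have positive length (t1 > t0)")
  count_in_window(spikes, t0, t1) / (t1 - t0)
}

#' Per-trial period firing rates
#'
#' For every trial: the baseline rate over the first `window_baseline`
#' seconds of fixation (or the last, with `baseline_last`), encoding rates
#' over `window_stim_on` after each image onset (`NA` for absent encoding
#' periods, never zero-filled), the maintenance rate over
#' `window_maintenance` after delay onset, and the probe rate over
#' `window_probe` after probe onset.
#'
#' @param unit a unit record or a numeric vector of spike times.
#' @param trials a Sternberg trials table.
#' @param config an [analysis_config()].
#' @return data.frame with columns `trial_id`, `baseline_hz`,
#'   `enc1_hz`..`enc3_hz`, `maintenance_hz`, `probe_hz`.
#' @export
trial_period_rates <- function(unit, trials, config = analysis_config()) {
  spikes <- if (is.list(unit)) unit$spike_times else unit
  n <- nrow(trials)
  rate_or_na <- function(ts, w0, w1) {
    vapply(seq_len(n), function(i) {
      if (ts[i] == 0) NA_real_ else rate_in_window(spikes, ts[i] + w0, ts[i] + w1)
    }, numeric(1))
  }
  base <- if (config$baseline_last) {
    # last window_baseline seconds of fixation, i.e. ending at encoding onset
    vapply(seq_len(n), function(i)
      rate_in_window(spikes, trials$ts_enc1[i] - config$window_baseline,
                     trials$ts_enc1[i]), numeric(1))
  } else {
    rate_or_na(trials$ts_fixation, 0, config$window_baseline)
  }
  data.frame(
    trial_id = trials$trial_id,
    baseline_hz = base,
    enc1_hz = rate_or_na(trials$ts_enc1, config$window_stim_on[1], config$window_stim_on[2]),
    enc2_hz = rate_or_na(trials$ts_enc2, config$window_stim_on[1], config$window_stim_on[2]),
    enc3_hz = rate_or_na(trials$ts_enc3, config$window_stim_on[1], config$window_stim_on[2]),
    maintenance_hz = rate_or_na(trials$ts_maintenance, config$window_maintenance[1],
                                config$window_maintenance[2]),
    probe_hz = rate_or_na(trials$ts_probe, config$window_probe[1], config$window_probe[2]))
}

#' Peristimulus time histogram
#'
#' Bins spikes relative to alignment events, averages over events, and
#' applies Gaussian-kernel smoothing to the binned rates. The raw
#' (unsmoothed) counts are retained and conserve the total spike count in
#' the aligned windows.
#'
#' @param spikes spike times, seconds.
#' @param align_times alignment event times (e.g. stimulus onsets).
#' @param window length-2 window around each event, seconds; its width must
#'   be a whole number of bins.
#' @param bin bin width, seconds.
#' @param smooth_sd Gaussian kernel width, seconds (SD, or FWHM with
#'   `smooth_as_fwhm`); 0 disables smoothing.
#' @param smooth_as_fwhm interpret `smooth_sd` as full width at half
#'   maximum.
#' @return object of class `psth`: `bin_edges`, smoothed `rate_hz`, raw
#'   `raw_hz`, total `counts` per bin, `n_events`.
#' @export
#' @examples
#' p <- psth(runif(500, 0, 100), align_times = seq(5, 95, 10),
#'           window = c(-0.5, 1), bin = 0.05, smooth_sd = 0.075)
#' sum(p$counts)
psth <- function(spikes, align_times, window = c(-0.5, 1.5), bin = 0.050,
                 smooth_sd = 0.075, smooth_as_fwhm = FALSE) {
  if (bin <= 0) stopf("bin must be > 0")
  if (length(align_times) == 0) stopf("no alignment events")
  nb <- round(diff(window) / bin)
  if (nb < 1 || abs(nb * bin - diff(window)) > 1e-9)
    stopf("window width must be a whole number of bins")
  edges <- window[1] + bin * (0:nb)
  counts <- integer(nb)
  for (t in align_times) {
    rel <- spikes - t
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges,
                                               rightmost.closed = FALSE), nb)
  }
  n_ev <- length(align_times)
  raw <- counts / (bin * n_ev)
  sm <- raw
  if (smooth_sd > 0) {
    sd_bins <- (if (smooth_as_fwhm) smooth_sd / (2 * sqrt(2 * log(2))) else smooth_sd) / bin
    half <- max(1L, ceiling(4 * sd_bins))
    kern <- stats::dnorm(-half:half, sd = sd_bins)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), raw, numeric(half))
    sm <- vapply(seq_len(nb), function(i) sum(padded[i:(i + 2 * half)] * rev(kern)),
                 numeric(1))
  }
  structure(list(bin_edges = edges, rate_hz = sm, raw_hz = raw,
                 counts = counts, n_events = n_ev, bin = bin),
            class = "psth")
}

#' @export
plot.psth <- function(x, ...) {
  mid <- x$bin_edges[-1] - x$bin / 2
  plot(mid, x$rate_hz, type = "l", xlab = "time from event (s)",
       ylab = "rate (Hz)", ...)
  graphics::lines(mid, x$raw_hz, col = "grey70")
  invisible(x)
}

#' ISI refractory-violation percentage
#'
#' @param spikes spike times, seconds.
#' @param threshold violation threshold, seconds (3 ms by default).
#' @return list with `pct_below` (percent of consecutive ISIs below the
#'   threshold; `NA` with fewer than two spikes) and `n_isi`.
#' @export
isi_metrics <- function(spikes, threshold = 0.003) {
  if (length(spikes) < 2)
    return(list(pct_below = NA_real_, n_isi = 0L))
  isi <- diff(spikes)
  list(pct_below = 100 * mean(isi < threshold), n_isi = length(isi))
}

#' CV2 local spike-train irregularity
#'
#' Mean over consecutive ISI pairs (a, b) of `2|a - b| / (a + b)`: 0 for a
#' perfectly regular train and approximately 1 for Poisson firing.
#'
#' @param spikes spike times (needs at least 3 spikes).
#' @return CV2 value, or `NA` when undefined.
#' @export
cv2_score <- function(spikes) {
  if (length(spikes) < 3) return(NA_real_)
  isi <- diff(spikes)
  a <- isi[-length(isi)]; b <- isi[-1]
  mean(2 * abs(b - a) / (a + b))
}

#' Session-wide mean firing rate
#'
#' Spike count over the task span (first to last event timestamp) divided
#' by the span length.
#'
#' @param unit a unit record or numeric spike times.
#' @param session the session providing the event span.
#' @return rate in Hz.
#' @export
session_mean_rate <- function(unit, session) {
  spikes <- if (is.list(unit) && !is.null(unit$spike_times)) unit$spike_times else unit
  ts <- session$events$timestamps
  if (length(ts) < 2 || diff(range(ts)) <= 0) stopf("session has a zero-length task span")
  span <- range(ts)
  sum(spikes >= span[1] & spikes <= span[2]) / diff(span)
}
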