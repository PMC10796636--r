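# Waveform feature extraction and cluster-quality metrics. The clustering
# feature space is energy, peak amplitude, total area under the waveform,
# and the first five principal components of the energy-normalized
# waveforms, with the PCA fit on all spikes of a channel pooled.

#' Waveform clustering features
#'
#' Per spike: `energy` (sum of squared samples), `peak` (signed value of
#' the sample with maximal magnitude), `area` (sum of absolute samples),
#' and the scores on the first five principal components of the
#' energy-normalized (row divided by sqrt(energy)), centred waveforms --
#' eight feature columns in total. Call it on all spikes of one electrode
#' pooled so that the PCA basis is shared by the units being compared.
#'
#' @param waveforms numeric matrix, spikes x samples (at least 6 spikes).
#' @return object of class `feature_matrix`: list with `features`
#'   (n x 8), the orthonormal PCA `basis` (samples x 5), `sdev`, and
#'   `flagged` (indices of degenerate all-zero waveforms, whose feature
#'   rows are `NA`).
#' @export
waveform_features <- function(waveforms) {
  w <- as.matrix(waveforms)
  n <- nrow(w)
  if (n < 6) stopf("PCA features need at least 6 spikes (got %d)", n)
  energy <- rowSums(w^2)
  flagged <- which(energy == 0)
  peak <- w[cbind(seq_len(n), max.col(abs(w), ties.method = "first"))]
  area <- rowSums(abs(w))
  norm <- w / sqrt(pmax(energy, .Machine$double.xmin))
  ok <- setdiff(seq_len(n), flagged)
  pc <- matrix(NA_real_, n, 5)
  ctr <- colMeans(norm[ok, , drop = FALSE])
  sv <- svd(sweep(norm[ok, , drop = FALSE], 2, ctr), nu = 0, nv = 5)
  basis <- sv$v
  pc[ok, ] <- sweep(norm[ok, , drop = FALSE], 2, ctr) %*% basis
  feats <- cbind(energy, peak, area, pc)
  feats[flagged, ] <- NA_real_
  colnames(feats) <- c("energy", "peak", "area", paste0("pc", 1:5))
  structure(list(features = feats, basis = basis,
                 sdev = sv$d[1:5] / sqrt(max(1, length(ok) - 1)),
                 flagged = flagged),
            class = "feature_matrix")
}

#' Isolation distance of a cluster
#'
#' The squared Mahalanobis distance -- under the cluster's own mean and
#' covariance -- of the n-th closest non-member ("noise") point, where n is
#' the cluster size: the squared radius of the ellipsoid that contains as
#' many noise points as the cluster has members. Undefined (`NA` with a
#' `reason` attribute) when the noise set is smaller than the cluster or
#' the cluster covariance is singular.
#'
#' @param cluster feature rows of the cluster's spikes (needs more rows
#'   than columns).
#' @param noise feature rows of all other same-channel spikes.
#' @return squared Mahalanobis distance, or `NA`.
#' @export
isolation_distance <- function(cluster, noise) {
  cluster <- as.matrix(cluster); noise <- as.matrix(noise)
  d <- ncol(cluster)
  if (nrow(cluster) < d + 1) {
    return(structure(NA_real_, reason = "cluster smaller than dimension + 1"))
  }
  n <- nrow(cluster)
  if (nrow(noise) < n) {
    return(structure(NA_real_, reason = "fewer noise events than cluster spikes"))
  }
  S <- stats::cov(cluster)
  d2 <- tryCatch(stats::mahalanobis(noise, colMeans(cluster), S),
                 error = function(e) NULL)
  if (is.null(d2)) return(structure(NA_real_, reason = "singular cluster covariance"))
  sort(d2)[n]
}

#' Projection test between two same-channel clusters
#'
#' Projects the points of both clusters onto the line joining the cluster
#' means and reports the separation of the projected means in units of the
#' pooled within-cluster SD of the projections.
#'
#' @param cluster_a,cluster_b feature (or raw waveform) rows of the two
#'   clusters.
#' @return separation in SD units; 0 by convention when the means coincide.
#' @export
projection_distance <- function(cluster_a, cluster_b) {
  a <- as.matrix(cluster_a); b <- as.matrix(cluster_b)
  if (!nrow(a) || !nrow(b)) stopf("both clusters must be non-empty")
  u <- colMeans(b) - colMeans(a)
  len <- sqrt(sum(u^2))
  if (len == 0) return(0)
  u <- u / len
  pa <- drop(a %*% u); pb <- drop(b %*% u)
  na <- length(pa); nb <- length(pb)
  if (na + nb < 3) stopf("need at least 3 points to estimate the projected SD")
  pooled_var <- (sum((pa - mean(pa))^2) + sum((pb - mean(pb))^2)) / (na + nb - 2)
  if (pooled_var == 0) return(Inf)
  abs(mean(pb) - mean(pa)) / sqrt(pooled_var)
}

#' Waveform signal-to-noise ratios
#'
#' Noise SD is the SD of the residuals (each waveform minus the mean
#' waveform) pooled over all samples and spikes. `snr_peak` divides the
#' peak magnitude of the mean waveform by it; `snr_mean` averages
#' `|mean waveform| / noise SD` over samples.
#'
#' @param waveforms spikes x samples matrix (at least 2 spikes).
#' @return list with `snr_peak` and `snr_mean` (`NA` with a reason if the
#'   residual SD is zero).
#' @export
snr_metrics <- function(waveforms) {
  w <- as.matrix(waveforms)
  if (nrow(w) < 2) stopf("SNR needs at least 2 spikes")
  mw <- colMeans(w)
  resid <- sweep(w, 2, mw)
  noise_sd <- stats::sd(as.vector(resid))
  if (!is.finite(noise_sd) || noise_sd == 0)
    return(list(snr_peak = structure(NA_real_, reason = "zero residual SD"),
                snr_mean = NA_real_))
  list(snr_peak = max(abs(mw)) / noise_sd, snr_mean = mean(abs(mw)) / noise_sd)
}

#' Spike-sorting quality metrics for every unit of a session
#'
#' Per unit: ISI refractory-violation percentage, session mean rate, CV2,
#' the two SNR measures, the isolation distance and the pairwise projection
#' distances against other units on the same electrode. The clustering feature
#' space is fit per electrode on all of its spikes pooled; a unit's "noise"
#' set is every same-electrode spike assigned to another cluster, so units
#' alone on their wire get an undefined isolation distance.
#'
#' @param session a `wm_session` whose units carry waveforms.
#' @param config an [analysis_config()] (ISI threshold).
#' @return object of class `unit_quality`: data.frame with one row per
#'   unit; pairwise projection distances in `attr(, "pairwise")`.
#' @export
unit_quality <- function(session, config = analysis_config()) {
  units <- session$units
  n <- length(units)
  out <- data.frame(
    unit_id = vapply(units, `[[`, integer(1), "unit_id"),
    electrode_id = vapply(units, `[[`, integer(1), "electrode_id"),
    n_spikes = vapply(units, function(u) length(u$spike_times), integer(1)),
    pct_isi_below_3ms = NA_real_, mean_rate_hz = NA_real_, cv2 = NA_real_,
    snr_peak = NA_real_, snr_mean = NA_real_, isolation_distance = NA_real_,
    mean_proj_dist = NA_real_)
  out$brain_area <- session$electrodes$brain_area[
    match(out$electrode_id, session$electrodes$electrode_id)]
  pairwise <- list()
  for (j in seq_len(n)) {
    u <- units[[j]]
    out$pct_isi_below_3ms[j] <- isi_metrics(u$spike_times,
                                            config$isi_violation_threshold)$pct_below
    out$mean_rate_hz[j] <- session_mean_rate(u, session)
    out$cv2[j] <- cv2_score(u$spike_times)
    if (!is.null(u$waveforms) && nrow(u$waveforms) >= 2) {
      sn <- snr_metrics(u$waveforms)
      out$snr_peak[j] <- as.numeric(sn$snr_peak)
      out$snr_mean[j] <- as.numeric(sn$snr_mean)
    }
  }
  # per-electrode feature space: isolation distance and projection test
  for (el in unique(out$electrode_id)) {
    members <- which(out$electrode_id == el &
                       vapply(units, function(u) !is.null(u$waveforms), logical(1)))
    members <- members[out$n_spikes[members] > 0]
    if (length(members) < 2) next
    wf_all <- do.call(rbind, lapply(units[members], `[[`, "waveforms"))
    if (nrow(wf_all) < 6) next
    owner <- rep(members, out$n_spikes[members])
    fm <- waveform_features(wf_all)$features
    keep <- stats::complete.cases(fm)
    for (j in members) {
      cl <- fm[owner == j & keep, , drop = FALSE]
      no <- fm[owner != j & keep, , drop = FALSE]
      out$isolation_distance[j] <- as.numeric(isolation_distance(cl, no))
    }
    prs <- utils::combn(members, 2, simplify = FALSE)
    for (pr in prs) {
      dme <- projection_distance(fm[owner == pr[1] & keep, , drop = FALSE],
                                 fm[owner == pr[2] & keep, , drop = FALSE])
      pairwise[[length(pairwise) + 1L]] <-
        data.frame(unit_a = out$unit_id[pr[1]], unit_b = out$unit_id[pr[2]],
                   electrode_id = el, distance = dme)
    }
  }
  pw <- if (length(pairwise)) do.call(rbind, pairwise) else
    data.frame(unit_a = integer(0), unit_b = integer(0),
               electrode_id = integer(0), distance = numeric(0))
  for (j in seq_len(n)) {
    ds <- pw$distance[pw$unit_a == out$unit_id[j] | pw$unit_b == out$unit_id[j]]
    if (length(ds)) out$mean_proj_dist[j] <- mean(ds)
  }
  structure(out, class = c("unit_quality", "data.frame"), pairwise = pw)
}

#' @export
summary.unit_quality <- function(object, ...) {
  num <- function(x) x[is.finite(x)]
  s <- function(x) {
    x <- num(x)
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x), n = length(x))
  }
  tab <- rbind(pct_isi_below_3ms = s(object$pct_isi_below_3ms),
               mean_rate_hz = s(object$mean_rate_hz),
               cv2 = s(object$cv2),
               snr_peak = s(object$snr_peak),
               snr_mean = s(object$snr_mean),
               proj_dist = s(attr(object, "pairwise")$distance),
               isolation_distance = s(object$isolation_distance))
  structure(list(table = tab, n_units = nrow(object)),
            class = "summary.unit_quality")
}

#' @export
print.summary.unit_quality <- function(x, ...) {
  cat(sprintf("Spike-sorting quality over %d units (mean, SD, median, n defined)\n",
              x$n_units))
  print(round(x$table, 3))
  invisible(x)
}

#' @export
print.unit_quality <- function(x, ...) {
  cat(sprintf("<unit_quality> %d units; %d same-electrode pairs\n",
              nrow(x), nrow(attr(x, "pairwise"))))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE, digits = 3)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
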