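# Permutation-based cell selection: concept cells (stimulus-identity
# selectivity during encoding), maintenance cells (delay-period elevation
# over baseline, invariant to content), probe cells (probe-period elevation
# over both encoding and maintenance), and the persistent-activity contrast
# across the concept-cell population.

#' Per-presentation stimulus responses of a unit
#'
#' One row per stimulus presentation with the image identity and the firing
#' rate in the stimulus-onset window. Sternberg: encoding presentations at
#' all positions are pooled; probe presentations are appended when
#' `include_probe`. Screening: one row per presentation of the log.
#'
#' @param unit unit record or spike-time vector.
#' @param session a `wm_session`.
#' @param config an [analysis_config()].
#' @param include_probe pool probe presentations with encoding ones
#'   (Sternberg only).
#' @return data.frame with `image` (1-based id), `rate_hz`, `period`
#'   (`"enc"`/`"probe"`/`"screen"`).
#' @export
stimulus_responses <- function(unit, session, config = analysis_config(),
                               include_probe = config$concept_pool_probe) {
  spikes <- if (is.list(unit)) unit$spike_times else unit
  w <- config$window_stim_on
  if (session$subject$task == "screening") {
    pr <- session$presentations
    return(data.frame(
      image = pr$stimulus_index + 1L,
      rate_hz = vapply(pr$onset_time, function(t)
        rate_in_window(spikes, t + w[1], t + w[2]), numeric(1)),
      period = "screen", stringsAsFactors = FALSE))
  }
  tr <- session$trials
  rows <- list()
  for (k in 1:3) {
    pic <- tr[[paste0("enc", k, "_pic")]]
    on <- tr[[paste0("ts_enc", k)]]
    sel <- pic != 0L
    if (any(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        image = pic[sel],
        rate_hz = vapply(on[sel], function(t)
          rate_in_window(spikes, t + w[1], t + w[2]), numeric(1)),
        period = "enc", stringsAsFactors = FALSE)
  }
  if (include_probe) {
    wp <- config$window_probe
    rows[[length(rows) + 1L]] <- data.frame(
      image = tr$probe_pic,
      rate_hz = vapply(tr$ts_probe, function(t)
        rate_in_window(spikes, t + wp[1], t + wp[2]), numeric(1)),
      period = "probe", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Preferred image of a unit
#'
#' The image with the maximal mean response over its presentations; exact
#' ties resolve to the lowest image id.
#'
#' @param responses a data.frame with `image` and `rate_hz` (typically
#'   encoding rows of [stimulus_responses()]).
#' @return integer image id.
#' @export
preferred_image <- function(responses) {
  if (!nrow(responses)) stopf("no presentations to rank")
  means <- tapply(responses$rate_hz, responses$image, mean)
  ids <- as.integer(names(means))
  ids[order(-means, ids)][1]
}

empty_classification <- function(units) {
  data.frame(
    unit_id = vapply(units, `[[`, integer(1), "unit_id"),
    electrode_id = vapply(units, `[[`, integer(1), "electrode_id"),
    is_concept = NA, is_maintenance = NA, is_probe = NA,
    preferred_image = NA_integer_,
    anova_p = NA_real_, maxvsrest_p = NA_real_,
    maint_p = NA_real_, maint_nonpref_p = NA_real_,
    probe_vs_enc_p = NA_real_, probe_vs_maint_p = NA_real_)
}

#' Concept-cell classification
#'
#' A unit is a concept cell when (i) a permutation one-way ANOVA of its
#' stimulus-window responses with image identity as the factor (x groups,
#' x = number of unique images in the session) is significant, and (ii) a
#' one-sided permutation t-test shows the responses to its maximal
#' (preferred) image exceed the pooled responses to all other images. The
#' preferred image is determined from encoding presentations.
#'
#' @param session a `wm_session`.
#' @param config an [analysis_config()].
#' @param result optional partial classification table to update.
#' @return classification data.frame with `is_concept`, `preferred_image`,
#'   `anova_p`, `maxvsrest_p` filled.
#' @export
classify_concept_cells <- function(session, config = analysis_config(),
                                   result = NULL) {
  res <- result %||% empty_classification(session$units)
  for (j in seq_along(session$units)) {
    u <- session$units[[j]]
    resp <- stimulus_responses(u, session, config)
    enc <- resp[resp$period != "probe", , drop = FALSE]
    an <- permutation_anova(resp$rate_hz, resp$image, n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 1L))
    pref <- preferred_image(enc)
    tt <- permutation_ttest(resp$rate_hz[resp$image == pref],
                            resp$rate_hz[resp$image != pref],
                            alternative = "greater", n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 2L))
    res$preferred_image[j] <- pref
    res$anova_p[j] <- an$p
    res$maxvsrest_p[j] <- tt$p
    res$is_concept[j] <- an$p < config$alpha && tt$p < config$alpha
  }
  res
}

trial_has_image <- function(trials, image) {
  trials$enc1_pic == image | trials$enc2_pic == image | trials$enc3_pic == image
}

#' Maintenance-cell classification
#'
#' A unit is a maintenance cell when its delay-period rate exceeds its
#' fixation-baseline rate across trials (one-sided permutation test). A unit
#' that is also a concept cell must in addition show the elevation on trials
#' that do NOT contain its preferred image, so that strong concept cells are
#' not automatically classified as maintenance cells.
#'
#' @inheritParams classify_concept_cells
#' @param result classification table with the concept columns already
#'   filled (from [classify_concept_cells()]).
#' @export
classify_maintenance_cells <- function(session, config = analysis_config(),
                                       result) {
  res <- result
  for (j in seq_along(session$units)) {
    u <- session$units[[j]]
    rates <- trial_period_rates(u, session$trials, config)
    tt <- permutation_ttest(rates$maintenance_hz, rates$baseline_hz,
                            alternative = "greater", n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 3L))
    res$maint_p[j] <- tt$p
    ok <- tt$p < config$alpha
    if (ok && isTRUE(res$is_concept[j])) {
      sel <- !trial_has_image(session$trials, res$preferred_image[j])
      if (sum(sel) >= 2) {
        tt2 <- permutation_ttest(rates$maintenance_hz[sel], rates$baseline_hz[sel],
                                 alternative = "greater", n_perm = config$n_perm,
                                 seed = derive_seed(config$rng_seed, u$unit_id, 4L))
        res$maint_nonpref_p[j] <- tt2$p
        ok <- tt2$p < config$alpha
      } else {
        ok <- FALSE   # no non-preferred trials to demonstrate invariance on
      }
    }
    res$is_maintenance[j] <- ok
  }
  res
}

#' Probe-cell classification
#'
#' A unit is a probe cell when its probe-window rate exceeds both its
#' encoding-window rates (pooled across all encoding periods) and its
#' maintenance-window rates, by two separate one-sided permutation t-tests.
#'
#' @inheritParams classify_maintenance_cells
#' @export
classify_probe_cells <- function(session, config = analysis_config(), result) {
  res <- result
  for (j in seq_along(session$units)) {
    u <- session$units[[j]]
    rates <- trial_period_rates(u, session$trials, config)
    enc_pool <- c(rates$enc1_hz, rates$enc2_hz, rates$enc3_hz)
    enc_pool <- enc_pool[!is.na(enc_pool)]
    t1 <- permutation_ttest(rates$probe_hz, enc_pool, alternative = "greater",
                            n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 5L))
    t2 <- permutation_ttest(rates$probe_hz, rates$maintenance_hz,
                            alternative = "greater", n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 6L))
    res$probe_vs_enc_p[j] <- t1$p
    res$probe_vs_maint_p[j] <- t2$p
    res$is_probe[j] <- t1$p < config$alpha && t2$p < config$alpha
  }
  res
}

#' Classify all units of a session
#'
#' Runs the three selection procedures (concept, maintenance, probe) over
#' every unit. All permutation seeds are derived deterministically from
#' `config$rng_seed` and the unit id, so the result is reproducible and
#' invariant to unit ordering.
#'
#' @param session a validated Sternberg `wm_session`.
#' @param config an [analysis_config()].
#' @return object of class `cell_classification`: a data.frame with one row
#'   per unit (`is_concept`, `is_maintenance`, `is_probe`,
#'   `preferred_image`, and all component p-values), with the config and
#'   electrode areas attached as attributes.
#' @export
#' @examples
#' \donttest{
#' s <- generate_sternberg_session(generator_config(n_trials = 40, seed = 5))
#' cl <- classify_cells(s, analysis_config(n_perm = 200))
#' summary(cl)
#' }
classify_cells <- function(session, config = analysis_config()) {
  if (session$subject$task != "sternberg")
    stopf("classify_cells expects a Sternberg session; see screening_image_selection")
  res <- classify_concept_cells(session, config)
  res <- classify_maintenance_cells(session, config, res)
  res <- classify_probe_cells(session, config, res)
  area <- session$electrodes$brain_area[match(res$electrode_id,
                                              session$electrodes$electrode_id)]
  res$brain_area <- area
  gt <- vapply(session$units, function(u) u$ground_truth %||% NA_character_, character(1))
  if (any(!is.na(gt))) res$ground_truth <- gt
  structure(res, class = c("cell_classification", "data.frame"),
            config = config, subject_id = session$subject$subject_id)
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("<cell_classification> %d units (subject %s): %d concept, %d maintenance, %d probe\n",
              nrow(x), attr(x, "subject_id") %||% "?",
              sum(x$is_concept), sum(x$is_maintenance), sum(x$is_probe)))
  utils::str(as.data.frame(x), give.attr = FALSE, vec.len = 3)
  invisible(x)
}

#' @export
summary.cell_classification <- function(object, ...) {
  grp <- ifelse(object$brain_area %in% MTL_AREAS, "MTL",
                ifelse(object$brain_area %in% MFC_AREAS, "MFC", "other"))
  tab <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    data.frame(region = g, n_units = sum(sel),
               n_concept = sum(object$is_concept[sel]),
               pct_concept = 100 * mean(object$is_concept[sel]),
               n_maintenance = sum(object$is_maintenance[sel]),
               pct_maintenance = 100 * mean(object$is_maintenance[sel]),
               n_probe = sum(object$is_probe[sel]),
               pct_probe = 100 * mean(object$is_probe[sel]))
  }))
  structure(list(by_region = tab, n_units = nrow(object)),
            class = "summary.cell_classification")
}

#' @export
print.summary.cell_classification <- function(x, ...) {
  cat(sprintf("Cell classification over %d units\n", x$n_units))
  print(x$by_region, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the screening images for the Sternberg task
#'
#' Scores every unit of a screening session with a permutation ANOVA over
#' its stimulus-window responses (image as factor). The preferred images of
#' significant units, ranked by F and deduplicated, are selected; if fewer
#' than `k` result, the remaining slots are filled with the images carrying
#' the strongest non-selective responses (largest across-unit peak mean
#' response).
#'
#' @param session a screening `wm_session`.
#' @param config an [analysis_config()].
#' @param k number of images to select (5 for the Sternberg task).
#' @return integer vector of `k` image ids (1-based).
#' @export
screening_image_selection <- function(session, config = analysis_config(), k = 5L) {
  if (session$subject$task != "screening") stopf("expected a screening session")
  K <- length(session$stimuli$images)
  if (K < k) stopf("session has %d images, need at least %d", K, k)
  stats_per_unit <- lapply(session$units, function(u) {
    resp <- stimulus_responses(u, session, config)
    an <- permutation_anova(resp$rate_hz, resp$image, n_perm = config$n_perm,
                            seed = derive_seed(config$rng_seed, u$unit_id, 11L))
    means <- tapply(resp$rate_hz, resp$image, mean)
    list(F = an$statistic, p = an$p, pref = preferred_image(resp), means = means)
  })
  sig <- Filter(function(s) s$p < config$alpha, stats_per_unit)
  sig <- sig[order(-vapply(sig, `[[`, numeric(1), "F"))]
  chosen <- unique(vapply(sig, `[[`, integer(1), "pref"))
  chosen <- chosen[seq_len(min(k, length(chosen)))]
  if (length(chosen) < k) {
    peak <- rep(-Inf, K)
    for (s in stats_per_unit) {
      ids <- as.integer(names(s$means))
      peak[ids] <- pmax(peak[ids], as.numeric(s$means))
    }
    remaining <- setdiff(order(-peak), chosen)
    chosen <- c(chosen, remaining[seq_len(k - length(chosen))])
  }
  as.integer(chosen)
}

#' Persistent-activity contrast across concept cells
#'
#' For each concept cell, the mean maintenance-window rate on trials whose
#' encoding set contains its preferred image versus trials where it does
#' not; the population contrast is a paired one-sided t-test across cells
#' (preferred exceeding non-preferred).
#'
#' @param session a Sternberg `wm_session`.
#' @param classification a `cell_classification` for that session.
#' @param config an [analysis_config()].
#' @return list with `mean_pref_hz`, `mean_nonpref_hz`, `p`, `n_cells`, and
#'   the per-cell rate pairs in `per_cell`.
#' @export
persistence_contrast <- function(session, classification,
                                 config = analysis_config()) {
  idx <- which(classification$is_concept)
  if (length(idx) < 2) stopf("persistence contrast needs at least 2 concept cells")
  uid <- vapply(session$units, `[[`, integer(1), "unit_id")
  per <- do.call(rbind, lapply(idx, function(j) {
    u <- session$units[[match(classification$unit_id[j], uid)]]
    rates <- trial_period_rates(u, session$trials, config)
    has <- trial_has_image(session$trials, classification$preferred_image[j])
    data.frame(unit_id = u$unit_id,
               pref_hz = mean(rates$maintenance_hz[has]),
               nonpref_hz = mean(rates$maintenance_hz[!has]))
  }))
  tt <- stats::t.test(per$pref_hz, per$nonpref_hz, paired = TRUE,
                      alternative = "greater")
  list(mean_pref_hz = mean(per$pref_hz), mean_nonpref_hz = mean(per$nonpref_hz),
       p = tt$p.value, n_cells = nrow(per), per_cell = per)
}
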