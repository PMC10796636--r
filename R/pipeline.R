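# Dataset-level driver: run every analysis stage over a directory of
# sessions and aggregate the per-session outputs into the summary tables
# (unit counts by area, selective-cell proportions by region group,
# behaviour, quality-metric distributions).

region_group <- function(area) {
  ifelse(area %in% MTL_AREAS, "MTL", ifelse(area %in% MFC_AREAS, "MFC", "other"))
}

analyze_session <- function(session, config) {
  cls <- if (session$subject$task == "sternberg") classify_cells(session, config)
  beh <- if (session$subject$task == "sternberg" && nrow(session$trials))
    behavior_by_load(session$trials)
  qual <- if (any(vapply(session$units, function(u) !is.null(u$waveforms), logical(1))))
    unit_quality(session, config) else NULL
  list(subject_id = session$subject$subject_id, task = session$subject$task,
       n_units = length(session$units),
       areas = session$electrodes$brain_area[
         match(vapply(session$units, `[[`, integer(1), "electrode_id"),
               session$electrodes$electrode_id)],
       classification = cls, behavior = beh, quality = qual)
}

#' Aggregate per-session analysis outputs into a dataset summary
#'
#' Unit counts by brain area and task, selective-cell counts and
#' proportions by region group (MTL = hippocampus + amygdala,
#' MFC = dACC + pre-SMA + vmPFC), the behaviour table, and quality-metric
#' distribution summaries. Proportions are always reported with their
#' counts and denominators.
#'
#' @param results list of per-session results (internal layout produced by
#'   [run_pipeline()]).
#' @return object of class `dataset_summary`.
#' @export
summarize_dataset <- function(results) {
  if (!length(results)) stopf("no session results to summarize")
  areas <- unlist(lapply(results, `[[`, "areas"))
  tasks <- rep(vapply(results, `[[`, character(1), "task"),
               vapply(results, `[[`, integer(1), "n_units"))
  units_by_area <- as.data.frame(table(area = areas, task = tasks),
                                 stringsAsFactors = FALSE)
  names(units_by_area)[3] <- "n_units"

  cls_all <- do.call(rbind, lapply(results, function(r)
    if (!is.null(r$classification)) as.data.frame(r$classification)))
  selective <- NULL
  if (!is.null(cls_all) && nrow(cls_all)) {
    grp <- region_group(cls_all$brain_area)
    selective <- do.call(rbind, lapply(unique(grp), function(g) {
      sel <- grp == g; n <- sum(sel)
      data.frame(region = g, n_units = n,
                 n_concept = sum(cls_all$is_concept[sel]),
                 pct_concept = 100 * sum(cls_all$is_concept[sel]) / n,
                 n_maintenance = sum(cls_all$is_maintenance[sel]),
                 pct_maintenance = 100 * sum(cls_all$is_maintenance[sel]) / n,
                 n_probe = sum(cls_all$is_probe[sel]),
                 pct_probe = 100 * sum(cls_all$is_probe[sel]) / n)
    }))
  }
  behavior <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$behavior)) return(NULL)
    cbind(subject_id = r$subject_id, r$behavior$per_load,
          overall_accuracy_pct = r$behavior$overall_accuracy_pct)
  }))
  qual_all <- do.call(rbind, lapply(results, function(r)
    if (!is.null(r$quality)) as.data.frame(r$quality)))
  quality <- if (!is.null(qual_all) && nrow(qual_all)) {
    s <- function(x) { x <- x[is.finite(x)]
      c(mean = mean(x), sd = stats::sd(x), median = stats::median(x)) }
    rbind(pct_isi_below_3ms = s(qual_all$pct_isi_below_3ms),
          mean_rate_hz = s(qual_all$mean_rate_hz), cv2 = s(qual_all$cv2),
          snr_peak = s(qual_all$snr_peak),
          isolation_distance = s(qual_all$isolation_distance))
  }
  structure(list(n_sessions = length(results),
                 n_units_total = sum(vapply(results, `[[`, integer(1), "n_units")),
                 units_by_area = units_by_area, selective = selective,
                 behavior = behavior, quality = quality, n_errors = 0L),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d sessions, %d units (%d unreadable sessions skipped)\n",
              x$n_sessions, x$n_units_total, x$n_errors))
  if (!is.null(x$selective)) {
    cat("Selective cells by region group:\n")
    print(x$selective, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Run the full analysis pipeline over a directory of sessions
#'
#' Discovers sessions under `input_dir` -- fixture directories (containing
#' `session.json`) and/or NWB-style HDF5 files (`.h5`/`.nwb`) -- analyses
#' each (behaviour, cell classification, quality metrics), writes the
#' per-session CSV outputs plus a dataset summary and a structured log
#' under `out_dir`, and returns the summary. Deterministic given the
#' config: reruns produce identical outputs. Unreadable sessions are
#' logged, skipped and counted.
#'
#' @param input_dir directory with session fixtures and/or HDF5 files.
#' @param out_dir output directory (created).
#' @param config an [analysis_config()].
#' @return a `dataset_summary` (invisibly also written as JSON).
#' @export
run_pipeline <- function(input_dir, out_dir, config = analysis_config()) {
  fixtures <- list.dirs(input_dir, recursive = FALSE)
  fixtures <- fixtures[file.exists(file.path(fixtures, "session.json"))]
  h5s <- list.files(input_dir, pattern = "\\.(h5|nwb)$", full.names = TRUE)
  paths <- c(fixtures, h5s)
  if (!length(paths)) stopf("no readable sessions under '%s'", input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("pipeline run | alpha=%g n_perm=%d seed=%d windows: stim=[%g,%g) maint=[%g,%g) base=%g probe=[%g,%g)\n",
              config$alpha, config$n_perm, config$rng_seed,
              config$window_stim_on[1], config$window_stim_on[2],
              config$window_maintenance[1], config$window_maintenance[2],
              config$window_baseline, config$window_probe[1],
              config$window_probe[2]), file = log_path)

  results <- list(); n_err <- 0L
  for (p in paths) {
    res <- tryCatch({
      session <- if (dir.exists(p)) load_fixture(p) else load_nwb_session(p)
      v <- validate_session(session)
      if (nrow(v)) stopf("invalid session: %s", v$message[1])
      logf("load ok: %s (%s, %d units)", basename(p), session$subject$task,
           length(session$units))
      r <- analyze_session(session, config)
      sdir <- file.path(out_dir, basename(p))
      dir.create(sdir, showWarnings = FALSE)
      if (!is.null(r$classification))
        utils::write.csv(as.data.frame(r$classification),
                         file.path(sdir, "classification.csv"), row.names = FALSE)
      if (!is.null(r$behavior))
        utils::write.csv(r$behavior$per_load, file.path(sdir, "behavior.csv"),
                         row.names = FALSE)
      if (!is.null(r$quality))
        utils::write.csv(as.data.frame(r$quality),
                         file.path(sdir, "quality.csv"), row.names = FALSE)
      r
    }, error = function(e) {
      logf("load FAILED: %s (%s)", basename(p), conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_err <- n_err + 1L else results[[length(results) + 1L]] <- res
  }
  if (!length(results)) stopf("all %d sessions failed to load", n_err)
  summary <- summarize_dataset(results)
  summary$n_errors <- n_err
  jsonlite::write_json(
    list(n_sessions = summary$n_sessions, n_units_total = summary$n_units_total,
         n_errors = n_err, units_by_area = summary$units_by_area,
         selective = summary$selective),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "rows")
  logf("summary: %d sessions, %d units, %d errors", summary$n_sessions,
       summary$n_units_total, n_err)
  summary
}
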