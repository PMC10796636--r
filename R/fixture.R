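# Plain-text fixture format: one JSON metadata document plus columnar numeric
# tables. Doubles are serialized with 17 significant digits, which round-trips
# IEEE doubles exactly; integers are stored verbatim.

FIXTURE_VERSION <- "1"

fmt_dbl <- function(x) sprintf("%.17g", x)

# data.frame -> CSV with doubles rendered at full precision
write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) if (is.double(out[[nm]])) out[[nm]] <- fmt_dbl(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

read_table <- function(path, int_cols = character(0), dbl_cols = character(0),
                       chr_cols = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (nm in int_cols) df[[nm]] <- as.integer(df[[nm]])
  for (nm in dbl_cols) df[[nm]] <- as.numeric(df[[nm]])
  df
}

TRIAL_INT_COLS <- c("trial_id", "load", "enc1_pic", "enc2_pic", "enc3_pic",
                    "probe_pic", "probe_in_out", "response_accuracy")
TRIAL_DBL_COLS <- c("ts_fixation", "ts_enc1", "ts_enc2", "ts_enc3",
                    "ts_enc1_end", "ts_enc2_end", "ts_enc3_end",
                    "ts_maintenance", "ts_probe", "ts_response")

#' Save a session to a plain-text fixture directory
#'
#' Writes a lossless, human-inspectable representation of a session: a JSON
#' metadata document (`session.json`) plus one CSV/text table per array
#' (electrodes, trials, events, presentations, units, concatenated spike
#' times and waveform rows). Integers round-trip bit-exactly and reals to
#' full double precision.
#'
#' @param session a valid `wm_session` (see [validate_session()]).
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [load_fixture()]
#' @export
save_fixture <- function(session, dir) {
  viol <- validate_session(session)
  if (nrow(viol)) stopf("refusing to save an invalid session (%d violations; first: %s)",
                        nrow(viol), viol$message[1])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- session$units
  meta <- list(
    version = FIXTURE_VERSION,
    subject = session$subject,
    stimuli = list(images = session$stimuli$images,
                   null_index = if (!is.null(session$stimuli$null_index) &&
                                    !is.na(session$stimuli$null_index))
                     as.integer(session$stimuli$null_index)),
    n_units = length(units)
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_table(session$electrodes, file.path(dir, "electrodes.csv"))
  write_table(session$trials, file.path(dir, "trials.csv"))
  write_table(data.frame(timestamp = session$events$timestamps,
                         code = session$events$codes),
              file.path(dir, "events.csv"))
  write_table(session$presentations, file.path(dir, "presentations.csv"))

  udf <- data.frame(
    unit_id = vapply(units, `[[`, integer(1), "unit_id"),
    electrode_id = vapply(units, `[[`, integer(1), "electrode_id"),
    n_spikes = vapply(units, function(u) length(u$spike_times), integer(1)),
    has_waveforms = vapply(units, function(u) as.integer(!is.null(u$waveforms)), integer(1)),
    n_samples = vapply(units, function(u) if (is.null(u$waveforms)) 0L else ncol(u$waveforms), integer(1)),
    ground_truth = vapply(units, function(u) u$ground_truth %||% NA_character_, character(1)),
    preferred_image = vapply(units, function(u) as.integer(u$preferred_image %||% NA_integer_), integer(1))
  )
  write_table(udf, file.path(dir, "units.csv"))
  spikes <- unlist(lapply(units, `[[`, "spike_times"))
  writeLines(fmt_dbl(spikes), file.path(dir, "spike_times.txt"))
  wf <- lapply(units, `[[`, "waveforms")
  wf <- wf[!vapply(wf, is.null, logical(1))]
  con <- file(file.path(dir, "waveforms.txt"), "w")
  for (m in wf) for (i in seq_len(nrow(m)))
    writeLines(paste(fmt_dbl(m[i, ]), collapse = " "), con)
  close(con)
  invisible(dir)
}

#' Load a session from a plain-text fixture directory
#'
#' Inverse of [save_fixture()]; the round trip is the identity on every
#' modelled field.
#'
#' @param dir fixture directory.
#' @return a `wm_session`.
#' @export
load_fixture <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stopf("no session.json under '%s'", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$version), FIXTURE_VERSION))
    stopf("unsupported fixture version '%s' (expected '%s')",
          meta$version, FIXTURE_VERSION)
  electrodes <- read_table(file.path(dir, "electrodes.csv"),
                           int_cols = c("electrode_id", "orig_channel"),
                           dbl_cols = c("mni_x", "mni_y", "mni_z"))
  electrodes$brain_area <- as.character(electrodes$brain_area)
  trials <- read_table(file.path(dir, "trials.csv"),
                       int_cols = TRIAL_INT_COLS, dbl_cols = TRIAL_DBL_COLS)
  evdf <- read_table(file.path(dir, "events.csv"),
                     int_cols = "code", dbl_cols = "timestamp")
  presentations <- read_table(file.path(dir, "presentations.csv"),
                              int_cols = "stimulus_index", dbl_cols = "onset_time")
  udf <- read_table(file.path(dir, "units.csv"),
                    int_cols = c("unit_id", "electrode_id", "n_spikes",
                                 "has_waveforms", "n_samples", "preferred_image"))
  spikes <- if (file.size(file.path(dir, "spike_times.txt")) > 0)
    scan(file.path(dir, "spike_times.txt"), what = double(), quiet = TRUE) else numeric(0)
  wf_lines <- readLines(file.path(dir, "waveforms.txt"))
  units <- vector("list", nrow(udf))
  sp_at <- 0L; wf_at <- 0L
  for (j in seq_len(nrow(udf))) {
    n <- udf$n_spikes[j]
    st <- if (n) spikes[(sp_at + 1L):(sp_at + n)] else numeric(0)
    sp_at <- sp_at + n
    wf <- NULL
    if (udf$has_waveforms[j] == 1L) {
      wf <- matrix(numeric(0), 0L, udf$n_samples[j])
      if (n) {
        rows <- wf_lines[(wf_at + 1L):(wf_at + n)]
        wf_at <- wf_at + n
        wf <- matrix(as.numeric(unlist(strsplit(rows, " ", fixed = TRUE))),
                     nrow = n, ncol = udf$n_samples[j], byrow = TRUE)
      }
    }
    gt <- udf$ground_truth[j]
    units[[j]] <- make_unit(udf$unit_id[j], udf$electrode_id[j], st, wf,
                            ground_truth = if (is.na(gt)) NULL else gt,
                            preferred_image = if (is.na(udf$preferred_image[j])) NULL
                                              else udf$preferred_image[j])
  }
  if (sp_at != length(spikes))
    stopf("fixture integrity error: %d spike times on disk, %d indexed", length(spikes), sp_at)
  null_index <- meta$stimuli$null_index
  if (!is.null(null_index) && is.na(suppressWarnings(as.integer(null_index))))
    null_index <- NULL
  wm_session(
    subject = list(subject_id = meta$subject$subject_id,
                   native_id = meta$subject$native_id,
                   age = as.integer(meta$subject$age),
                   sex = meta$subject$sex, task = meta$subject$task),
    electrodes = electrodes, units = units,
    events = list(timestamps = evdf$timestamp, codes = evdf$code),
    trials = trials,
    stimuli = list(images = as.character(meta$stimuli$images),
                   null_index = if (is.null(null_index)) NA_integer_
                                else as.integer(null_index)),
    presentations = presentations
  )
}
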