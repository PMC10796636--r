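#' Assemble a session record
#'
#' The in-memory model of one task session: subject metadata, the electrode
#' table, sorted units, the raw TTL event stream, the trials table (empty for
#' screening sessions), the stimulus set and the stimulus presentation log.
#' All timestamps are seconds on one session clock with an arbitrary origin.
#'
#' Picture identities in `trials` use the 1-based convention (1--5, 0 =
#' absent); `presentations$stimulus_index` uses the 0-based template
#' convention where index `n_images` is the Sternberg null image (template
#' index = picture id - 1).
#'
#' @param subject list with `subject_id`, `native_id`, `age`, `sex`
#'   (`"M"`/`"F"`) and `task` (`"screening"` or `"sternberg"`).
#' @param electrodes data.frame with columns `electrode_id`, `brain_area`,
#'   `mni_x`, `mni_y`, `mni_z`, `orig_channel`.
#' @param units list of units from [make_unit()].
#' @param events list with numeric `timestamps` and integer `codes`.
#' @param trials data.frame in the layout of [empty_trials()].
#' @param stimuli list with character `images` and optional `null_index`
#'   (0-based; `NA` for screening).
#' @param presentations data.frame with `stimulus_index` (0-based) and
#'   `onset_time`.
#' @return an object of class `wm_session`.
#' @seealso [validate_session()], [generate_sternberg_session()]
#' @export
wm_session <- function(subject, electrodes, units, events, trials, stimuli,
                       presentations) {
  structure(list(
    subject = subject, electrodes = electrodes, units = units,
    events = events, trials = trials, stimuli = stimuli,
    presentations = presentations
  ), class = "wm_session")
}

#' Construct a unit record
#'
#' @param unit_id,electrode_id integer identifiers; `electrode_id` must
#'   resolve in the session's electrode table.
#' @param spike_times strictly increasing spike times, seconds.
#' @param waveforms optional matrix (spikes x samples, microvolts) with one
#'   row per spike.
#' @param ground_truth optional planted class (synthetic sessions only):
#'   `"concept"`, `"maintenance"`, `"probe"` or `"null"`.
#' @param preferred_image optional planted preferred image id (1-based).
#' @export
make_unit <- function(unit_id, electrode_id, spike_times, waveforms = NULL,
                      ground_truth = NULL, preferred_image = NULL) {
  list(unit_id = as.integer(unit_id), electrode_id = as.integer(electrode_id),
       spike_times = as.numeric(spike_times), waveforms = waveforms,
       ground_truth = ground_truth, preferred_image = preferred_image)
}

#' Empty Sternberg trials table
#'
#' Column layout shared by the generator, the event parser and the fixture
#' format. Absent encoding periods are encoded as picture id 0 and
#' timestamp 0.
#' @param n number of (all-zero) rows.
#' @export
empty_trials <- function(n = 0L) {
  z <- numeric(n); zi <- integer(n)
  data.frame(trial_id = if (n) seq_len(n) else integer(0),
             load = zi, enc1_pic = zi, enc2_pic = zi, enc3_pic = zi,
             probe_pic = zi, probe_in_out = zi, response_accuracy = zi,
             ts_fixation = z, ts_enc1 = z, ts_enc2 = z, ts_enc3 = z,
             ts_enc1_end = z, ts_enc2_end = z, ts_enc3_end = z,
             ts_maintenance = z, ts_probe = z, ts_response = z)
}

violation <- function(type, field, index, message) {
  data.frame(type = type, field = field, index = index, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(type = character(0), field = character(0), index = integer(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Validate a session against the data-model invariants
#'
#' Checks every structural invariant of the session model (controlled
#' vocabularies, monotone timestamps, load/picture consistency, jagged-array
#' coherence between spike counts and waveform rows, cross-reference
#' resolution) and returns the violations as data rather than raising:
#' an empty data.frame means the session is valid.
#'
#' @param session a `wm_session`.
#' @return data.frame with columns `type`, `field`, `index`, `message`;
#'   zero rows iff all invariants hold.
#' @export
#' @examples
#' s <- generate_sternberg_session(generator_config(n_trials = 4, seed = 1))
#' nrow(validate_session(s)) == 0
validate_session <- function(session) {
  v <- list(no_violations())
  sub <- session$subject
  if (!sub$task %in% c("screening", "sternberg"))
    v[[length(v) + 1L]] <- violation("SubjectMeta", "task", 1L, "task must be screening or sternberg")
  if (!is.finite(sub$age) || sub$age <= 0)
    v[[length(v) + 1L]] <- violation("SubjectMeta", "age", 1L, "age must be > 0")
  if (!sub$sex %in% c("M", "F"))
    v[[length(v) + 1L]] <- violation("SubjectMeta", "sex", 1L, "sex must be M or F")

  el <- session$electrodes
  if (anyDuplicated(el$electrode_id))
    v[[length(v) + 1L]] <- violation("ElectrodeInfo", "electrode_id",
                                     anyDuplicated(el$electrode_id), "duplicate electrode_id")
  bad_area <- which(!el$brain_area %in% BRAIN_AREAS)
  for (i in bad_area)
    v[[length(v) + 1L]] <- violation("ElectrodeInfo", "brain_area", i,
                                     sprintf("unknown brain area '%s'", el$brain_area[i]))
  bad_mni <- which(!is.finite(el$mni_x) | !is.finite(el$mni_y) | !is.finite(el$mni_z))
  for (i in bad_mni)
    v[[length(v) + 1L]] <- violation("ElectrodeInfo", "mni_xyz", i, "non-finite MNI coordinate")

  ev <- session$events
  if (length(ev$timestamps) != length(ev$codes))
    v[[length(v) + 1L]] <- violation("EventStream", "codes", 1L,
                                     "timestamps and codes differ in length")
  if (is.unsorted(ev$timestamps))
    v[[length(v) + 1L]] <- violation("EventStream", "timestamps",
                                     which(diff(ev$timestamps) < 0)[1] + 1L,
                                     "timestamps must be non-decreasing")
  code_table <- if (sub$task == "sternberg") STERNBERG_CODES else SCREENING_CODES
  bad_code <- which(!ev$codes %in% code_table)
  if (length(bad_code))
    v[[length(v) + 1L]] <- violation("EventStream", "codes", bad_code[1],
                                     sprintf("code %d not in the %s task code table",
                                             ev$codes[bad_code[1]], sub$task))

  tr <- session$trials
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      pics <- c(tr$enc1_pic[i], tr$enc2_pic[i], tr$enc3_pic[i])
      if (!tr$load[i] %in% 1:3)
        v[[length(v) + 1L]] <- violation("TrialSternberg", "load", i, "load must be 1-3")
      if (sum(pics != 0) != tr$load[i])
        v[[length(v) + 1L]] <- violation("TrialSternberg", "enc_pic_ids", i,
                                         "count of nonzero picture ids must equal load")
      if (tr$probe_in_out[i] == 1 && !tr$probe_pic[i] %in% pics[pics != 0])
        v[[length(v) + 1L]] <- violation("TrialSternberg", "probe_pic", i,
                                         "in-probe must be one of the encoded pictures")
      ts <- c(tr$ts_fixation[i], tr$ts_enc1[i], tr$ts_enc2[i], tr$ts_enc3[i],
              tr$ts_maintenance[i], tr$ts_probe[i], tr$ts_response[i])
      ts <- ts[ts != 0]
      if (any(diff(ts) <= 0))
        v[[length(v) + 1L]] <- violation("TrialSternberg", "timestamps", i,
                                         "present timestamps must strictly increase in task order")
    }
  }

  for (j in seq_along(session$units)) {
    u <- session$units[[j]]
    if (length(u$spike_times) > 1 && any(diff(u$spike_times) <= 0))
      v[[length(v) + 1L]] <- violation("UnitRecord", "spike_times", j,
                                       sprintf("unit %d spike times must strictly increase", u$unit_id))
    if (!is.null(u$waveforms) && nrow(u$waveforms) != length(u$spike_times))
      v[[length(v) + 1L]] <- violation("UnitRecord", "waveforms", j,
                                       sprintf("unit %d waveform rows != spike count", u$unit_id))
    if (!u$electrode_id %in% el$electrode_id)
      v[[length(v) + 1L]] <- violation("UnitRecord", "electrode_id", j,
                                       sprintf("unit %d references unknown electrode %d",
                                               u$unit_id, u$electrode_id))
  }

  K <- length(session$stimuli$images)
  null_idx <- session$stimuli$null_index
  if (sub$task == "sternberg") {
    if (K != 6L || is.null(null_idx) || is.na(null_idx) || null_idx != 5L)
      v[[length(v) + 1L]] <- violation("StimulusSet", "images", 1L,
                                       "Sternberg stimulus set must have 6 images with null_index 5")
  } else {
    if (K < 54L || K > 64L)
      v[[length(v) + 1L]] <- violation("StimulusSet", "images", 1L,
                                       "screening stimulus set must have 54-64 images")
    if (!is.null(null_idx) && !is.na(null_idx))
      v[[length(v) + 1L]] <- violation("StimulusSet", "null_index", 1L,
                                       "screening sessions have no null image")
  }
  pr <- session$presentations
  if (nrow(pr)) {
    bad <- which(pr$stimulus_index < 0 | pr$stimulus_index >= K)
    if (length(bad))
      v[[length(v) + 1L]] <- violation("SessionRecord", "presentations", bad[1],
                                       "stimulus_index outside the template range")
    if (is.unsorted(pr$onset_time))
      v[[length(v) + 1L]] <- violation("SessionRecord", "presentations",
                                       which(diff(pr$onset_time) < 0)[1] + 1L,
                                       "presentation onsets must be non-decreasing")
  }
  do.call(rbind, v)
}

#' @export
print.wm_session <- function(x, ...) {
  cat(sprintf("<wm_session> %s task, subject %s (%s)\n",
              x$subject$task, x$subject$subject_id, x$subject$native_id))
  cat(sprintf("  %d units on %d electrodes | %d trials | %d events | %d presentations\n",
              length(x$units), nrow(x$electrodes), nrow(x$trials),
              length(x$events$codes), nrow(x$presentations)))
  gt <- vapply(x$units, function(u) u$ground_truth %||% NA_character_, character(1))
  if (any(!is.na(gt)))
    cat("  ground truth:", paste(sprintf("%s=%d", names(table(gt)), table(gt)), collapse = ", "), "\n")
  invisible(x)
}
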