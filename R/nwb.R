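# HDF5 adapter for the NWB-style session layout: /general (subject and
# electrode metadata), /acquisition/events (TTL stream), /intervals/trials,
# /stimulus/templates + /stimulus/presentation, and /units with the jagged
# spike_times/spike_times_index arrays (each index entry marks the LAST spike
# of its unit). The writer targets this group layout for round-trip testing;
# it does not claim standards-compliant NWB output.

nwb_required_groups <- function(task) {
  g <- c("general", "acquisition/events", "stimulus", "units")
  if (task == "sternberg") g <- c(g, "intervals/trials")
  g
}

h5_has <- function(contents, path) path %in% contents

#' Read a session from an NWB-style HDF5 file
#'
#' Decodes the group layout used by the public Sternberg/screening release:
#' units from the jagged `spike_times`/`spike_times_index` arrays (an index
#' entry marks the last spike of its unit), trials from `/intervals/trials`
#' columns (`loads`, `loadsEnc[1-3]_PicIDs`, `timestamps_*`, ...), the TTL
#' stream from `/acquisition/events`, electrodes from
#' `/general/extracellular_ephys/electrodes` and stimuli from `/stimulus`.
#'
#' @param path HDF5 file.
#' @return a `wm_session`.
#' @seealso [write_nwb_session()] for the inverse used in tests.
#' @export
load_nwb_session <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  ls <- rhdf5::h5ls(path)
  contents <- unique(sub("^/", "", file.path(sub("^/$", "", ls$group), ls$name)))
  on.exit(rhdf5::H5close(), add = TRUE)
  rd <- function(p) rhdf5::h5read(path, p)

  if (!any(startsWith(contents, "general")))
    stopf("NWB load error: missing group 'general'")
  task <- as.character(rd("general/task"))
  for (g in nwb_required_groups(task)) {
    if (!any(startsWith(contents, g)))
      stopf("NWB load error: missing group '%s'", basename(g))
  }

  subject <- list(subject_id = as.character(rd("general/subject/subject_id")),
                  native_id = as.character(rd("general/subject/native_id")),
                  age = as.integer(rd("general/subject/age")),
                  sex = as.character(rd("general/subject/sex")),
                  task = task)
  ep <- "general/extracellular_ephys/electrodes"
  electrodes <- data.frame(
    electrode_id = as.integer(rd(file.path(ep, "id"))),
    brain_area = as.character(rd(file.path(ep, "location"))),
    mni_x = as.numeric(rd(file.path(ep, "x"))),
    mni_y = as.numeric(rd(file.path(ep, "y"))),
    mni_z = as.numeric(rd(file.path(ep, "z"))),
    orig_channel = as.integer(rd(file.path(ep, "origChannel"))),
    stringsAsFactors = FALSE)

  events <- list(timestamps = as.numeric(rd("acquisition/events/timestamps")),
                 codes = as.integer(rd("acquisition/events/data")))

  trials <- empty_trials()
  if (h5_has(contents, "intervals/trials/loads")) {
    tp <- "intervals/trials"
    trials <- data.frame(
      trial_id = as.integer(rd(file.path(tp, "id"))),
      load = as.integer(rd(file.path(tp, "loads"))),
      enc1_pic = as.integer(rd(file.path(tp, "loadsEnc1_PicIDs"))),
      enc2_pic = as.integer(rd(file.path(tp, "loadsEnc2_PicIDs"))),
      enc3_pic = as.integer(rd(file.path(tp, "loadsEnc3_PicIDs"))),
      probe_pic = as.integer(rd(file.path(tp, "loadsProbe_PicIDs"))),
      probe_in_out = as.integer(rd(file.path(tp, "probe_in_out"))),
      response_accuracy = as.integer(rd(file.path(tp, "response_accuracy"))),
      ts_fixation = as.numeric(rd(file.path(tp, "timestamps_FixationCross"))),
      ts_enc1 = as.numeric(rd(file.path(tp, "timestamps_Encoding1"))),
      ts_enc2 = as.numeric(rd(file.path(tp, "timestamps_Encoding2"))),
      ts_enc3 = as.numeric(rd(file.path(tp, "timestamps_Encoding3"))),
      ts_enc1_end = as.numeric(rd(file.path(tp, "timestamps_Encoding1_end"))),
      ts_enc2_end = as.numeric(rd(file.path(tp, "timestamps_Encoding2_end"))),
      ts_enc3_end = as.numeric(rd(file.path(tp, "timestamps_Encoding3_end"))),
      ts_maintenance = as.numeric(rd(file.path(tp, "timestamps_Maintenance"))),
      ts_probe = as.numeric(rd(file.path(tp, "timestamps_Probe"))),
      ts_response = as.numeric(rd(file.path(tp, "timestamps_Response"))))
  }

  images <- as.character(rd("stimulus/templates/StimulusTemplates/image_names"))
  null_index <- if (h5_has(contents, "stimulus/templates/StimulusTemplates/null_index"))
    as.integer(rd("stimulus/templates/StimulusTemplates/null_index")) else NA_integer_
  presentations <- data.frame(
    stimulus_index = as.integer(rd("stimulus/presentation/StimulusPresentation/data")),
    onset_time = as.numeric(rd("stimulus/presentation/StimulusPresentation/timestamps")))

  uid <- as.integer(rd("units/id"))
  uel <- as.integer(rd("units/electrodes"))
  sp_all <- as.numeric(rd("units/spike_times"))
  sp_idx <- as.integer(rd("units/spike_times_index"))
  if (length(sp_idx) != length(uid))
    stopf("NWB integrity error: spike_times_index length %d != %d units",
          length(sp_idx), length(uid))
  if (is.unsorted(sp_idx, strictly = FALSE) || sp_idx[length(sp_idx)] != length(sp_all))
    stopf("NWB integrity error: spike_times_index does not partition spike_times (last=%d, n=%d)",
          sp_idx[length(sp_idx)], length(sp_all))
  has_wf <- h5_has(contents, "units/waveforms")
  wf_all <- if (has_wf) rd("units/waveforms") else NULL
  gt <- if (h5_has(contents, "units/ground_truth"))
    as.character(rd("units/ground_truth")) else rep(NA_character_, length(uid))
  pref <- if (h5_has(contents, "units/preferred_image"))
    as.integer(rd("units/preferred_image")) else rep(NA_integer_, length(uid))

  units <- vector("list", length(uid))
  start <- 1L
  for (j in seq_along(uid)) {
    end <- sp_idx[j]
    if (end < start - 1L) stopf("NWB integrity error: index inversion at unit %d", uid[j])
    st <- if (end >= start) sp_all[start:end] else numeric(0)
    wf <- if (!has_wf) NULL
          else if (end >= start) wf_all[start:end, , drop = FALSE]
          else matrix(numeric(0), 0L, ncol(wf_all))
    units[[j]] <- make_unit(uid[j], uel[j], st, wf,
                            ground_truth = if (is.na(gt[j]) || gt[j] == "") NULL else gt[j],
                            preferred_image = if (is.na(pref[j]) || pref[j] < 0) NULL else pref[j])
    start <- end + 1L
  }
  wm_session(subject, electrodes, units, events, trials,
             list(images = images, null_index = null_index), presentations)
}

#' Write a session to an NWB-style HDF5 file
#'
#' Emits the group layout read by [load_nwb_session()]. Planted
#' `ground_truth`/`preferred_image` labels are stored as extra `/units`
#' columns so that synthetic sessions round-trip completely.
#'
#' @param session a valid `wm_session`.
#' @param path output `.h5`/`.nwb` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_nwb_session <- function(session, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5createFile(path)
  h5g <- function(g) rhdf5::h5createGroup(path, g)
  for (g in c("general", "general/subject", "general/extracellular_ephys",
              "general/extracellular_ephys/electrodes", "acquisition",
              "acquisition/events", "intervals", "intervals/trials",
              "stimulus", "stimulus/templates",
              "stimulus/templates/StimulusTemplates",
              "stimulus/presentation",
              "stimulus/presentation/StimulusPresentation", "units")) h5g(g)
  wr <- function(obj, name) rhdf5::h5write(obj, path, name)

  wr(session$subject$task, "general/task")
  h5s <- "general/subject"
  wr(session$subject$subject_id, file.path(h5s, "subject_id"))
  wr(session$subject$native_id, file.path(h5s, "native_id"))
  wr(as.integer(session$subject$age), file.path(h5s, "age"))
  wr(session$subject$sex, file.path(h5s, "sex"))
  el <- session$electrodes
  ep <- "general/extracellular_ephys/electrodes"
  wr(as.integer(el$electrode_id), file.path(ep, "id"))
  wr(as.character(el$brain_area), file.path(ep, "location"))
  wr(as.numeric(el$mni_x), file.path(ep, "x"))
  wr(as.numeric(el$mni_y), file.path(ep, "y"))
  wr(as.numeric(el$mni_z), file.path(ep, "z"))
  wr(as.integer(el$orig_channel), file.path(ep, "origChannel"))

  wr(as.numeric(session$events$timestamps), "acquisition/events/timestamps")
  wr(as.integer(session$events$codes), "acquisition/events/data")

  tr <- session$trials
  if (nrow(tr)) {
    tp <- "intervals/trials"
    wr(tr$trial_id, file.path(tp, "id"))
    wr(tr$load, file.path(tp, "loads"))
    wr(tr$enc1_pic, file.path(tp, "loadsEnc1_PicIDs"))
    wr(tr$enc2_pic, file.path(tp, "loadsEnc2_PicIDs"))
    wr(tr$enc3_pic, file.path(tp, "loadsEnc3_PicIDs"))
    wr(tr$probe_pic, file.path(tp, "loadsProbe_PicIDs"))
    wr(tr$probe_in_out, file.path(tp, "probe_in_out"))
    wr(tr$response_accuracy, file.path(tp, "response_accuracy"))
    wr(tr$ts_fixation, file.path(tp, "timestamps_FixationCross"))
    wr(tr$ts_enc1, file.path(tp, "timestamps_Encoding1"))
    wr(tr$ts_enc2, file.path(tp, "timestamps_Encoding2"))
    wr(tr$ts_enc3, file.path(tp, "timestamps_Encoding3"))
    wr(tr$ts_enc1_end, file.path(tp, "timestamps_Encoding1_end"))
    wr(tr$ts_enc2_end, file.path(tp, "timestamps_Encoding2_end"))
    wr(tr$ts_enc3_end, file.path(tp, "timestamps_Encoding3_end"))
    wr(tr$ts_maintenance, file.path(tp, "timestamps_Maintenance"))
    wr(tr$ts_probe, file.path(tp, "timestamps_Probe"))
    wr(tr$ts_response, file.path(tp, "timestamps_Response"))
    wr(tr$ts_fixation, file.path(tp, "start_time"))
    wr(tr$ts_response, file.path(tp, "stop_time"))
  }

  wr(as.character(session$stimuli$images),
     "stimulus/templates/StimulusTemplates/image_names")
  ni <- session$stimuli$null_index
  if (!is.null(ni) && !is.na(ni))
    wr(as.integer(ni), "stimulus/templates/StimulusTemplates/null_index")
  wr(as.integer(session$presentations$stimulus_index),
     "stimulus/presentation/StimulusPresentation/data")
  wr(as.numeric(session$presentations$onset_time),
     "stimulus/presentation/StimulusPresentation/timestamps")

  units <- session$units
  wr(vapply(units, `[[`, integer(1), "unit_id"), "units/id")
  wr(vapply(units, `[[`, integer(1), "electrode_id"), "units/electrodes")
  sp <- lapply(units, `[[`, "spike_times")
  wr(unlist(sp) %||% numeric(0), "units/spike_times")
  wr(as.integer(cumsum(lengths(sp))), "units/spike_times_index")
  wfs <- lapply(units, `[[`, "waveforms")
  if (length(units) && all(!vapply(wfs, is.null, logical(1)))) {
    wf_all <- do.call(rbind, wfs)
    wr(wf_all, "units/waveforms")
    wr(t(vapply(units, function(u) colMeans(u$waveforms), numeric(ncol(wf_all)))),
       "units/waveform_mean")
    wr(t(vapply(units, function(u) apply(u$waveforms, 2, stats::sd), numeric(ncol(wf_all)))),
       "units/waveform_sd")
  }
  wr(vapply(units, function(u) u$ground_truth %||% "", character(1)),
     "units/ground_truth")
  wr(vapply(units, function(u) as.integer(u$preferred_image %||% -1L), integer(1)),
     "units/preferred_image")
  invisible(path)
}
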