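# TTL event-stream parsing. Sternberg grammar per trial:
#   11 (fixation) -> 1 [5 2 [5 3]] (pictures with transitions) -> 6
#   (end of encoding / maintenance onset) -> 7 (probe) -> 8 (response)
# with 61/60 framing the experiment. Screening: 1 (picture on) -> 3
# (picture off), with interleaved 4 (control-question response).

parse_error <- function(offset, code, why) {
  stopf("parse error at offset %d (code %d): %s", offset, code, why)
}

#' Parse a Sternberg TTL stream into trials
#'
#' Walks the event grammar and emits one parsed trial per
#' fixation-to-response span, with every period timestamp populated and the
#' load inferred from the number of picture codes seen. Encoding end times
#' are taken from the following transition (5) or end-of-encoding (6)
#' marker. Offsets in parse errors are zero-based positions in the stream.
#'
#' Picture identities are not carried by the TTL codes; when the session's
#' stimulus `presentations` log is supplied (4 referenced images per trial:
#' three encoding slots with the null image for absent slots, then the
#' probe) the picture id columns are filled from it, completing the trials
#' table.
#'
#' @param events list with `timestamps` and `codes`.
#' @param presentations optional presentations data.frame
#'   (`stimulus_index` 0-based, `onset_time`).
#' @param null_index 0-based template index of the null image (default 5).
#' @return a trials data.frame in the layout of [empty_trials()]; picture
#'   columns are zero when `presentations` is absent.
#' @export
parse_sternberg_events <- function(events, presentations = NULL, null_index = 5L) {
  ts <- events$timestamps; codes <- events$codes
  if (length(ts) != length(codes)) stopf("timestamps and codes differ in length")
  if (is.unsorted(ts)) stopf("timestamps must be non-decreasing")
  bad <- which(!codes %in% STERNBERG_CODES)
  if (length(bad)) parse_error(bad[1] - 1L, codes[bad[1]], "code not in the Sternberg table")

  trials <- list()
  state <- "idle"   # idle -> fix -> pic -> after_pic -> maint -> probe -> idle
  cur <- NULL; n_pic <- 0L
  for (i in seq_along(codes)) {
    code <- codes[i]; t <- ts[i]; off <- i - 1L
    if (code %in% c(61L, 60L)) {
      if (state != "idle") parse_error(off, code, "experiment marker inside a trial")
      next
    }
    switch(state,
      idle = {
        if (code != 11L) parse_error(off, code, "expected fixation cross (11)")
        cur <- empty_trials(1L); cur$ts_fixation <- t; n_pic <- 0L
        state <- "fix"
      },
      fix = {
        if (code != 1L) parse_error(off, code, "expected picture #1 (1) after fixation")
        n_pic <- 1L; cur$ts_enc1 <- t; state <- "after_pic"
      },
      after_pic = {
        if (code == 5L) {
          cur[[paste0("ts_enc", n_pic, "_end")]] <- t
          state <- "transition"
        } else if (code == 6L) {
          cur[[paste0("ts_enc", n_pic, "_end")]] <- t
          cur$ts_maintenance <- t; state <- "maint"
        } else parse_error(off, code, sprintf("expected transition (5) or end of encoding (6) after picture #%d", n_pic))
      },
      transition = {
        if (code != n_pic + 1L || n_pic >= 3L)
          parse_error(off, code, sprintf("expected picture #%d (%d) after transition", n_pic + 1L, n_pic + 1L))
        n_pic <- n_pic + 1L
        cur[[paste0("ts_enc", n_pic)]] <- t
        state <- "after_pic"
      },
      maint = {
        if (code != 7L) parse_error(off, code, "expected probe onset (7) after maintenance start")
        cur$ts_probe <- t; state <- "probe"
      },
      probe = {
        if (code != 8L) parse_error(off, code, "expected response (8) after probe")
        cur$ts_response <- t; cur$load <- n_pic
        trials[[length(trials) + 1L]] <- cur
        state <- "idle"; cur <- NULL
      })
  }
  if (state != "idle")
    parse_error(length(codes) - 1L, codes[length(codes)], "stream ends inside a trial")
  out <- if (length(trials)) do.call(rbind, trials) else empty_trials()
  out$trial_id <- seq_len(nrow(out))

  if (!is.null(presentations) && nrow(out)) {
    if (nrow(presentations) != 4L * nrow(out))
      stopf("presentations log has %d rows; expected 4 per trial (%d)",
            nrow(presentations), 4L * nrow(out))
    idx <- matrix(presentations$stimulus_index, ncol = 4L, byrow = TRUE)
    pic <- ifelse(idx == null_index, 0L, idx + 1L)
    out$enc1_pic <- pic[, 1]; out$enc2_pic <- pic[, 2]; out$enc3_pic <- pic[, 3]
    out$probe_pic <- pic[, 4]
  }
  out
}

#' Parse a screening TTL stream
#'
#' @param events list with `timestamps` and `codes` drawn from
#'   \{61, 1, 3, 4, 60\}.
#' @return list with `presentations` (data.frame `onset`, `offset`) and
#'   `responses` (numeric vector of control-question response times).
#' @export
parse_screening_events <- function(events) {
  ts <- events$timestamps; codes <- events$codes
  if (length(codes) == 0) stopf("parse error at offset 0 (code NA): empty event stream")
  bad <- which(!codes %in% SCREENING_CODES)
  if (length(bad)) parse_error(bad[1] - 1L, codes[bad[1]], "code not in the screening table")
  onsets <- numeric(0); offsets <- numeric(0); responses <- numeric(0)
  open <- NA_real_
  for (i in seq_along(codes)) {
    code <- codes[i]; off <- i - 1L
    if (code == 1L) {
      if (!is.na(open)) parse_error(off, code, "presentation start without preceding end")
      open <- ts[i]
    } else if (code == 3L) {
      if (is.na(open)) parse_error(off, code, "presentation end without start")
      if (ts[i] <= open) parse_error(off, code, "presentation offset not after onset")
      onsets <- c(onsets, open); offsets <- c(offsets, ts[i]); open <- NA_real_
    } else if (code == 4L) {
      responses <- c(responses, ts[i])
    }
  }
  if (!is.na(open))
    parse_error(length(codes) - 1L, codes[length(codes)], "presentation start without end")
  list(presentations = data.frame(onset = onsets, offset = offsets),
       responses = responses)
}

#' Reconcile parsed trials against a stored trials table
#'
#' The stored trials table of a session is derived from the raw TTLs; this
#' checks that derivation. Every stored timestamp (and load, and picture id
#' when the parsed table carries them) is compared to its parsed
#' counterpart; absent periods use the 0 convention on both sides.
#'
#' @param parsed trials from [parse_sternberg_events()].
#' @param stored stored trials table.
#' @param tol absolute timestamp tolerance, seconds.
#' @return data.frame of discrepancies (`trial`, `field`, `parsed`,
#'   `stored`); zero rows iff the tables agree.
#' @export
reconcile_trials <- function(parsed, stored, tol = 1e-6) {
  disc <- list(data.frame(trial = integer(0), field = character(0),
                          parsed = numeric(0), stored = numeric(0)))
  if (nrow(parsed) != nrow(stored)) {
    return(data.frame(trial = NA_integer_, field = "n_trials",
                      parsed = nrow(parsed), stored = nrow(stored)))
  }
  int_fields <- c("load")
  if (any(parsed$enc1_pic != 0L) || any(parsed$probe_pic != 0L))
    int_fields <- c(int_fields, "enc1_pic", "enc2_pic", "enc3_pic", "probe_pic")
  for (f in int_fields) {
    bad <- which(parsed[[f]] != stored[[f]])
    for (i in bad)
      disc[[length(disc) + 1L]] <- data.frame(trial = i, field = f,
                                              parsed = parsed[[f]][i],
                                              stored = stored[[f]][i])
  }
  for (f in TRIAL_DBL_COLS) {
    bad <- which(abs(parsed[[f]] - stored[[f]]) > tol)
    for (i in bad)
      disc[[length(disc) + 1L]] <- data.frame(trial = i, field = f,
                                              parsed = parsed[[f]][i],
                                              stored = stored[[f]][i])
  }
  do.call(rbind, disc)
}
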