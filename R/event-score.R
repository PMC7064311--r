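#' Resonance deflection patterns
#'
#' An RDP is the triple (delta1, delta2, delta3) of deflection coefficients,
#' each in [-1, 1], giving the intended direction and normalized magnitude
#' of change of the first three vocal tract resonances. `builtin_rdp()`
#' returns the canonical stop-consonant place patterns: bilabial deflects
#' all three resonances down; alveolar deflects the first down and the
#' second and third up; velar deflects the first down, the second up, and
#' the third down.
#'
#' @param delta1,delta2,delta3 Deflection coefficients in [-1, 1].
#' @param class One of `"bilabial"`, `"alveolar"`, `"velar"`.
#' @return A numeric vector of class `rdp`, length 3.
#' @examples
#' builtin_rdp("bilabial")  # -1 -1 -1
#' @export
rdp <- function(delta1, delta2, delta3) {
  d <- c(delta1, delta2, delta3)
  if (length(d) != 3 || any(!is.finite(d)) || any(abs(d) > 1)) {
    vt_stop("RDP coefficients must be three finite values in [-1, 1]",
            "vt_invalid_parameter")
  }
  structure(as.numeric(d), names = c("delta1", "delta2", "delta3"),
            class = "rdp")
}

#' @rdname rdp
#' @export
builtin_rdp <- function(class = c("bilabial", "alveolar", "velar")) {
  class <- tryCatch(match.arg(class),
                    error = function(e) vt_stop(
                      paste0("unknown RDP class: ", class[1]), "vt_invalid_parameter"))
  switch(class,
         bilabial = rdp(-1, -1, -1),
         alveolar = rdp(-1,  1,  1),
         velar    = rdp(-1,  1, -1))
}

#' Build an utterance script
#'
#' An utterance script is a timeline of acoustic events plus voice-source
#' gestures. Events live in a tibble with one row per event: a phonetic
#' `label` (ARPAbet, informational), the RDP coefficients `delta1..delta3`,
#' the constriction degree `mu` (>= 0; < 1 partial constriction, 1 complete
#' closure at one point, > 1 spatially spread closure), and timing in
#' seconds: peak time `tp`, full width at half maximum `tw`, and hold
#' duration `th` (a plateau at peak amplitude, centered on `tp`). The
#' optional logical column `consonant` tags events for the vowels-only
#' rendering variant. The unstressed neutral vowel is expressed by the
#' absence of events.
#'
#' @param events A data frame with columns `label`, `delta1`, `delta2`,
#'   `delta3`, `mu`, `tp`, `tw`, `th` and optionally `consonant`.
#' @param duration Utterance duration t_d in seconds.
#' @param frame_rate Vocal tract modulation rate f_svt in Hz (default 146,
#'   matching articulatory-database frame rates).
#' @param f0 Data frame of fundamental-frequency breakpoints with columns
#'   `time` (s) and `f0` (Hz), linearly interpolated.
#' @param abduction Data frame of devoicing intervals with columns `start`
#'   and `end` (s); within them the voice source is abducted (voiceless).
#' @return An object of class `utterance_script`.
#' @export
utterance_script <- function(events, duration, frame_rate = 146,
                             f0 = tibble::tibble(time = c(0, duration),
                                                 f0 = c(110, 110)),
                             abduction = tibble::tibble(start = numeric(),
                                                        end = numeric())) {
  events <- tibble::as_tibble(events)
  needed <- c("label", "delta1", "delta2", "delta3", "mu", "tp", "tw", "th")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0) {
    vt_stop(paste0("events is missing columns: ",
                   paste(missing_cols, collapse = ", ")), "vt_schema_error")
  }
  if (!("consonant" %in% names(events))) {
    events$consonant <- events$mu >= 0.9
  }
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    bad <- NULL
    if (any(abs(c(ev$delta1, ev$delta2, ev$delta3)) > 1)) bad <- "delta outside [-1, 1]"
    else if (ev$mu < 0) bad <- "mu < 0"
    else if (ev$tp < 0) bad <- "tp < 0"
    else if (ev$tw <= 0) bad <- "tw <= 0"
    else if (ev$th < 0) bad <- "th < 0"
    if (!is.null(bad)) {
      vt_stop(sprintf("event %d ('%s'): %s", k, ev$label, bad), "vt_schema_error")
    }
  }
  if (duration <= 0 ||
      (nrow(events) > 0 && duration <= max(events$tp))) {
    vt_stop("duration must exceed the latest event peak", "vt_schema_error")
  }
  if (frame_rate <= 0) vt_stop("frame_rate must be positive", "vt_schema_error")
  f0 <- tibble::as_tibble(f0)
  if (nrow(f0) < 1 || any(f0$f0 <= 0)) {
    vt_stop("f0 breakpoints must be positive", "vt_schema_error")
  }
  abduction <- tibble::as_tibble(abduction)
  structure(
    list(events = events, duration = duration, frame_rate = frame_rate,
         f0 = f0, abduction = abduction,
         n_frames = max(1L, as.integer(round(duration * frame_rate)))),
    class = "utterance_script"
  )
}

#' @export
print.utterance_script <- function(x, ...) {
  cat(sprintf("<utterance_script> %d events, %.2f s @ %g Hz (%d frames), %d abduction interval(s)\n",
              nrow(x$events), x$duration, x$frame_rate, x$n_frames,
              nrow(x$abduction)))
  if (nrow(x$events) > 0) {
    cat(" ", paste0("{", x$events$label, "}", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
glance.utterance_script <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$events), duration_s = x$duration,
                 frame_rate_hz = x$frame_rate, n_frames = x$n_frames,
                 n_consonants = sum(x$events$consonant),
                 n_abduction = nrow(x$abduction))
}

#' Convert times to modulation frames
#'
#' Event timing in seconds maps to frame counts as `round(t * f_svt)`; the
#' inverse mapping is exact to within half a frame.
#'
#' @param t Time(s) in seconds, non-negative.
#' @param frame_rate Modulation sampling rate f_svt, Hz.
#' @return Integer frame count(s).
#' @examples
#' time_to_samples(0.14, 146)  # 20
#' @export
time_to_samples <- function(t, frame_rate = 146) {
  if (any(t < 0)) vt_stop("t must be non-negative", "vt_invalid_parameter")
  as.integer(round(t * frame_rate))
}

#' Sampled event function
#'
#' The time course of one acoustic event is a Gaussian pulse
#' `E(n) = exp(-ln(16) ((n - N_p) / N_w)^2)` with peak amplitude 1 at frame
#' `N_p` and full width `N_w` frames at amplitude 0.5. A positive hold
#' duration inserts a plateau of value 1 centered on the peak, with the two
#' Gaussian halves attached at the plateau edges.
#'
#' @param tp,tw,th Peak time, half-maximum width, and hold duration in
#'   seconds. `event_function()` also accepts a one-row event data frame as
#'   its first argument.
#' @param n_frames Number of frames N_d to evaluate.
#' @param frame_rate Modulation rate f_svt, Hz.
#' @return Numeric vector `E` of length `n_frames`, values in [0, 1].
#' @export
event_function <- function(tp, tw = NULL, th = 0, n_frames, frame_rate = 146) {
  if (is.data.frame(tp)) {
    ev <- tp
    tp <- ev$tp; tw <- ev$tw; th <- ev$th
  }
  Np <- tp * frame_rate
  Nw <- tw * frame_rate
  Nh <- th * frame_rate
  if (Nw <= 0) vt_stop("tw must be positive", "vt_invalid_parameter")
  n <- seq_len(n_frames)
  if (Nh > 0) {
    lo <- Np - Nh / 2
    hi <- Np + Nh / 2
    dev <- ifelse(n < lo, n - lo, ifelse(n > hi, n - hi, 0))
  } else {
    dev <- n - Np
  }
  exp(-log(16) * (dev / Nw)^2)
}

# ---- script JSON I/O -------------------------------------------------------

#' Read and write utterance scripts as JSON
#'
#' Scripts are exchanged as JSON documents with fields `duration`,
#' `frame_rate`, `events` (objects with `label`, `delta` = [d1, d2, d3],
#' `mu`, `tp`, `tw`, `th`, optional `consonant`), `f0` (objects with
#' `time`, `f0`) and `abduction` (objects with `start`, `end`). All type
#' invariants are validated on read; the round trip is lossless.
#'
#' @param path File path.
#' @param script An [utterance_script()].
#' @return `read_script()` returns an `utterance_script`;
#'   `write_script()` returns `path` invisibly.
#' @export
read_script <- function(path) {
  if (!file.exists(path)) vt_stop(paste0("script not found: ", path), "vt_io_error")
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$events) || is.null(doc$duration)) {
    vt_stop("script must contain 'events' and 'duration'", "vt_schema_error")
  }
  evd <- doc$events
  deltas <- do.call(rbind, lapply(seq_len(nrow(evd)), function(k) {
    d <- evd$delta[[k]]
    if (length(d) != 3) {
      vt_stop(sprintf("event %d: delta must have 3 components", k), "vt_schema_error")
    }
    as.numeric(d)
  }))
  events <- tibble::tibble(
    label = as.character(evd$label),
    delta1 = deltas[, 1], delta2 = deltas[, 2], delta3 = deltas[, 3],
    mu = as.numeric(evd$mu), tp = as.numeric(evd$tp),
    tw = as.numeric(evd$tw), th = as.numeric(evd$th)
  )
  if (!is.null(evd$consonant)) events$consonant <- as.logical(evd$consonant)
  f0 <- if (is.null(doc$f0)) tibble::tibble(time = c(0, doc$duration),
                                            f0 = c(110, 110))
        else tibble::as_tibble(doc$f0)
  abd <- if (is.null(doc$abduction) || length(doc$abduction) == 0) {
    tibble::tibble(start = numeric(), end = numeric())
  } else tibble::as_tibble(doc$abduction)
  utterance_script(events, duration = doc$duration,
                   frame_rate = if (is.null(doc$frame_rate)) 146 else doc$frame_rate,
                   f0 = f0, abduction = abd)
}

#' @rdname read_script
#' @export
write_script <- function(script, path) {
  stopifnot(inherits(script, "utterance_script"))
  ev <- script$events
  doc <- list(
    duration = script$duration,
    frame_rate = script$frame_rate,
    events = lapply(seq_len(nrow(ev)), function(k) {
      list(label = ev$label[k],
           delta = c(ev$delta1[k], ev$delta2[k], ev$delta3[k]),
           mu = ev$mu[k], tp = ev$tp[k], tw = ev$tw[k], th = ev$th[k],
           consonant = ev$consonant[k])
    }),
    f0 = script$f0,
    abduction = script$abduction
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
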