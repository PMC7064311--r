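#' Track resonances through a tract movie
#'
#' Computes the first three resonance frequencies of every movie frame
#' with the frequency-domain model. Frames whose minimum area falls below
#' `gap_threshold` (fully occluded or nearly so) are marked as gaps; other
#' frames are floored at `occlusion_floor` for the acoustic computation.
#' Continuity is not enforced: each frame reports its raw refined peaks.
#'
#' @param movie A `tract_movie`.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @param gap_threshold Minimum area (cm^2) below which a frame is a gap
#'   (default 0.05). With 0, no gaps are produced and occluded frames
#'   report floored-tract resonances.
#' @param occlusion_floor Area floor for the acoustics, cm^2.
#' @param variant Label stored with the tracks (`"neutral"`,
#'   `"vowels_only"`, `"all_events"`, ...).
#' @param f_grid Frequency grid for resonance finding.
#' @return A tibble of class `resonance_tracks`: `frame`, `time_s`,
#'   `f_R1`, `f_R2`, `f_R3` (NA in gaps), `gap`, `min_area_cm2`,
#'   `variant`.
#' @export
track_resonances <- function(movie, branch = NULL, losses = loss_config(),
                             gap_threshold = 0.05, occlusion_floor = 0.01,
                             variant = "all_events",
                             f_grid = seq(50, 5000, by = 10)) {
  stopifnot(inherits(movie, "tract_movie"))
  grid <- movie$neutral$grid
  rows <- purrr::map(seq_len(nrow(movie$frames)), function(n) {
    a <- movie$frames[n, ]
    amin <- min(a)
    if (amin < gap_threshold) {
      return(tibble::tibble(frame = n, time_s = movie$times[n],
                            f_R1 = NA_real_, f_R2 = NA_real_, f_R3 = NA_real_,
                            gap = TRUE, min_area_cm2 = amin))
    }
    af <- area_function(pmax(a, occlusion_floor), grid)
    fr <- frequency_response(af, branch, losses, f_grid)
    f <- find_resonances(fr, 3)$f_R
    tibble::tibble(frame = n, time_s = movie$times[n],
                   f_R1 = f[1], f_R2 = f[2], f_R3 = f[3],
                   gap = FALSE, min_area_cm2 = amin)
  })
  out <- dplyr::bind_rows(rows)
  out$variant <- variant
  class(out) <- c("resonance_tracks", class(out))
  out
}

#' Vowels-only variant of a script
#'
#' Returns a copy of the script in which every consonant event has its
#' constriction degree set to zero, so only the vowel events shape the
#' tract (the reference condition for measuring consonant deflections).
#' Events are consonants if they carry an explicit `consonant` tag,
#' otherwise if `mu >= mu_threshold`.
#'
#' @param script An [utterance_script()].
#' @param mu_threshold Tagging threshold when no explicit tags exist
#'   (default 0.9).
#' @param use_tags Honor the script's `consonant` column (default TRUE).
#' @return An [utterance_script()].
#' @export
vowels_only_variant <- function(script, mu_threshold = 0.9, use_tags = TRUE) {
  ev <- script$events
  is_cons <- if (use_tags && "consonant" %in% names(ev)) ev$consonant
             else ev$mu >= mu_threshold
  ev$mu[is_cons] <- 0
  utterance_script(ev, duration = script$duration,
                   frame_rate = script$frame_rate, f0 = script$f0,
                   abduction = script$abduction)
}

#' Deflection-direction verdict for one event
#'
#' Compares event tracks against reference tracks at the last non-gap
#' frame (in both) at or before the event's peak, and reports
#' `sign(f_Rj_event - f_Rj_reference)` for each resonance. Events that
#' occlude the tract at their peak are probed at the nearest earlier frame
#' with defined resonances. A verdict of NA means no comparable frame
#' exists (undetermined).
#'
#' @param tracks_event,tracks_reference `resonance_tracks` on a common
#'   time base.
#' @param event A one-row event data frame (with `tp`), or a peak time in
#'   seconds.
#' @return Integer vector of three signs (-1, 0, 1), possibly NA.
#' @export
deflection_verdict <- function(tracks_event, tracks_reference, event) {
  tp <- if (is.data.frame(event)) event$tp else event
  frame_rate <- 1 / diff(tracks_event$time_s[1:2])
  peak_frame <- round(tp * frame_rate)
  ok <- !tracks_event$gap & !tracks_reference$gap &
    tracks_event$frame <= peak_frame
  if (!any(ok)) return(rep(NA_integer_, 3))
  n <- max(tracks_event$frame[ok])
  ev <- tracks_event[tracks_event$frame == n, ]
  rf <- tracks_reference[tracks_reference$frame == n, ]
  as.integer(sign(c(ev$f_R1 - rf$f_R1, ev$f_R2 - rf$f_R2, ev$f_R3 - rf$f_R3)))
}

#' Wideband spectrogram of synthesized audio
#'
#' Short-time Fourier magnitude with a wideband default (5 ms Hanning
#' window), returned as a tidy grid.
#'
#' @param audio An `audio_result` or numeric vector.
#' @param window_ms Analysis window, ms (default 5, wideband).
#' @param hop_ms Hop size, ms (default 2).
#' @param rate Sampling rate when `audio` is a bare vector.
#' @param max_freq Truncate the grid above this frequency, Hz.
#' @return A tibble of class `vt_spectrogram`: `time_s`, `frequency_hz`,
#'   `magnitude` (linear), `magnitude_db`.
#' @export
spectrogram <- function(audio, window_ms = 5, hop_ms = 2,
                        rate = 44100, max_freq = 5000) {
  x <- if (inherits(audio, "audio_result")) audio$samples else as.numeric(audio)
  if (inherits(audio, "audio_result")) rate <- audio$rate
  if (length(x) == 0) vt_stop("empty audio", "vt_invalid_parameter")
  nwin <- round(window_ms / 1000 * rate)
  hop <- max(1, round(hop_ms / 1000 * rate))
  if (nwin > length(x)) {
    vt_stop("analysis window longer than the signal", "vt_invalid_parameter")
  }
  sp <- signal::specgram(x, n = nwin, Fs = rate, overlap = nwin - hop)
  keep <- sp$f <= max_freq
  mag <- abs(sp$S[keep, , drop = FALSE])
  out <- tibble::tibble(
    time_s = rep(as.numeric(sp$t), each = sum(keep)),
    frequency_hz = rep(as.numeric(sp$f[keep]), length(sp$t)),
    magnitude = as.vector(mag),
    magnitude_db = 20 * log10(pmax(as.vector(mag), 1e-12))
  )
  class(out) <- c("vt_spectrogram", class(out))
  out
}

#' Spectral envelope peaks of an audio segment
#'
#' Estimates formant-like spectral peaks: Welch-averaged power spectrum
#' (Hanning windows, half overlap), cepstrally smoothed with a quefrency
#' lifter below the glottal period to suppress the harmonic comb, then
#' local maxima of the envelope. Used to verify that synthesized audio
#' carries its tract's resonances.
#'
#' @param audio An `audio_result` or numeric vector.
#' @param n_peaks Number of peaks to return (strongest first, then sorted
#'   by frequency).
#' @param rate Sampling rate when `audio` is a bare vector.
#' @param nfft Welch segment length.
#' @param lifter_ms Cepstral cutoff in ms; keep below the glottal period.
#' @param band Search band in Hz.
#' @param min_separation Minimum spacing between reported peaks, Hz;
#'   suppresses residual harmonic ripple.
#' @return Numeric vector of peak frequencies (Hz), ascending.
#' @export
spectral_peaks <- function(audio, n_peaks = 3, rate = 44100, nfft = 8192,
                           lifter_ms = 8, band = c(250, 3200),
                           min_separation = 300) {
  se <- spectral_envelope(audio, rate = rate, nfft = nfft,
                          lifter_ms = lifter_ms)
  env <- se$envelope
  fax <- se$frequency_hz
  loc <- which(diff(sign(diff(env))) == -2) + 1
  loc <- loc[fax[loc] > band[1] & fax[loc] < band[2]]
  # greedy selection by envelope height with a spacing constraint
  loc <- loc[order(env[loc], decreasing = TRUE)]
  picked <- integer()
  for (l in loc) {
    if (length(picked) == n_peaks) break
    if (all(abs(fax[l] - fax[picked]) >= min_separation)) picked <- c(picked, l)
  }
  if (length(picked) < n_peaks) {
    vt_stop("fewer well-separated envelope peaks than requested",
            "vt_resolution_error")
  }
  sort(fax[picked])
}

#' @rdname spectral_peaks
#' @return `spectral_envelope()` returns a tibble with `frequency_hz` and
#'   `envelope` (log power).
#' @export
spectral_envelope <- function(audio, rate = 44100, nfft = 8192,
                              lifter_ms = 8) {
  x <- if (inherits(audio, "audio_result")) audio$samples else as.numeric(audio)
  if (inherits(audio, "audio_result")) rate <- audio$rate
  if (length(x) < 2 * nfft) vt_stop("audio too short for Welch averaging",
                                    "vt_invalid_parameter")
  nseg <- floor(length(x) / nfft) * 2 - 1
  win <- signal::hanning(nfft)
  ps <- rowMeans(vapply(seq_len(nseg), function(k) {
    i <- (k - 1) * nfft / 2
    Mod(stats::fft(x[(i + 1):(i + nfft)] * win))[1:(nfft / 2)]^2
  }, numeric(nfft / 2)))
  logspec <- log(pmax(c(ps, rev(ps)), 1e-20))
  cep <- Re(stats::fft(logspec, inverse = TRUE)) / length(logspec)
  lift <- round(lifter_ms / 1000 * rate)
  cep[(lift + 1):(length(cep) - lift)] <- 0
  tibble::tibble(frequency_hz = (0:(nfft / 2 - 1)) * rate / nfft,
                 envelope = Re(stats::fft(cep))[1:(nfft / 2)])
}

#' Periodicity strength of an audio segment
#'
#' Maximum of the normalized autocorrelation over candidate pitch lags
#' (default 60-400 Hz), a simple voicing measure: near 1 for strongly
#' periodic segments, near 0 for silence or aspiration noise.
#'
#' @param audio An `audio_result` or numeric vector.
#' @param from,to Segment limits in seconds (default: whole signal).
#' @param rate Sampling rate when `audio` is a bare vector.
#' @param f0_range Candidate F0 range, Hz.
#' @return Periodicity strength in [0, 1] (0 for near-silent segments).
#' @export
voicing_strength <- function(audio, from = NULL, to = NULL, rate = 44100,
                             f0_range = c(60, 400)) {
  x <- if (inherits(audio, "audio_result")) audio$samples else as.numeric(audio)
  if (inherits(audio, "audio_result")) rate <- audio$rate
  if (!is.null(from)) {
    i0 <- max(1, round(from * rate)); i1 <- min(length(x), round(to * rate))
    x <- x[i0:i1]
  }
  x <- x - mean(x)
  e0 <- sum(x^2)
  if (e0 < 1e-12) return(0)
  lags <- seq(floor(rate / f0_range[2]), ceiling(rate / f0_range[1]))
  lags <- lags[lags < length(x) - 1]
  if (length(lags) == 0) return(0)
  ac <- vapply(lags, function(l) {
    a <- x[1:(length(x) - l)]; b <- x[(l + 1):length(x)]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  max(0, max(ac))
}

#' Short-time RMS energy contour
#'
#' @param audio An `audio_result` or numeric vector.
#' @param window_ms,hop_ms Analysis window and hop, ms.
#' @param rate Sampling rate when `audio` is a bare vector.
#' @return A tibble with `time_s` and `rms`.
#' @export
energy_contour <- function(audio, window_ms = 20, hop_ms = 5, rate = 44100) {
  x <- if (inherits(audio, "audio_result")) audio$samples else as.numeric(audio)
  if (inherits(audio, "audio_result")) rate <- audio$rate
  nwin <- round(window_ms / 1000 * rate)
  hop <- max(1, round(hop_ms / 1000 * rate))
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  tibble::tibble(
    time_s = (starts + nwin / 2) / rate,
    rms = vapply(starts, function(s) sqrt(mean(x[s:(s + nwin - 1)]^2)),
                 numeric(1))
  )
}

#' Export resonance tracks as delimited text
#'
#' @param tracks A `resonance_tracks` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tracks_table <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
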