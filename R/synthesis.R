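#' Parametric voice source
#'
#' A simplified, non-interactive glottal source: a raised-cosine glottal
#' flow pulse train following an F0 contour, with abduction (devoicing)
#' gestures during which the pulse amplitude ramps to zero, a steady
#' transglottal leak flow opens (the aspiration air stream), and the
#' glottal area widens. The source accepts any F0 breakpoint contour and
#' list of abduction intervals, so it stands behind a stable interface.
#'
#' @param f0 Data frame of breakpoints `time` (s), `f0` (Hz).
#' @param abduction Data frame of devoicing intervals `start`, `end` (s).
#' @param pulse_amplitude Peak glottal flow of the voiced pulse, cm^3/s.
#' @param open_quotient Fraction of the period the glottis is open.
#' @param glottal_area_max Peak glottal area during the open phase, cm^2.
#' @param leak_flow Steady flow during abduction, cm^3/s.
#' @param leak_area Glottal area opened during abduction, cm^2.
#' @param ramp_s Raised-cosine ramp time into/out of abduction, s.
#' @return An object of class `voice_source`.
#' @export
voice_source <- function(f0 = tibble::tibble(time = 0, f0 = 110),
                         abduction = tibble::tibble(start = numeric(),
                                                    end = numeric()),
                         pulse_amplitude = 350, open_quotient = 0.6,
                         glottal_area_max = 0.2, leak_flow = 150,
                         leak_area = 0.15, ramp_s = 0.012) {
  if (any(f0$f0 <= 0) || pulse_amplitude < 0 || open_quotient <= 0 ||
      open_quotient > 1) {
    vt_stop("invalid voice source parameters", "vt_invalid_parameter")
  }
  structure(list(f0 = tibble::as_tibble(f0),
                 abduction = tibble::as_tibble(abduction),
                 pulse_amplitude = pulse_amplitude,
                 open_quotient = open_quotient,
                 glottal_area_max = glottal_area_max,
                 leak_flow = leak_flow, leak_area = leak_area,
                 ramp_s = ramp_s),
            class = "voice_source")
}

#' @rdname voice_source
#' @param script An [utterance_script()] whose F0 contour and abduction
#'   intervals are adopted.
#' @param ... Passed to [voice_source()].
#' @export
voice_source_from_script <- function(script, ...) {
  voice_source(f0 = script$f0, abduction = script$abduction, ...)
}

#' Turbulence noise parameters
#'
#' Parameters of the Reynolds-number gated noise source: noise is permitted
#' only where the Reynolds number exceeds the critical value `re_c`, and
#' the flow increment is `N_f * (Re^2 - Re_c^2) * gain` with `N_f` a
#' uniform noise signal in [-0.5, 0.5] band-pass filtered between the band
#' edges (second-order Butterworth).
#'
#' @param re_c Critical Reynolds number (default 1200).
#' @param gain Noise gain constant (default 1e-6).
#' @param band Band-pass edges in Hz (default 500-2500).
#' @param order Butterworth order (default 2).
#' @param rng_seed Seed for the noise streams.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(re_c = 1200, gain = 1e-6, band = c(500, 2500),
                         order = 2, rng_seed = 1L) {
  if (re_c <= 0 || length(band) != 2 || band[1] >= band[2]) {
    vt_stop("invalid noise parameters", "vt_invalid_parameter")
  }
  structure(list(re_c = re_c, gain = gain, band = band, order = order,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_params")
}

#' Reynolds number of flow through a tubelet
#'
#' `Re = |U| d_h / (A nu)` with hydraulic diameter `d_h = 2 sqrt(A / pi)`
#' of the circular-equivalent section, volume flow `U` (cm^3/s), area `A`
#' (cm^2) and kinematic viscosity `nu` (cm^2/s). Closed sections (zero
#' area) carry no flow and return 0.
#'
#' @param flow Volume velocity, cm^3/s.
#' @param area Cross-sectional area, cm^2.
#' @param nu Kinematic viscosity of air, cm^2/s.
#' @return Reynolds number (dimensionless), vectorized.
#' @export
reynolds_number <- function(flow, area, nu = .vt_const$kinematic_viscosity) {
  if (any(area < 0)) vt_stop("area must be non-negative", "vt_invalid_parameter")
  ifelse(area == 0, 0, abs(flow) * 2 * sqrt(area / pi) / (area * nu))
}

#' Reynolds-gated turbulence flow increment
#'
#' @param re Reynolds number(s).
#' @param nf Filtered noise sample(s).
#' @param params A [noise_params()].
#' @return Flow increment(s), cm^3/s: 0 where `re <= re_c`, otherwise
#'   `nf * (re^2 - re_c^2) * gain`.
#' @examples
#' noise_flow(1300, 0.5, noise_params())  # 0.125
#' noise_flow(1200, 0.5, noise_params())  # 0
#' @export
noise_flow <- function(re, nf, params = noise_params()) {
  ifelse(re > params$re_c, nf * (re^2 - params$re_c^2) * params$gain, 0)
}

# Uniform [-0.5, 0.5] noise band-pass filtered per the noise parameters.
band_limited_noise <- function(n, fs, params) {
  x <- runif(n, -0.5, 0.5)
  bf <- signal::butter(params$order, params$band / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

# Piecewise-linear interpolation of the F0 contour onto a per-sample grid.
interp_f0 <- function(f0, times) {
  if (nrow(f0) == 1) return(rep(f0$f0, length(times)))
  approx(f0$time, f0$f0, xout = times, rule = 2)$y
}

# Raised-cosine voicing envelope: 1 outside abduction intervals, ramping to
# 0 inside them.
abduction_envelope <- function(abduction, times, ramp_s) {
  env <- rep(1, length(times))
  for (k in seq_len(nrow(abduction))) {
    s <- abduction$start[k]; e <- abduction$end[k]
    inside <- times >= s & times <= e
    env[inside & times >= s + ramp_s & times <= e - ramp_s] <- 0
    ramp_in <- times >= s & times < s + ramp_s
    env[ramp_in] <- pmin(env[ramp_in], 0.5 * (1 + cos(pi * (times[ramp_in] - s) / ramp_s)))
    ramp_out <- times > e - ramp_s & times <= e
    env[ramp_out] <- pmin(env[ramp_out], 0.5 * (1 - cos(pi * (times[ramp_out] - (e - ramp_s)) / ramp_s)))
  }
  env
}

# Glottal flow pulse train, glottal area, and the per-sample glottal drive
# (voiced pulses + abduction leak + Reynolds-gated glottal noise).
glottal_drive <- function(source, noise, n_samples, fs) {
  t <- (seq_len(n_samples) - 1) / fs
  f0 <- interp_f0(source$f0, t)
  phase <- (cumsum(f0) / fs) %% 1
  oq <- source$open_quotient
  pulse <- ifelse(phase < oq, 0.5 * (1 - cos(2 * pi * phase / oq)), 0)
  venv <- abduction_envelope(source$abduction, t, source$ramp_s)
  leak_env <- 1 - venv
  ug_voiced <- source$pulse_amplitude * pulse * venv
  ug_leak <- source$leak_flow * leak_env
  ug <- ug_voiced + ug_leak
  ag <- pmax(source$glottal_area_max * pulse * venv +
               source$leak_area * leak_env, 0.02)
  re_g <- reynolds_number(ug, ag)
  nf <- band_limited_noise(n_samples, fs, noise)
  ug_noise <- noise_flow(re_g, nf, noise)
  list(ug = ug + ug_noise, ag = ag, re_glottis = re_g, t = t)
}

#' Synthesize audio from a tract movie
#'
#' Propagates a glottal source through the time-varying area function with
#' a one-dimensional wave-reflection (Kelly-Lochbaum) algorithm: pressure
#' waves travel through half-sample tubelets, scatter at area junctions,
#' reflect at the glottal and lip ends, and radiate at the lips (the
#' output is the differentiated lip flow). Area functions are linearly
#' interpolated from the modulation frame rate to the audio rate; sections
#' below the closure threshold act as (nearly) fully reflecting closed
#' junctions, so stop closures and release transients emerge from the
#' waveguide states. Glottal turbulence noise enters the glottal flow and
#' supraglottal noise is injected immediately downstream of the most
#' constricted section whose Reynolds number exceeds the critical value.
#' The result is deterministic for a fixed noise seed.
#'
#' @param movie A [render_movie()] result (or any `tract_movie`).
#' @param source A [voice_source()]; defaults to the movie's script
#'   gestures when available.
#' @param noise A [noise_params()]; `NULL` disables turbulence noise.
#' @param losses If `loss_config(lossless = TRUE)`, propagation is
#'   lossless with ideal closed-glottis/open-lip ends; otherwise the
#'   default interior attenuation and boundary reflectances apply.
#' @param sampling_rate Audio rate, Hz; must satisfy the tubelet relation
#'   `section_length = c / (2 Fs)` of the movie's grid.
#' @param atten Per-section, per-half-step wave attenuation factor
#'   (lossy mode).
#' @param r_glottis,r_lip Boundary reflection coefficients (lossy mode).
#' @param closure_threshold Areas below this (cm^2) are clamped for
#'   scattering, i.e. treated as closed (default 0.001).
#' @param normalize Peak-normalize the output to -1 dBFS.
#' @return An object of class `audio_result`: `samples` (normalized
#'   waveform), `rate`, and a per-sample `diagnostics` tibble (time,
#'   glottal flow, Reynolds numbers, minimum area).
#' @export
synthesize <- function(movie, source = NULL, noise = noise_params(),
                       losses = loss_config(),
                       sampling_rate = movie$neutral$grid$sampling_rate,
                       atten = 0.9965, r_glottis = 0.98, r_lip = -0.9,
                       closure_threshold = 0.001, normalize = TRUE) {
  stopifnot(inherits(movie, "tract_movie"))
  grid <- movie$neutral$grid
  if (abs(grid$section_length * 2 * sampling_rate - grid$sound_speed) >
      1e-6 * grid$sound_speed) {
    vt_stop("audio rate inconsistent with the tubelet grid: need section_length = c/(2 Fs)",
            "vt_configuration_error")
  }
  if (is.null(source)) {
    source <- if (!is.null(movie$script)) voice_source_from_script(movie$script)
              else voice_source()
  }
  if (losses$lossless) {
    atten <- 1; r_glottis <- 1; r_lip <- -1
  }
  n_samples <- as.integer(round(nrow(movie$frames) / movie$frame_rate *
                                  sampling_rate))
  no_noise <- is.null(noise)
  if (no_noise) noise <- noise_params(gain = 0)
  seed_guard <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(noise$rng_seed)
  drive <- glottal_drive(source, noise, n_samples, sampling_rate)
  supra <- band_limited_noise(n_samples, sampling_rate, noise)
  if (!is.null(seed_guard)) assign(".Random.seed", seed_guard, .GlobalEnv)
  rho <- if (losses$lossless) .vt_const$air_density else losses$air_density
  wg <- waveguide_synth(movie$frames, movie$frame_rate, drive$ug, supra,
                        sampling_rate, rho, grid$sound_speed,
                        .vt_const$kinematic_viscosity,
                        noise$re_c, if (no_noise) 0 else noise$gain,
                        r_glottis, r_lip, atten, closure_threshold)
  y <- c(0, diff(wg$lip_flow))
  if (normalize && max(abs(y)) > 0) y <- y / max(abs(y)) * 10^(-1 / 20)
  structure(
    list(samples = y, rate = sampling_rate,
         diagnostics = tibble::tibble(
           time_s = drive$t, glottal_flow = drive$ug,
           re_glottis = drive$re_glottis, re_supraglottal = wg$re_supra,
           min_area_cm2 = wg$min_area)),
    class = "audio_result"
  )
}

#' @export
print.audio_result <- function(x, ...) {
  cat(sprintf("<audio_result> %.3f s @ %g Hz (%d samples), peak %.3f\n",
              length(x$samples) / x$rate, x$rate, length(x$samples),
              max(abs(x$samples))))
  invisible(x)
}

#' Impulse response of a static tract through the waveguide
#'
#' Rings a (static) area function with a unit glottal flow impulse and
#' returns the raw lip-flow response; with `lossless = TRUE` the ends are
#' ideal (closed glottis, open lips) so a uniform tube rings at its
#' quarter-wave resonances. Used to cross-validate the time-domain
#' synthesizer against the frequency-domain model.
#'
#' @param af An [area_function()].
#' @param n_samples Response length.
#' @param lossless Ideal ends and no attenuation.
#' @param atten,r_glottis,r_lip Propagation parameters when not lossless.
#' @return Numeric lip-flow vector.
#' @export
tube_impulse_response <- function(af, n_samples = 8192, lossless = TRUE,
                                  atten = 0.9965, r_glottis = 0.98,
                                  r_lip = -0.9) {
  frames <- matrix(af$areas, nrow = 2, ncol = af$grid$n_sections, byrow = TRUE)
  ug <- c(1, rep(0, n_samples - 1))
  if (lossless) { atten <- 1; r_glottis <- 1; r_lip <- -1 }
  wg <- waveguide_synth(frames, 1, ug, rep(0, n_samples),
                        af$grid$sampling_rate, .vt_const$air_density,
                        af$grid$sound_speed, .vt_const$kinematic_viscosity,
                        1200, 0, r_glottis, r_lip, atten, 0.001)
  as.numeric(wg$lip_flow)
}

# ---- WAV I/O ---------------------------------------------------------------

#' Read and write 16-bit PCM WAV audio
#'
#' Minimal RIFF/WAVE I/O: mono, 16-bit PCM. `write_wav()` peak-normalizes
#' to -1 dBFS before quantization (disable with `normalize = FALSE`); the
#' round trip is sample-exact to within one quantization step.
#'
#' @param audio An `audio_result` or numeric vector in [-1, 1].
#' @param path File path.
#' @param rate Sampling rate when `audio` is a bare vector.
#' @param normalize Peak-normalize to -1 dBFS before writing.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns an
#'   `audio_result`.
#' @export
write_wav <- function(audio, path, rate = 44100, normalize = TRUE) {
  x <- if (inherits(audio, "audio_result")) audio$samples else as.numeric(audio)
  if (inherits(audio, "audio_result")) rate <- audio$rate
  if (any(!is.finite(x))) vt_stop("samples must be finite", "vt_invalid_parameter")
  if (normalize && max(abs(x)) > 0) x <- x / max(abs(x)) * 10^(-1 / 20)
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) vt_stop(paste0("WAV not found: ", path), "vt_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) vt_stop("not a RIFF file", "vt_format_error")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) vt_stop("not a WAVE file", "vt_format_error")
  rate <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 2, size = 2, endian = "little"))
      if (fmt[1] != 1 || fmt[2] != 1) {
        vt_stop("only mono 16-bit PCM WAV is supported", "vt_format_error")
      }
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(tag, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(rate) || is.null(samples)) vt_stop("malformed WAV file", "vt_format_error")
  structure(list(samples = samples / 32767, rate = rate, diagnostics = NULL),
            class = "audio_result")
}
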