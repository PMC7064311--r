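test_that("the turbulence gate follows the Reynolds threshold law", {
  np <- noise_params()
  expect_equal(noise_flow(1200, 0.5, np), 0)
  expect_equal(noise_flow(0, 0.5, np), 0)
  expect_equal(noise_flow(1300, 0.5, np), 0.125)
  # vectorized gate: zero wherever Re <= Re_c
  re <- c(0, 500, 1200, 1201, 5000)
  out <- noise_flow(re, rep(1, 5), np)
  expect_true(all(out[re <= 1200] == 0))
  expect_true(all(out[re > 1200] > 0))
})

test_that("Reynolds numbers scale with flow and constriction", {
  expect_equal(reynolds_number(0, 1), 0)
  expect_equal(reynolds_number(200, 1), 2 * reynolds_number(100, 1))
  expect_gt(reynolds_number(100, 0.5), reynolds_number(100, 1))
  expect_equal(reynolds_number(100, 0), 0)  # closed section carries no flow
  expect_error(reynolds_number(100, -1), class = "vt_invalid_parameter")
})

test_that("the lossless waveguide rings a uniform tube at quarter-wave modes", {
  tube <- uniform_tube()
  y <- tube_impulse_response(tube, n_samples = 16384)
  sp <- Mod(stats::fft(y))[1:8192]
  fax <- (0:8191) * 44100 / 16384
  loc <- which(diff(sign(diff(sp))) == -2) + 1
  loc <- loc[fax[loc] > 200 & fax[loc] < 3000]
  loc <- loc[order(sp[loc], decreasing = TRUE)][1:3]
  expect_equal(sort(fax[loc]), quarter_wave(tube$grid$total_length),
               tolerance = 0.01)
})

test_that("a neutral voiced vowel is periodic and carries the tract resonances", {
  om <- neutral_tract_standin()
  scr <- empty_script(duration = 1, frame_rate = 146)
  mv <- render_movie(scr, om, side_branch())
  # turbulence noise off (isolates the tract filter) and a low flat pitch
  # so the harmonic comb samples the envelope densely around each formant
  au <- synthesize(mv, source = voice_source(f0 = tibble::tibble(time = 0,
                                                                 f0 = 68)),
                   noise = NULL)
  expect_equal(length(au$samples), 44100L)
  expect_gt(voicing_strength(au, 0.2, 0.8), 0.7)
  # each tract resonance appears as a local spectral-envelope maximum
  # within 5%; the reference is the lossless, unbranched frequency-domain
  # model because the time-domain engine treats losses as frequency-flat
  # attenuation (peak positions stay at the lossless values)
  f_ref <- find_resonances(frequency_response(om, losses = lossless))$f_R
  se <- spectral_envelope(au, lifter_ms = 9)
  loc <- which(diff(sign(diff(se$envelope))) == -2) + 1
  pk <- se$frequency_hz[loc]
  for (f in f_ref) {
    expect_lt(min(abs(pk / f - 1)), 0.05, label = sprintf("%.0f Hz", f))
  }
})

test_that("abduction across the utterance removes periodicity", {
  om <- neutral_tract_standin()
  scr <- utterance_script(empty_script(0.8)$events, duration = 0.8,
                          frame_rate = 146,
                          abduction = tibble::tibble(start = 0, end = 0.8))
  mv <- render_movie(scr, om, side_branch())
  au <- synthesize(mv)
  expect_lt(voicing_strength(au, 0.2, 0.6), 0.5)
})

test_that("synthesis is bit-reproducible for a fixed seed", {
  om <- neutral_tract_standin()
  mv <- render_movie(empty_script(0.4), om, side_branch())
  a1 <- synthesize(mv, noise = noise_params(rng_seed = 11))
  a2 <- synthesize(mv, noise = noise_params(rng_seed = 11))
  expect_identical(a1$samples, a2$samples)
  a3 <- synthesize(mv, noise = noise_params(rng_seed = 12))
  expect_false(identical(a3$samples, a1$samples))
})

test_that("the audio rate must satisfy the tubelet length relation", {
  om <- neutral_tract_standin()
  mv <- render_movie(empty_script(0.2), om)
  expect_error(synthesize(mv, sampling_rate = 22050),
               class = "vt_configuration_error")
})

test_that("WAV I/O round-trips within one quantization step", {
  x <- sin(2 * pi * 220 * (1:8820) / 44100) * 0.5
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, path, normalize = FALSE)
  back <- read_wav(path)
  expect_equal(back$rate, 44100)
  expect_lte(max(abs(back$samples - x)), 2^-15)
  # silence stays exactly zero
  write_wav(rep(0, 1000), path, normalize = FALSE)
  expect_true(all(read_wav(path)$samples == 0))
  # 1.64 s at 44100 Hz
  write_wav(rep(0, round(1.64 * 44100)), path)
  expect_equal(length(read_wav(path)$samples), 72324)
})
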