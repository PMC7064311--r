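test_that("a static neutral movie yields flat tracks at the neutral resonances", {
  om <- neutral_tract_standin()
  br <- side_branch()
  mv <- render_movie(empty_script(0.15), om, br)
  trk <- track_resonances(mv, br, variant = "neutral")
  f_neu <- find_resonances(frequency_response(om, br))$f_R
  expect_false(any(trk$gap))
  expect_lt(stats::var(trk$f_R1), 1e-6)
  expect_equal(trk$f_R1[1], f_neu[1], tolerance = 1e-3)
  expect_equal(trk$f_R3[1], f_neu[3], tolerance = 1e-3)
  expect_true(all(trk$f_R1 < trk$f_R2 & trk$f_R2 < trk$f_R3))
})

test_that("gap marking follows the minimum-area threshold", {
  om <- neutral_tract_standin()
  mv <- render_movie(empty_script(0.05), om)
  mv$frames[3, 20] <- 0  # occlude one frame by hand
  trk <- track_resonances(mv, gap_threshold = 0.05)
  expect_true(trk$gap[3])
  expect_true(all(is.na(trk$f_R1[3])))
  expect_false(any(trk$gap[-3]))
  # threshold 0: no gaps, floored-tract resonances at the occlusion
  trk0 <- track_resonances(mv, gap_threshold = 0)
  expect_false(any(trk0$gap))
  expect_true(all(is.finite(trk0$f_R1)))
})

test_that("the vowels-only variant zeroes consonant constriction degrees", {
  s1 <- sentence_script(1)
  v <- vowels_only_variant(s1)
  cons <- s1$events$consonant
  expect_true(all(v$events$mu[cons] == 0))
  expect_equal(v$events$mu[!cons], s1$events$mu[!cons])
  expect_equal(v$events[, c("delta1", "delta2", "delta3", "tp", "tw", "th")],
               s1$events[, c("delta1", "delta2", "delta3", "tp", "tw", "th")])
  # an all-vowel script is untouched
  vow <- s1$events[!cons, ]
  sv <- utterance_script(vow, duration = 1.64)
  expect_equal(vowels_only_variant(sv)$events, sv$events)
  # nothing tagged consonant under an unreachable mu threshold
  sv2 <- utterance_script(dplyr::select(s1$events, -"consonant"),
                          duration = 1.64)
  sv2$events$consonant <- NULL
  expect_equal(vowels_only_variant(sv2, mu_threshold = 2)$events$mu,
               s1$events$mu)
})

test_that("deflection verdicts report signed differences at the peak frame", {
  tr <- tibble::tibble(frame = 1:10, time_s = (1:10) / 146,
                       f_R1 = 500, f_R2 = 1500, f_R3 = 2500, gap = FALSE)
  expect_equal(deflection_verdict(tr, tr, 5 / 146), c(0L, 0L, 0L))
  up <- dplyr::mutate(tr, f_R1 = 520, f_R2 = 1450)
  expect_equal(deflection_verdict(up, tr, 5 / 146), c(1L, -1L, 0L))
  # occluded peak: the verdict falls back to the last non-gap frame
  gapped <- dplyr::mutate(up, gap = frame >= 4)
  expect_equal(deflection_verdict(gapped, tr, 8 / 146), c(1L, -1L, 0L))
  # no comparable frame: undetermined
  allgap <- dplyr::mutate(up, gap = TRUE)
  expect_true(all(is.na(deflection_verdict(allgap, tr, 5 / 146))))
})

test_that("spectrograms localize tones and vanish on silence", {
  t <- (1:22050) / 44100
  sg <- spectrogram(sin(2 * pi * 1000 * t), rate = 44100)
  ridge <- dplyr::summarize(
    dplyr::group_by(sg, time_s),
    peak = frequency_hz[which.max(magnitude)])
  bin <- 44100 / round(0.005 * 44100)
  expect_true(all(abs(ridge$peak - 1000) <= bin))
  sg0 <- spectrogram(rep(0, 22050), rate = 44100)
  expect_true(all(sg0$magnitude == 0))
  expect_error(spectrogram(rep(0, 100), rate = 44100, window_ms = 5),
               class = "vt_invalid_parameter")
})

test_that("energy and voicing helpers behave on known signals", {
  t <- (1:44100) / 44100
  voiced <- sin(2 * pi * 120 * t)
  expect_gt(voicing_strength(voiced, rate = 44100), 0.9)
  set.seed(1)
  expect_lt(voicing_strength(runif(44100, -1, 1), rate = 44100), 0.5)
  expect_equal(voicing_strength(rep(0, 44100), rate = 44100), 0)
  ec <- energy_contour(c(rep(0, 22050), sin(2 * pi * 200 * t[1:22050])),
                       rate = 44100)
  expect_lt(max(ec$rms[ec$time_s < 0.4]), 0.05)
  expect_gt(max(ec$rms[ec$time_s > 0.6]), 0.5)
})
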