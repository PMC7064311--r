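test_that("the Gaussian event function has unit peak and stated landmarks", {
  # frame_rate 100, tp = 1 s: N_p = 100; tw = 0.2 s: N_w = 20
  E <- event_function(tp = 1, tw = 0.2, th = 0, n_frames = 200,
                      frame_rate = 100)
  expect_true(all(E >= 0 & E <= 1))
  expect_equal(E[100], 1)
  expect_equal(E[110], 0.5)          # half maximum at N_p + N_w/2
  expect_equal(E[90], 0.5)
  expect_equal(E[120], 1 / 16)       # exp(-ln 16) one width out
  # symmetry about the peak
  expect_equal(E[100 + 1:30], E[100 - 1:30])
  # sampled FWHM equals N_w within one frame
  fwhm <- sum(E >= 0.5)
  expect_lte(abs(fwhm - 20), 1)
})

test_that("a hold inserts a centered unit plateau between the Gaussian halves", {
  E <- event_function(tp = 1, tw = 0.2, th = 0.2, n_frames = 200,
                      frame_rate = 100)
  expect_true(all(E[91:110] == 1))   # plateau of N_h = 20 frames about N_p
  expect_lt(E[89], 1)
  expect_equal(E[120], 0.5)          # half maximum now N_w/2 past the plateau
  expect_true(all(E >= 0 & E <= 1))
})

test_that("times convert to frames by rounding at f_svt", {
  expect_identical(time_to_samples(0.14, 146), 20L)
  expect_identical(time_to_samples(0, 146), 0L)
  expect_identical(time_to_samples(1, 146), 146L)
  expect_error(time_to_samples(-0.1), class = "vt_invalid_parameter")
})

test_that("built-in RDP classes encode place-of-articulation deflections", {
  expect_equal(unclass(builtin_rdp("bilabial")), c(delta1 = -1, delta2 = -1, delta3 = -1))
  expect_equal(unclass(builtin_rdp("alveolar")), c(delta1 = -1, delta2 = 1, delta3 = 1))
  expect_equal(unclass(builtin_rdp("velar")), c(delta1 = -1, delta2 = 1, delta3 = -1))
  expect_error(builtin_rdp("uvular"), class = "vt_invalid_parameter")
  expect_error(rdp(0, 1.5, 0), class = "vt_invalid_parameter")
})

test_that("scripts validate their invariants with the offending event named", {
  ev <- sentence_script(1)$events
  ev$delta2[3] <- 1.5
  expect_error(utterance_script(ev, duration = 1.64), "event 3",
               class = "vt_schema_error")
  ev <- sentence_script(1)$events
  ev$tw[5] <- 0
  expect_error(utterance_script(ev, duration = 1.64), "event 5",
               class = "vt_schema_error")
  expect_error(utterance_script(sentence_script(1)$events, duration = 1.0),
               class = "vt_schema_error")  # duration before last peak
})

test_that("script JSON round-trips losslessly", {
  s <- sentence_script(2)
  path <- withr::local_tempfile(fileext = ".json")
  write_script(s, path)
  back <- read_script(path)
  expect_equal(back$events, s$events)
  expect_equal(back$duration, s$duration)
  expect_equal(back$f0, s$f0)
  expect_equal(back$abduction, s$abduction)
})

test_that("shipped sentence fixtures match the published event timing", {
  p1 <- system.file("extdata", "sentence1.json", package = "vtsynth")
  s1 <- read_script(p1)
  expect_equal(nrow(s1$events), 9)
  expect_equal(s1$events$label,
               c("d", "ao", "g", "eh", "ih", "t", "b", "ah", "g"))
  expect_equal(s1$events$tp,
               c(0.14, 0.34, 0.55, 0.79, 0.86, 0.92, 1.13, 1.27, 1.47))
  expect_equal(s1$events$th,
               c(0, 0, 0.03, 0, 0, 0, 0.03, 0, 0.01))
  expect_equal(s1$events$mu[s1$events$label == "d"], 1.1)

  s2 <- read_script(system.file("extdata", "sentence2.json", package = "vtsynth"))
  expect_equal(nrow(s2$events), 11)
  expect_equal(s2$events[1, c("tp", "tw", "th")],
               tibble::tibble(tp = 0.10, tw = 0.10, th = 0.03))
  expect_true(all(s2$events$mu[s2$events$label == "f"] == 0.98))
  expect_true(all(s2$events$th[s2$events$label == "f"] == 0.03))
  # shared symbols carry identical RDPs across the two sentences
  shared <- intersect(s1$events$label, s2$events$label)
  for (sym in shared) {
    expect_equal(unique(s1$events[s1$events$label == sym,
                                  c("delta1", "delta2", "delta3", "mu")]),
                 unique(s2$events[s2$events$label == sym,
                                  c("delta1", "delta2", "delta3", "mu")]),
                 label = sym)
  }
})

test_that("fixture regeneration is byte-identical", {
  dir <- withr::local_tempdir()
  write_sentence_fixtures(dir)
  a <- readLines(file.path(dir, "sentence1.json"))
  write_sentence_fixtures(dir)
  expect_identical(readLines(file.path(dir, "sentence1.json")), a)
})
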