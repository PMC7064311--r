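test_that("combined sensitivities are linear in the RDP", {
  om <- neutral_tract_standin()
  sf <- adjust_sensitivity(sensitivity_functions(om, side_branch()))
  expect_equal(combine_sensitivities(sf, c(1, 0, 0)), sf$Z[, 1])
  expect_equal(combine_sensitivities(sf, c(0, 0, 0)), rep(0, 44))
  expect_equal(combine_sensitivities(sf, c(-1, -1, -1)),
               -(sf$Z[, 1] + sf$Z[, 2] + sf$Z[, 3]))
})

test_that("deformation multipliers satisfy the closure semantics", {
  om <- neutral_tract_standin()
  sf <- adjust_sensitivity(sensitivity_functions(om, side_branch()))
  y <- combine_sensitivities(sf, builtin_rdp("alveolar"))
  imin <- which.min(y)

  # E = 0: neutral identity
  d0 <- deformation_frame(y, 0, 1)
  expect_equal(d0$D, rep(1, 44))

  # mu E = 1: complete closure exactly at the minimum of y
  d1 <- deformation_frame(y, 1, 1)
  expect_equal(d1$D[imin], 0)
  expect_equal(sum(d1$D == 0), 1)
  expect_equal(min(om$areas * d1$D), 0)
  # synergistic expansion where y > 0
  expect_true(all(d1$D[y > 0] > 1))

  # mu > 1: the closure spreads to a contiguous run
  d2 <- deformation_frame(y, 1, 1.1)
  zero <- which(d2$D == 0)
  expect_gte(length(zero), 2)
  expect_true(all(diff(zero) == 1))

  # mu < 1 never fully occludes
  expect_true(all(deformation_frame(y, 1, 0.9)$D > 0))

  # monotone constriction: higher drive never enlarges the constriction
  # site (the minimum of y), and the fully driven tract is the narrowest
  drives <- seq(0, 1.2, by = 0.1)
  site <- vapply(drives, function(mu) {
    (om$areas * deformation_frame(y, 1, mu)$D)[imin]
  }, numeric(1))
  expect_true(all(diff(site) <= 1e-12))
  mins <- vapply(drives, function(mu) min(om$areas * deformation_frame(y, 1, mu)$D),
                 numeric(1))
  expect_equal(mins[length(mins)], min(mins))
})

test_that("degenerate deflection patterns are rejected or neutral", {
  expect_error(deformation_frame(abs(sin(1:44)), 1, 1),
               class = "vt_degenerate_pattern")
  dn <- deformation_frame(rep(0, 44), 1, 1)
  expect_true(dn$degenerate)
  expect_equal(dn$D, rep(1, 44))
})

test_that("zero-event frames reproduce the neutral tract bit-exactly", {
  om <- neutral_tract_standin()
  mv <- render_movie(empty_script(duration = 0.3), om, side_branch())
  expect_equal(nrow(mv$frames), 44L)  # round(0.3 * 146)
  for (n in seq_len(nrow(mv$frames))) {
    expect_identical(mv$frames[n, ], om$areas)
  }
})

test_that("a single-event frame equals the direct single-event computation", {
  om <- neutral_tract_standin()
  br <- side_branch()
  scr <- one_event_script(mu = 0.7)
  mv <- render_movie(scr, om, br)
  n_peak <- time_to_samples(scr$events$tp[1], scr$frame_rate)
  E <- event_function(scr$events[1, ], n_frames = scr$n_frames,
                      frame_rate = scr$frame_rate)
  sf <- adjust_sensitivity(sensitivity_functions(om, br))
  y <- combine_sensitivities(sf, c(scr$events$delta1, scr$events$delta2,
                                   scr$events$delta3))
  D <- deformation_frame(y, E[n_peak], scr$events$mu)$D
  expect_equal(mv$frames[n_peak, ], om$areas * D, tolerance = 1e-12)
})

test_that("occlusion at the peak follows the constriction degree", {
  om <- neutral_tract_standin()
  br <- side_branch()
  mv_open <- render_movie(one_event_script(mu = 0.8), om, br)
  expect_true(all(mv_open$frames > 0))
  # frame-aligned peak (t_p = 30/146 s) so the sampled event reaches 1
  tp <- 30 / 146
  mv_closed <- render_movie(one_event_script(mu = 1.0, tp = tp), om, br)
  expect_equal(min(mv_closed$frames[30, ]), 0)
})

test_that("movie tables round-trip through delimited text", {
  om <- neutral_tract_standin()
  mv <- render_movie(one_event_script(mu = 0.7, duration = 0.25, tp = 0.12,
                                      tw = 0.08), om, side_branch())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_movie_table(mv, path)
  back <- read_movie_table(path, om)
  expect_equal(back$frames, mv$frames, tolerance = 1e-9)
  expect_equal(back$frame_rate, mv$frame_rate, tolerance = 1e-6)
})
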