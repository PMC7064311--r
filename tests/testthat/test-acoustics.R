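test_that("lossless uniform closed-open tube peaks at quarter-wave frequencies", {
  tube <- uniform_tube()
  fr <- frequency_response(tube, losses = lossless)
  f <- find_resonances(fr)$f_R
  expect_equal(f, quarter_wave(tube$grid$total_length),
               tolerance = 0.005)
  # doubling every area leaves a uniform tube's resonances unchanged
  f2 <- find_resonances(frequency_response(
    area_function(rep(6, 44)), losses = lossless))$f_R
  expect_equal(f2, f, tolerance = 1e-4)
})

test_that("losses keep peaks within 5% of lossless and magnitudes finite", {
  tube <- uniform_tube()
  f_ll <- find_resonances(frequency_response(tube, losses = lossless))$f_R
  fr <- frequency_response(tube)
  expect_true(all(is.finite(fr$magnitude_db)))
  f_lo <- find_resonances(fr)$f_R
  expect_true(all(abs(f_lo / f_ll - 1) < 0.05))
})

test_that("resonances are grid-refinement stable for the uniform tube", {
  f44 <- find_resonances(frequency_response(uniform_tube(n = 44),
                                            losses = lossless))$f_R
  # half the sections, double the length: same total tube
  g22 <- tubelet_grid(n_sections = 22, sampling_rate = 22050)
  f22 <- find_resonances(frequency_response(
    area_function(rep(3, 22), g22), losses = lossless))$f_R
  expect_true(all(abs(f22 / f44 - 1) < 0.01))
})

test_that("the piriform branch perturbs but does not reorganize resonances", {
  om <- neutral_tract_standin()
  f_off <- find_resonances(frequency_response(om))$f_R
  f_on <- find_resonances(frequency_response(om, side_branch()))$f_R
  expect_true(all(abs(f_on / f_off - 1) < 0.10))
})

test_that("degenerate inputs raise classed errors", {
  occluded <- area_function(c(rep(3, 20), 0, rep(3, 23)))
  expect_error(frequency_response(occluded), class = "vt_degenerate_tract")
  expect_error(frequency_response(uniform_tube(),
                                  f_grid = c(100, 50)),
               class = "vt_invalid_parameter")
  # a peak-free (monotone) response cannot yield three resonances
  fr <- frequency_response(uniform_tube(), losses = lossless,
                           f_grid = seq(50, 400, 10))
  expect_error(find_resonances(fr, 3), class = "vt_resolution_error")
})

test_that("modal distributions show the closed-open standing-wave patterns", {
  tube <- uniform_tube()
  f <- quarter_wave(tube$grid$total_length)
  md <- modal_distributions(tube, losses = lossless, f_R = f[1:2])
  u1 <- Mod(md$flows[, 1]); p1 <- Mod(md$pressures[, 1])
  # quarter-wave mode: flow node at the glottis, antinode at the lips
  expect_lt(u1[1], 0.1 * max(u1))
  expect_gt(u1[44], 0.9 * max(u1))
  expect_gt(p1[1], 0.9 * max(p1))
  expect_lt(p1[44], 0.15 * max(p1))
  # three-quarter-wave mode: one interior pressure node
  p2 <- Mod(md$pressures[, 2])
  interior <- p2[3:42]
  expect_equal(sum(diff(sign(diff(interior))) == 2), 1)
  expect_error(modal_distributions(tube, f_R = -5),
               class = "vt_invalid_parameter")
})
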