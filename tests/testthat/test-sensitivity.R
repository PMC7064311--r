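test_that("acoustic energies are quadratic forms with the right structure", {
  tube <- uniform_tube()
  f1 <- quarter_wave(tube$grid$total_length)[1]
  md <- modal_distributions(tube, losses = lossless, f_R = f1)
  p <- md$pressures[, 1]; u <- md$flows[, 1]
  en0 <- acoustic_energies(tube, p, u * 0, sound_speed = 35000)
  expect_true(all(en0$kinetic == 0))
  en <- acoustic_energies(tube, p, u, sound_speed = 35000)
  en2 <- acoustic_energies(tube, 3 * p, 3 * u, sound_speed = 35000)
  expect_equal(en2$kinetic, 9 * en$kinetic)
  expect_equal(en2$potential, 9 * en$potential)
  # quarter-wave mode: kinetic energy toward the lips, potential toward glottis
  expect_gt(sum(en$kinetic[23:44]), sum(en$kinetic[1:22]))
  expect_gt(sum(en$potential[1:22]), sum(en$potential[23:44]))
})

test_that("sensitivity functions are bounded, polarity-structured, and scale-free", {
  tube <- uniform_tube()
  sf <- sensitivity_functions(tube, losses = lossless)
  expect_true(all(abs(sf$S) <= 1))
  # lip constriction lowers the first resonance: S_1 > 0 at the lips,
  # < 0 at the glottis
  expect_gt(sf$S[44, 1], 0)
  expect_lt(sf$S[1, 1], 0)
  # uniform relative perturbation of a uniform tube shifts nothing
  expect_true(all(abs(colSums(sf$S)) < 0.05))
})

test_that("predicted shifts match brute-force recomputation (lossless tract)", {
  om <- neutral_tract_standin()
  sf <- sensitivity_functions(om, losses = lossless)
  expect_equal(predict_resonance_shift(sf, rep(0, 44)), rep(0, 3))
  dA <- rep(0, 44); dA[40] <- 0.01
  pred <- predict_resonance_shift(sf, dA)
  expect_equal(predict_resonance_shift(sf, -dA), -pred)
  om2 <- area_function(om$areas * (1 + dA), om$grid)
  f2 <- find_resonances(frequency_response(om2, losses = lossless))$f_R
  act <- (f2 - sf$f_R) / sf$f_R
  ok <- abs(pred - act) / pmax(abs(act), 1e-12) < 0.10 | abs(pred - act) < 1e-3
  expect_true(all(ok))
})

test_that("first-order predictions hold at seeded random sections", {
  om <- neutral_tract_standin()
  sf <- sensitivity_functions(om, losses = lossless)
  set.seed(42)
  for (s in sample(44, 5)) {
    dA <- rep(0, 44); dA[s] <- 0.01
    pred <- predict_resonance_shift(sf, dA)
    om2 <- area_function(om$areas * (1 + dA), om$grid)
    f2 <- find_resonances(frequency_response(om2, losses = lossless))$f_R
    act <- (f2 - sf$f_R) / sf$f_R
    ok <- abs(pred - act) / pmax(abs(act), 1e-12) < 0.10 | abs(pred - act) < 1e-3
    expect_true(all(ok), label = sprintf("section %d", s))
  }
})

test_that("adjustment balances, normalizes, and preserves polarity", {
  for (af in list(uniform_tube(), neutral_tract_standin())) {
    sf <- adjust_sensitivity(sensitivity_functions(af, side_branch()))
    for (j in 1:3) {
      Z <- sf$Z[, j]; S <- sf$S[, j]
      expect_equal(max(abs(Z)), 1)
      nz <- S != 0
      expect_equal(sign(Z[nz]), sign(S[nz]))
    }
  }
  # non-negative input stays non-negative
  z <- adjust_sensitivity(abs(sin(seq(0, 3, length.out = 44))) + 0.01)
  expect_true(all(z >= 0))
  expect_error(adjust_sensitivity(rep(0, 44)), class = "vt_degenerate_pattern")
})

test_that("sensitivities are invariant to modal drive amplitude", {
  tube <- uniform_tube()
  f1 <- quarter_wave(tube$grid$total_length)[1]
  md <- modal_distributions(tube, losses = lossless, f_R = f1)
  mk_S <- function(scale) {
    en <- acoustic_energies(tube, scale * md$pressures[, 1],
                            scale * md$flows[, 1], sound_speed = 35000)
    (en$kinetic - en$potential) / sum(en$kinetic + en$potential)
  }
  expect_equal(mk_S(10), mk_S(1), tolerance = 1e-12)
})
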