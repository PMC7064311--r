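# Shared fixtures built in code.

uniform_tube <- function(area = 3, n = 44) {
  area_function(rep(area, n), tubelet_grid(n_sections = n))
}

# Closed-open quarter-wave resonances of a uniform tube, Hz.
quarter_wave <- function(total_length, k = 1:3, c0 = 35000) {
  (2 * k - 1) * c0 / (4 * total_length)
}

lossless <- loss_config(lossless = TRUE)

# A short script with a single event, for sequencing checks.
one_event_script <- function(mu = 0.7, delta = c(-1, 1, 1), tp = 0.2,
                             tw = 0.12, th = 0, duration = 0.4) {
  utterance_script(
    tibble::tibble(label = "x", delta1 = delta[1], delta2 = delta[2],
                   delta3 = delta[3], mu = mu, tp = tp, tw = tw, th = th),
    duration = duration, frame_rate = 146
  )
}

empty_script <- function(duration = 0.3, frame_rate = 146) {
  utterance_script(
    tibble::tibble(label = character(), delta1 = numeric(),
                   delta2 = numeric(), delta3 = numeric(), mu = numeric(),
                   tp = numeric(), tw = numeric(), th = numeric()),
    duration = duration, frame_rate = frame_rate
  )
}
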