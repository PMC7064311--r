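# RDP, mu assignments for the demonstration sentences. Timing (tp/tw/th)
# follows the published event tables for the two sentences; deflection
# magnitudes and constriction degrees for most events are editorial choices
# (only directions are constrained): stops use the canonical place patterns
# with mu = 1.0 ({d}: 1.1), fricative {f} deflects the first two resonances
# down with mu = 0.98, liquids use delta = (-0.3, 0, -/+1) with mu = 0.8
# ({r}) and 0.9 ({l}), and vowels use target-formant-relative signs with
# mu = 0.5.
sentence_phone_params <- function() {
  tibble::tribble(
    ~label, ~delta1, ~delta2, ~delta3, ~mu,  ~consonant,
    "d",    -1,       1,       1,      1.1,  TRUE,
    "t",    -1,       1,       1,      1.0,  TRUE,
    "g",    -1,       1,      -1,      1.0,  TRUE,
    "b",    -1,      -1,      -1,      1.0,  TRUE,
    "f",    -1,      -1,       0,      0.98, TRUE,
    "r",    -0.3,     0,      -1,      0.8,  TRUE,
    "l",    -0.3,     0,       1,      0.9,  TRUE,
    "ao",    1,      -1,       0,      0.5,  FALSE,
    "eh",   -0.5,     0.7,     0.3,    0.5,  FALSE,
    "ih",   -0.8,     1,       0.5,    0.5,  FALSE,
    "ah",    1,      -0.5,     0,      0.5,  FALSE,
    "aa",    1,      -0.8,     0,      0.5,  FALSE
  )
}

#' Demonstration sentence scripts
#'
#' Builds the utterance scripts for the two demonstration sentences,
#' "a dog ate a bug" (9 events) and "a frog ate a fly" (11 events), with
#' the published event timing (peak, width, hold; both sentences last
#' 1.64 s at f_svt = 146 Hz). Each begins and returns to the unstressed
#' neutral vowel, which is realized by the absence of events. The voice
#' source carries a rising-falling F0 contour and abduction gestures that
#' devoice the {t} (and, in sentence 2, the two {f}s).
#'
#' @param which 1 or `"dog"` for "a dog ate a bug"; 2 or `"frog"` for
#'   "a frog ate a fly".
#' @return An [utterance_script()].
#' @examples
#' sentence_script(1)
#' @export
sentence_script <- function(which = 1) {
  which <- if (identical(which, "dog")) 1 else if (identical(which, "frog")) 2 else which
  pp <- sentence_phone_params()
  if (which == 1) {
    ev <- tibble::tibble(
      label = c("d", "ao", "g", "eh", "ih", "t", "b", "ah", "g"),
      tp = c(0.14, 0.34, 0.55, 0.79, 0.86, 0.92, 1.13, 1.27, 1.47),
      tw = c(0.10, 0.21, 0.14, 0.21, 0.21, 0.10, 0.07, 0.24, 0.14),
      th = c(0, 0, 0.03, 0, 0, 0, 0.03, 0, 0.01)
    )
    abd <- tibble::tibble(start = 0.86, end = 1.02)
  } else if (which == 2) {
    ev <- tibble::tibble(
      label = c("f", "r", "ao", "g", "eh", "ih", "t", "f", "l", "aa", "ih"),
      tp = c(0.10, 0.21, 0.34, 0.58, 0.79, 0.86, 0.92, 1.13, 1.23, 1.37, 1.47),
      tw = c(0.10, 0.10, 0.17, 0.14, 0.21, 0.21, 0.10, 0.10, 0.10, 0.21, 0.21),
      th = c(0.03, 0.03, 0, 0.03, 0, 0, 0, 0.03, 0, 0, 0)
    )
    abd <- tibble::tibble(start = c(0.03, 0.86, 1.06),
                          end = c(0.18, 1.02, 1.21))
  } else {
    vt_stop("which must be 1/'dog' or 2/'frog'", "vt_invalid_parameter")
  }
  ev <- dplyr::left_join(ev, pp, by = "label")
  utterance_script(
    ev[, c("label", "delta1", "delta2", "delta3", "mu", "tp", "tw", "th",
           "consonant")],
    duration = 1.64, frame_rate = 146,
    f0 = tibble::tibble(time = c(0, 0.6, 1.2, 1.64),
                        f0 = c(105, 125, 110, 85)),
    abduction = abd
  )
}

#' Write the demonstration sentence fixtures
#'
#' Writes `sentence1.json` and `sentence2.json` (the scripts from
#' [sentence_script()]) into a directory. Regeneration is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_sentence_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "sentence1.json")
  p2 <- file.path(dir, "sentence2.json")
  write_script(sentence_script(1), p1)
  write_script(sentence_script(2), p2)
  invisible(c(p1, p2))
}
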