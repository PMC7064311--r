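#' Combine adjusted sensitivity functions under an RDP
#'
#' Forms the weighted sum `y(i) = delta1 Z_1(i) + delta2 Z_2(i) +
#' delta3 Z_3(i)`; its minimum marks where the tract will constrict and its
#' positive regions where it will synergistically expand.
#'
#' @param Z An `n_sections` x 3 matrix of adjusted sensitivity functions
#'   (the `Z` field of an adjusted [sensitivity_functions()] object, which
#'   may be passed directly).
#' @param rdp An [rdp()] or numeric length-3 vector.
#' @return Numeric vector `y`, one value per tubelet.
#' @export
combine_sensitivities <- function(Z, rdp) {
  if (inherits(Z, "sensitivity_functions")) {
    if (is.null(Z$Z)) vt_stop("sensitivity functions not adjusted yet; call adjust_sensitivity()",
                              "vt_invalid_parameter")
    Z <- Z$Z
  }
  if (ncol(Z) != 3 || length(rdp) != 3) {
    vt_stop("need three adjusted sensitivity functions and three deltas",
            "vt_invalid_parameter")
  }
  as.numeric(Z %*% as.numeric(rdp))
}

#' Deformation multipliers for one event at one frame
#'
#' Converts the combined sensitivity `y(i)`, the event amplitude `E_n`, and
#' the constriction degree `mu` into per-section deformation multipliers
#' `D(i) = 1 - mu * E_n * y(i) / min(y)`, clipped below at 0. At `E_n = 0`
#' the tract is neutral (`D` identically 1); at `mu * E_n = 1` the section
#' at the minimum of `y` closes completely; for `mu * E_n > 1` the closure
#' spreads to a contiguous run of sections; sections with `y(i) > 0`
#' expand (`D > 1`).
#'
#' @param y Combined sensitivity vector from [combine_sensitivities()];
#'   must attain a negative minimum (some section driven toward
#'   constriction) unless identically zero, which is treated as "no event".
#' @param E_n Event amplitude in [0, 1].
#' @param mu Constriction degree, >= 0.
#' @return A list of class `deformation_frame`: `D` (multipliers), `y`,
#'   and `drive` (`mu * E_n`).
#' @export
deformation_frame <- function(y, E_n, mu) {
  if (E_n < 0 || E_n > 1 || mu < 0) {
    vt_stop("need E_n in [0, 1] and mu >= 0", "vt_invalid_parameter")
  }
  if (all(y == 0)) {
    return(structure(list(D = rep(1, length(y)), y = y, drive = 0,
                          degenerate = TRUE),
                     class = "deformation_frame"))
  }
  if (min(y) >= 0) {
    vt_stop("combined sensitivity has no negative minimum: no constriction direction defined",
            "vt_degenerate_pattern")
  }
  D <- 1 - mu * E_n * y / min(y)
  structure(list(D = pmax(D, 0), y = y, drive = mu * E_n, degenerate = FALSE),
            class = "deformation_frame")
}

# Order of application of simultaneously active events: ascending
# constriction degree, ties broken by ascending peak time, then script
# order.
event_order <- function(events) {
  order(events$mu, events$tp, seq_len(nrow(events)))
}

#' Render an utterance script to a time-varying area function
#'
#' Runs the multi-event sequencing loop. For every modulation frame, the
#' active events (amplitude at or above `activity_threshold`) are applied
#' in ascending order of constriction degree `mu`: starting from the
#' neutral tract, each iteration recomputes the resonances and adjusted
#' sensitivity functions of the current working tract, combines them under
#' the event's RDP, builds the deformation multipliers for the event's
#' `mu` and amplitude, and multiplies them into the working tract, which
#' feeds the next event. Frames with no active event reproduce the neutral
#' tract exactly (this realizes the unstressed neutral vowel).
#'
#' When an earlier event has (nearly) occluded the working tract, areas are
#' floored at `occlusion_floor` for the acoustic/sensitivity computation
#' only; the geometric areas keep their true values.
#'
#' @param script An [utterance_script()].
#' @param neutral An [area_function()], the neutral tract.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @param activity_threshold Events with amplitude below this are skipped
#'   at that frame (default 1e-3).
#' @param occlusion_floor Minimum area (cm^2) substituted during in-loop
#'   sensitivity recomputation (default 0.01).
#' @param cache_sensitivities Fast mode: reuse each frame's first-iteration
#'   sensitivity functions (computed on the neutral tract, which is the
#'   same every frame) instead of recomputing per event. Off by default;
#'   the faithful mode recomputes for every event at every frame.
#' @param f_grid Frequency grid for resonance finding.
#' @return An object of class `tract_movie`: list with `frames`
#'   (`n_frames` x `n_sections` area matrix, cm^2), `times` (s),
#'   `frame_rate`, `neutral`, `script`.
#' @export
render_movie <- function(script, neutral, branch = NULL,
                         losses = loss_config(),
                         activity_threshold = 1e-3, occlusion_floor = 0.01,
                         cache_sensitivities = FALSE,
                         f_grid = seq(50, 5000, by = 10)) {
  stopifnot(inherits(script, "utterance_script"),
            inherits(neutral, "area_function"))
  n_frames <- script$n_frames
  nx <- neutral$grid$n_sections
  ev <- script$events
  frames <- matrix(rep(neutral$areas, each = n_frames), n_frames, nx)
  if (nrow(ev) > 0) {
    # per-frame event amplitudes, n_frames x n_events
    E <- vapply(seq_len(nrow(ev)), function(k) {
      event_function(ev[k, ], n_frames = n_frames,
                     frame_rate = script$frame_rate)
    }, numeric(n_frames))
    ord <- event_order(ev)
    neutral_sf <- NULL
    for (n in seq_len(n_frames)) {
      active <- ord[E[n, ord] >= activity_threshold]
      if (length(active) == 0) next
      working <- neutral$areas
      for (k in active) {
        af_k <- area_function(pmax(working, occlusion_floor), neutral$grid)
        sf <- NULL
        if (cache_sensitivities && identical(working, neutral$areas)) {
          if (is.null(neutral_sf)) {
            neutral_sf <- adjust_sensitivity(
              sensitivity_functions(af_k, branch, losses, f_grid = f_grid))
          }
          sf <- neutral_sf
        }
        if (is.null(sf)) {
          sf <- adjust_sensitivity(
            sensitivity_functions(af_k, branch, losses, f_grid = f_grid))
        }
        y <- combine_sensitivities(sf, c(ev$delta1[k], ev$delta2[k], ev$delta3[k]))
        df <- deformation_frame(y, E[n, k], ev$mu[k])
        working <- working * df$D
      }
      frames[n, ] <- working
    }
  }
  structure(
    list(frames = frames, times = seq_len(n_frames) / script$frame_rate,
         frame_rate = script$frame_rate, neutral = neutral, script = script),
    class = "tract_movie"
  )
}

#' @export
print.tract_movie <- function(x, ...) {
  cat(sprintf("<tract_movie> %d frames x %d sections @ %g Hz (%.2f s), min area %.4f cm^2\n",
              nrow(x$frames), ncol(x$frames), x$frame_rate,
              nrow(x$frames) / x$frame_rate, min(x$frames)))
  invisible(x)
}

#' @export
as_tibble.tract_movie <- function(x, ...) {
  nx <- ncol(x$frames)
  tibble::tibble(
    frame = rep(seq_len(nrow(x$frames)), each = nx),
    time_s = rep(x$times, each = nx),
    section = rep(seq_len(nx), nrow(x$frames)),
    distance_cm = rep(x$neutral$grid$distances, nrow(x$frames)),
    area_cm2 = as.vector(t(x$frames))
  )
}

#' Read and write tract-movie tables
#'
#' A tract movie is exported as whitespace-delimited text with one row per
#' (frame, section): `frame time_s section distance_cm area_cm2`.
#'
#' @param movie A `tract_movie`.
#' @param path File path.
#' @param neutral The neutral [area_function()] to attach on import (its
#'   grid must match the table).
#' @return `write_movie_table()` returns `path` invisibly;
#'   `read_movie_table()` returns a `tract_movie` (without a script).
#' @export
write_movie_table <- function(movie, path) {
  tab <- as_tibble(movie)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame time_s section distance_cm area_cm2", con)
  writeLines(sprintf("%d\t%.9f\t%d\t%.9f\t%.9f", tab$frame, tab$time_s,
                     tab$section, tab$distance_cm, tab$area_cm2), con)
  invisible(path)
}

#' @rdname write_movie_table
#' @export
read_movie_table <- function(path, neutral) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("frame", "time_s", "section",
                                         "distance_cm", "area_cm2"))
  n_frames <- max(tab$frame)
  nx <- max(tab$section)
  if (nx != neutral$grid$n_sections) {
    vt_stop("movie table section count does not match the neutral grid",
            "vt_format_error")
  }
  frames <- matrix(NA_real_, n_frames, nx)
  frames[cbind(tab$frame, tab$section)] <- tab$area_cm2
  dt <- tab$time_s[tab$frame == 1][1]
  structure(
    list(frames = frames, times = sort(unique(tab$time_s)),
         frame_rate = 1 / dt, neutral = neutral, script = NULL),
    class = "tract_movie"
  )
}
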