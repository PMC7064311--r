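#' End-to-end synthesis pipeline
#'
#' Runs the full pipeline for one utterance script: render the
#' time-varying area function, synthesize audio, track resonances (all
#' three variants: neutral reference, vowels-only, all events), and write
#' every artifact plus a run manifest into an output directory. This is
#' the programmatic equivalent of the `synth` subcommand of the bundled
#' command-line tool (`system.file("exec", "vtsynth", package =
#' "vtsynth")`).
#'
#' @param script Path to a JSON utterance script, or an
#'   [utterance_script()].
#' @param out_dir Output directory (created if needed).
#' @param neutral Path to an area table, or an [area_function()];
#'   default the built-in neutral stand-in.
#' @param branch A [side_branch()], or `NULL` to disable the piriform
#'   branch.
#' @param losses A [loss_config()].
#' @param seed Seed for the turbulence noise streams.
#' @param cache_sensitivities Fast sensitivity mode for [render_movie()].
#' @param tracks Also compute the three resonance-track variants (default
#'   TRUE; the rendering of the vowels-only variant roughly doubles the
#'   run time).
#' @return Invisibly, a list with `paths` (the files written) and the
#'   in-memory `movie`, `audio`, and `tracks` objects.
#' @export
run_synthesis_pipeline <- function(script, out_dir, neutral = NULL,
                                   branch = side_branch(),
                                   losses = loss_config(), seed = 1L,
                                   cache_sensitivities = FALSE,
                                   tracks = TRUE) {
  if (is.character(script)) script <- read_script(script)
  if (is.null(neutral)) neutral <- neutral_tract_standin()
  else if (is.character(neutral)) {
    if (!file.exists(neutral)) {
      vt_stop(paste0("tract file not found: ", neutral), "vt_io_error")
    }
    neutral <- read_area_table(neutral)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  movie <- render_movie(script, neutral, branch, losses,
                        cache_sensitivities = cache_sensitivities)
  audio <- synthesize(movie, noise = noise_params(rng_seed = seed),
                      losses = losses)
  paths <- list(
    wav = file.path(out_dir, "audio.wav"),
    movie = file.path(out_dir, "movie.tsv"),
    diagnostics = file.path(out_dir, "diagnostics.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_wav(audio, paths$wav)
  write_movie_table(movie, paths$movie)
  utils::write.table(as.data.frame(audio$diagnostics), paths$diagnostics,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  trk <- NULL
  if (tracks) {
    neutral_movie <- render_movie(
      utterance_script(script$events[0, ], duration = script$duration,
                       frame_rate = script$frame_rate, f0 = script$f0,
                       abduction = script$abduction),
      neutral, branch, losses)
    trk <- dplyr::bind_rows(
      track_resonances(neutral_movie, branch, losses, variant = "neutral"),
      track_resonances(render_movie(vowels_only_variant(script), neutral,
                                    branch, losses,
                                    cache_sensitivities = cache_sensitivities),
                       branch, losses, variant = "vowels_only"),
      track_resonances(movie, branch, losses, variant = "all_events")
    )
    paths$tracks <- file.path(out_dir, "tracks.tsv")
    write_tracks_table(trk, paths$tracks)
  }
  manifest <- list(
    package = "vtsynth",
    version = as.character(utils::packageVersion("vtsynth")),
    seed = seed,
    n_events = nrow(script$events),
    duration_s = script$duration,
    frame_rate_hz = script$frame_rate,
    branch = !is.null(branch),
    lossless = isTRUE(losses$lossless),
    cache_sensitivities = cache_sensitivities,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, movie = movie, audio = audio, tracks = trk))
}

#' Sensitivity report for a tract
#'
#' Computes and writes the frequency response, resonances, and raw and
#' adjusted sensitivity functions of an area function (the `sensitivity`
#' subcommand of the command-line tool).
#'
#' @param neutral Path to an area table, or an [area_function()];
#'   default the built-in stand-in.
#' @param out_dir Output directory.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @return Invisibly, a list with the table paths plus `resonance_set` and
#'   the adjusted sensitivity `functions`.
#' @export
sensitivity_report <- function(neutral = NULL, out_dir,
                               branch = side_branch(),
                               losses = loss_config()) {
  if (is.null(neutral)) neutral <- neutral_tract_standin()
  else if (is.character(neutral)) neutral <- read_area_table(neutral)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fr <- frequency_response(neutral, branch, losses)
  res <- find_resonances(fr)
  sf <- adjust_sensitivity(sensitivity_functions(neutral, branch, losses,
                                                 resonances = res))
  paths <- list(response = file.path(out_dir, "frequency_response.tsv"),
                resonances = file.path(out_dir, "resonances.tsv"),
                sensitivity = file.path(out_dir, "sensitivity.tsv"))
  utils::write.table(as.data.frame(as_tibble(fr)), paths$response,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(tidy(res)), paths$resonances,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(tidy(sf)), paths$sensitivity,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, list(resonance_set = res, functions = sf)))
}
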