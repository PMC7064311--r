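#' Tubelet grid for a discretized vocal tract
#'
#' The vocal tract is represented as a chain of `n_sections` uniform
#' cylindrical tubelets of equal length. The section length is tied to the
#' audio sampling rate by the wave-propagation algorithm: a wave crosses one
#' tubelet in half an audio sample, so `section_length = sound_speed /
#' (2 * sampling_rate)`. With the defaults (44 sections, c = 35000 cm/s,
#' 44100 Hz) each tubelet is 0.396825 cm long and the tract measures
#' 17.46 cm from glottis to lips.
#'
#' Sections are indexed 1..`n_sections` from the glottis to the lips; the
#' distance of section `i` from the glottis is the position of its lip-side
#' edge, `i * section_length`.
#'
#' @param n_sections Number of tubelet sections (default 44).
#' @param sound_speed Speed of sound in cm/s (default 35000).
#' @param sampling_rate Acoustic sampling rate in Hz (default 44100).
#' @return An object of class `tubelet_grid` with fields `n_sections`,
#'   `section_length` (cm), `sound_speed`, `sampling_rate`, `distances`
#'   (lip-side edge of each section, cm) and `total_length` (cm).
#' @examples
#' g <- tubelet_grid()
#' g$section_length      # 0.396825
#' g$total_length        # 17.46
#' @export
tubelet_grid <- function(n_sections = 44, sound_speed = 35000,
                         sampling_rate = 44100) {
  if (n_sections < 1 || sound_speed <= 0 || sampling_rate <= 0) {
    vt_stop("all tubelet_grid arguments must be positive", "vt_invalid_parameter")
  }
  n_sections <- as.integer(n_sections)
  L <- sound_speed / (2 * sampling_rate)
  structure(
    list(
      n_sections = n_sections,
      section_length = L,
      sound_speed = sound_speed,
      sampling_rate = sampling_rate,
      distances = seq_len(n_sections) * L,
      total_length = n_sections * L
    ),
    class = "tubelet_grid"
  )
}

#' @export
print.tubelet_grid <- function(x, ...) {
  cat(sprintf("<tubelet_grid> %d sections x %.6f cm = %.2f cm (c = %g cm/s, Fs = %g Hz)\n",
              x$n_sections, x$section_length, x$total_length,
              x$sound_speed, x$sampling_rate))
  invisible(x)
}

#' Area function on a tubelet grid
#'
#' An area function assigns a cross-sectional area in cm^2 to every tubelet,
#' glottis first. Zero areas are permitted here (a complete occlusion); the
#' frequency-domain acoustics refuse them, while the time-domain synthesizer
#' treats them as closed junctions.
#'
#' @param areas Numeric vector of cross-sectional areas, cm^2, glottis first.
#' @param grid A [tubelet_grid()]; defaults to one sized to `areas`.
#' @return An object of class `area_function` with fields `areas` and `grid`.
#' @export
area_function <- function(areas, grid = tubelet_grid(n_sections = length(areas))) {
  areas <- as.numeric(areas)
  if (length(areas) != grid$n_sections) {
    vt_stop(sprintf("length(areas) [%d] != grid$n_sections [%d]",
                    length(areas), grid$n_sections), "vt_invalid_parameter")
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    vt_stop("areas must be finite and non-negative", "vt_invalid_parameter")
  }
  structure(list(areas = areas, grid = grid), class = "area_function")
}

#' @export
print.area_function <- function(x, ...) {
  cat(sprintf("<area_function> %d sections, %.2f cm, areas %.3f..%.3f cm^2 (min %.3f)\n",
              x$grid$n_sections, x$grid$total_length,
              x$areas[1], x$areas[length(x$areas)], min(x$areas)))
  invisible(x)
}

#' @export
as_tibble.area_function <- function(x, ...) {
  tibble::tibble(
    section = seq_len(x$grid$n_sections),
    distance_cm = x$grid$distances,
    area_cm2 = x$areas
  )
}

#' Parametric stand-in for the neutral vocal tract
#'
#' The neutral configuration is the tract shape produced in the absence of
#' any acoustic event (it realizes the unstressed neutral vowel). The
#' published adult-male table this model was demonstrated with is not
#' shipped; this function builds a smooth, strictly positive stand-in with
#' the same qualitative anatomy: a narrow laryngeal inlet, a wider pharynx,
#' and a mildly tapered oral cavity. Use [read_area_table()] to substitute a
#' measured area function.
#'
#' The shape is a sum of fixed Gaussian bumps over relative distance from
#' the glottis and is deterministic for fixed parameters.
#'
#' @param grid A [tubelet_grid()].
#' @param pharynx_scale,oral_scale Multiplicative scalings of the pharyngeal
#'   and oral cavity bumps (defaults 1).
#' @return An `area_function`, all areas in (0, 10] cm^2.
#' @export
neutral_tract_standin <- function(grid = tubelet_grid(), pharynx_scale = 1,
                                  oral_scale = 1) {
  r <- seq_len(grid$n_sections) / grid$n_sections  # relative distance, 0..1
  a <- 0.6 +
    pharynx_scale * 1.2 * exp(-((r - 0.38) / 0.25)^2) +
    oral_scale    * 1.5 * exp(-((r - 0.78) / 0.20)^2) -
    0.5 * exp(-((r - 0.97) / 0.07)^2)
  a <- pmin(pmax(a, 0.2), 10)
  area_function(a, grid)
}

#' Piriform sinus side branch
#'
#' The piriform sinuses are modeled as a single short, closed side tube
#' coupled to the main tract near the larynx. The model this package
#' implements attaches it 2.4 cm from the glottis; the branch dimensions are
#' a documented, user-overridable stand-in (a tapered closed tube of
#' plausible piriform volume).
#'
#' @param attach_distance_cm Distance from the glottis of the coupling
#'   point, cm (default 2.4).
#' @param branch_areas Areas of the branch tubelets, cm^2, attachment end
#'   first; default 8 sections tapering 1.5 to 0.3 cm^2.
#' @param section_length_cm Branch tubelet length, cm; defaults to the main
#'   grid's section length.
#' @return An object of class `side_branch`.
#' @export
side_branch <- function(attach_distance_cm = 2.4,
                        branch_areas = seq(1.5, 0.3, length.out = 8),
                        section_length_cm = tubelet_grid()$section_length) {
  if (attach_distance_cm <= 0 || section_length_cm <= 0 ||
      any(branch_areas <= 0)) {
    vt_stop("side_branch dimensions must be positive", "vt_invalid_parameter")
  }
  structure(
    list(attach_distance = attach_distance_cm,
         branch_areas = as.numeric(branch_areas),
         branch_section_length = section_length_cm),
    class = "side_branch"
  )
}

# Main-tract section index whose lip-side edge is nearest the attachment
# point; the branch shunts the junction at that edge.
branch_attach_index <- function(branch, grid) {
  i <- which.min(abs(grid$distances - branch$attach_distance))
  if (i >= grid$n_sections) {
    vt_stop("side branch must attach strictly inside the tract",
            "vt_invalid_parameter")
  }
  i
}

#' Read and write delimited area-function tables
#'
#' Area functions are exchanged as whitespace-delimited text with a header
#' comment line `# index distance_cm area_cm2` and one row per tubelet,
#' 1-based and glottis first. The reader validates monotone distances,
#' non-negative areas, and (optionally) the declared section count; the
#' round trip is lossless to 1e-9.
#'
#' @param path File path.
#' @param af An `area_function`.
#' @param grid Optional [tubelet_grid()] the table must match; if `NULL`,
#'   a grid is reconstructed from the distance column.
#' @return `read_area_table()` returns an `area_function`;
#'   `write_area_table()` returns `path` invisibly.
#' @export
read_area_table <- function(path, grid = NULL) {
  if (!file.exists(path)) {
    vt_stop(paste0("area table not found: ", path), "vt_io_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) vt_stop("area table has no data rows", "vt_format_error")
  parsed <- lapply(rows, function(ln) {
    parts <- strsplit(trimws(lines[ln]), "[[:space:],;]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3 || any(is.na(vals))) {
      vt_stop(sprintf("malformed area-table row at line %d: '%s'", ln, lines[ln]),
              "vt_format_error")
    }
    if (vals[3] < 0) {
      vt_stop(sprintf("negative area at line %d: '%s'", ln, lines[ln]),
              "vt_format_error")
    }
    vals
  })
  tab <- do.call(rbind, parsed)
  if (any(order(tab[, 1]) != seq_len(nrow(tab))) || any(diff(tab[, 2]) <= 0)) {
    vt_stop("area-table indices/distances must be strictly increasing",
            "vt_format_error")
  }
  if (is.null(grid)) {
    L <- tab[2, 2] - tab[1, 2]
    if (nrow(tab) == 1) L <- tab[1, 2]
    grid <- tubelet_grid(n_sections = nrow(tab),
                         sampling_rate = .vt_const$sound_speed / (2 * L))
  } else if (nrow(tab) != grid$n_sections) {
    vt_stop(sprintf("area table has %d rows but grid declares %d sections",
                    nrow(tab), grid$n_sections), "vt_format_error")
  }
  area_function(tab[, 3], grid)
}

#' @rdname read_area_table
#' @export
write_area_table <- function(af, path) {
  stopifnot(inherits(af, "area_function"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# index distance_cm area_cm2", con)
  writeLines(sprintf("%d\t%.9f\t%.9f", seq_len(af$grid$n_sections),
                     af$grid$distances, af$areas), con)
  invisible(path)
}
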