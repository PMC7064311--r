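#' Per-section kinetic and potential acoustic energies
#'
#' For a mode with per-section pressure `p(i)` and volume velocity `u(i)`,
#' the standard per-tubelet acoustic energies are
#' `K_e(i) = rho L / (2 A(i)) |u(i)|^2` (kinetic) and
#' `P_e(i) = A(i) L / (2 rho c^2) |p(i)|^2` (potential). Their normalized
#' difference is the acoustic sensitivity of the resonance to a fractional
#' area change in section `i`.
#'
#' @param af An [area_function()] with strictly positive areas.
#' @param p,u Complex (or numeric) per-section pressure and flow vectors.
#' @param rho Air density, g/cm^3.
#' @param sound_speed Sound speed, cm/s.
#' @return A list with numeric vectors `kinetic` and `potential` (erg).
#' @export
acoustic_energies <- function(af, p, u, rho = .vt_const$air_density,
                              sound_speed = NULL) {
  check_positive_areas(af)
  n <- af$grid$n_sections
  if (length(p) != n || length(u) != n) {
    vt_stop("p and u must have one value per tubelet", "vt_invalid_parameter")
  }
  c0 <- if (is.null(sound_speed)) af$grid$sound_speed else sound_speed
  L <- af$grid$section_length
  list(
    kinetic = rho * L / (2 * af$areas) * Mod(u)^2,
    potential = af$areas * L / (2 * rho * c0^2) * Mod(p)^2
  )
}

#' Acoustic sensitivity functions of the first three resonances
#'
#' For each resonance `j`, the sensitivity function is
#' `S_j(i) = (K_e_j(i) - P_e_j(i)) / sum_i (K_e_j(i) + P_e_j(i))`:
#' a positive value means a local area increase at section `i` raises the
#' resonance frequency, a negative value lowers it, and `|S_j(i)| <= 1` by
#' construction. The modal pressures and flows come from the
#' transmission-line model; because the energies are quadratic, the result
#' is invariant to the drive amplitude.
#'
#' @param af An [area_function()] with strictly positive areas.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @param resonances Optional precomputed `resonance_set`; found from the
#'   frequency response when `NULL`.
#' @param f_grid Frequency grid for resonance finding.
#' @return An object of class `sensitivity_functions`: list with `S`
#'   (`n_sections` x 3 matrix), `f_R` (the source resonances), and `af`.
#'   [adjust_sensitivity()] adds the balanced/normalized `Z`.
#' @examples
#' tube <- area_function(rep(3, 44))
#' sf <- sensitivity_functions(tube, losses = loss_config(lossless = TRUE))
#' sf$S[44, 1] > 0  # lip expansion raises the first resonance
#' @export
sensitivity_functions <- function(af, branch = NULL, losses = loss_config(),
                                  resonances = NULL,
                                  f_grid = seq(50, 5000, by = 10)) {
  if (is.null(resonances)) {
    fr <- frequency_response(af, branch, losses, f_grid)
    resonances <- find_resonances(fr, n = 3)
  }
  md <- modal_distributions(af, branch, losses, resonances$f_R)
  S <- vapply(seq_along(resonances$f_R), function(j) {
    en <- acoustic_energies(af, md$pressures[, j], md$flows[, j],
                            rho = if (losses$lossless) .vt_const$air_density
                                  else losses$air_density)
    tot <- sum(en$kinetic + en$potential)
    if (tot <= 0) vt_stop("zero total modal energy", "vt_degenerate_tract")
    (en$kinetic - en$potential) / tot
  }, numeric(af$grid$n_sections))
  structure(list(S = S, f_R = resonances$f_R, af = af, Z = NULL),
            class = "sensitivity_functions")
}

#' @export
print.sensitivity_functions <- function(x, ...) {
  cat(sprintf("<sensitivity_functions> %d sections x %d resonances (f_R: %s Hz)%s\n",
              nrow(x$S), ncol(x$S),
              paste(sprintf("%.0f", x$f_R), collapse = ", "),
              if (is.null(x$Z)) "" else ", adjusted"))
  invisible(x)
}

#' @export
tidy.sensitivity_functions <- function(x, ...) {
  out <- tibble::tibble(
    section = rep(seq_len(nrow(x$S)), ncol(x$S)),
    distance_cm = rep(x$af$grid$distances, ncol(x$S)),
    resonance = rep(seq_len(ncol(x$S)), each = nrow(x$S)),
    S = as.vector(x$S)
  )
  if (!is.null(x$Z)) out$Z <- as.vector(x$Z)
  out
}

#' First-order resonance shifts predicted from sensitivity functions
#'
#' Applies the perturbation relation
#' `delta_f_Rj / f_Rj = sum_i S_j(i) * delta_A(i) / A(i)`.
#'
#' @param sf A [sensitivity_functions()] object.
#' @param rel_area_change Per-section relative area change
#'   `delta_A(i)/A(i)`.
#' @return Numeric vector of relative frequency shifts, one per resonance.
#' @export
predict_resonance_shift <- function(sf, rel_area_change) {
  if (length(rel_area_change) != nrow(sf$S)) {
    vt_stop("perturbation vector must align with the tract", "vt_invalid_parameter")
  }
  as.numeric(crossprod(sf$S, rel_area_change))
}

# Zero-phase (forward-backward) second-order Butterworth smoother along the
# section axis, with odd-reflection padding at both ends to suppress the
# startup transient on short vectors.
lowpass_zero_phase <- function(x, cutoff = 0.1, pad = 9) {
  bf <- signal::butter(2, cutoff)
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Balance and normalize a sensitivity function
#'
#' Balances the magnitude of a sensitivity function along the tract so no
#' region dominates the deformation, then normalizes to unit peak
#' magnitude. The steps: store the polarity `Q(i)` (+1 where `S_j(i) >= 0`,
#' else -1); low-pass filter `|S_j(i)|` (second-order Butterworth,
#' normalized cutoff 0.1 of the spatial Nyquist, applied zero-phase) into
#' `R(i)`; form the trend `R_o(i) = R(i) + max(|S_j(i)| - R(i))`; detrend
#' as `R_a(i) = (|S_j(i)| / R_o(i)) * Q(i)`; and normalize
#' `Z_j(i) = R_a(i) / max |R_a(i)|`. The result satisfies
#' `max |Z_j| = 1` and has the polarity of `S_j` wherever `S_j != 0`.
#'
#' @param S_j A per-section sensitivity vector, or a
#'   [sensitivity_functions()] object (then every column is adjusted and
#'   the result is the object with `Z` filled in).
#' @param cutoff Normalized low-pass cutoff (fraction of spatial Nyquist).
#' @return A numeric `Z_j` vector, or the updated object.
#' @export
adjust_sensitivity <- function(S_j, cutoff = 0.1) {
  if (inherits(S_j, "sensitivity_functions")) {
    S_j$Z <- apply(S_j$S, 2, adjust_sensitivity, cutoff = cutoff)
    return(S_j)
  }
  if (!all(is.finite(S_j))) vt_stop("S_j must be finite", "vt_invalid_parameter")
  if (all(S_j == 0)) vt_stop("all-zero sensitivity function", "vt_degenerate_pattern")
  Q <- ifelse(S_j >= 0, 1, -1)
  absS <- abs(S_j)
  R <- lowpass_zero_phase(absS, cutoff)
  Ro <- R + max(absS - R)
  if (any(Ro <= 0)) {
    vt_stop("non-positive trend R_o(i) during sensitivity adjustment",
            "vt_numerical_guard")
  }
  Ra <- (absS / Ro) * Q
  Ra / max(abs(Ra))
}
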