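#' Loss configuration for the frequency-domain tract model
#'
#' The transmission-line model includes the standard energy losses of tube
#' acoustics: yielding walls (a per-unit-wall-area resistance/mass/stiffness
#' shunt), viscous friction and heat conduction at the tube surface
#' (frequency-dependent series resistance and shunt conductance), and
#' acoustic radiation at the lips (piston-in-a-baffle load). Defaults are
#' drawn from standard practice for the adult vocal tract (cgs units
#' throughout). With `lossless = TRUE` every loss term is zeroed and the lip
#' end becomes an ideal open end (zero pressure), which is the configuration
#' the quarter-wave analytic checks use.
#'
#' @param wall_resistance Wall resistance per unit wall area, dyn s/cm^3.
#' @param wall_mass Wall mass per unit wall area, g/cm^2.
#' @param wall_stiffness Wall stiffness per unit wall area, dyn/cm^3.
#' @param air_density Air density, g/cm^3.
#' @param viscosity Dynamic viscosity of air, dyn s/cm^2.
#' @param heat_conduction Thermal conductivity, erg/(cm s K).
#' @param specific_heat Specific heat at constant pressure, erg/(g K).
#' @param adiabatic_index Ratio of specific heats.
#' @param radiation Logical: include the piston-in-baffle radiation load.
#' @param lossless Logical: disable all losses and the radiation load.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(wall_resistance = 1600, wall_mass = 1.5,
                        wall_stiffness = 3e5,
                        air_density = .vt_const$air_density,
                        viscosity = .vt_const$air_viscosity,
                        heat_conduction = .vt_const$heat_conduction,
                        specific_heat = .vt_const$specific_heat,
                        adiabatic_index = .vt_const$adiabatic_index,
                        radiation = TRUE, lossless = FALSE) {
  cfg <- list(wall_resistance = wall_resistance, wall_mass = wall_mass,
              wall_stiffness = wall_stiffness, air_density = air_density,
              viscosity = viscosity, heat_conduction = heat_conduction,
              specific_heat = specific_heat, adiabatic_index = adiabatic_index,
              radiation = radiation, lossless = lossless)
  if (!lossless &&
      any(unlist(cfg[1:8]) <= 0)) {
    vt_stop("loss_config physical constants must be positive", "vt_invalid_parameter")
  }
  structure(cfg, class = "loss_config")
}

# Per-section chain (ABCD) matrix entries of a lossy uniform transmission
# line, vectorized over angular frequency. Returns list(A, B, C, D) of
# complex vectors: [P_in; U_in] = [[A,B],[C,D]] [P_out; U_out].
section_chain <- function(area, length_cm, w, losses, sound_speed) {
  rho <- if (losses$lossless) .vt_const$air_density else losses$air_density
  c0 <- sound_speed
  Lse <- rho / area                 # series inertance / unit length
  Csh <- area / (rho * c0^2)        # shunt compliance / unit length
  if (losses$lossless) {
    Zs <- 1i * w * Lse
    Ys <- 1i * w * Csh
  } else {
    S <- 2 * sqrt(pi * area)        # circumference
    Rv <- (S / area^2) * sqrt(w * rho * losses$viscosity / 2)
    Gh <- S * (losses$adiabatic_index - 1) / (rho * c0^2) *
      sqrt(losses$heat_conduction * w / (2 * losses$specific_heat * rho))
    Yw <- S / (losses$wall_resistance + 1i * w * losses$wall_mass +
                 losses$wall_stiffness / (1i * w))
    Zs <- Rv + 1i * w * Lse
    Ys <- Gh + Yw + 1i * w * Csh
  }
  gam <- sqrt(Zs * Ys)
  Zc <- sqrt(Zs / Ys)
  gl <- gam * length_cm
  ch <- cosh(gl); sh <- sinh(gl)
  list(A = ch, B = Zc * sh, C = sh / Zc, D = ch)
}

# Radiation impedance at the lips: piston in an infinite baffle,
# low-frequency approximation (resistance capped at rho*c/A).
radiation_impedance <- function(area, w, losses, sound_speed) {
  if (losses$lossless || !losses$radiation) return(rep(0 + 0i, length(w)))
  rho <- losses$air_density
  a <- sqrt(area / pi)
  ka <- w * a / sound_speed
  (rho * sound_speed / area) * (pmin(ka^2 / 2, 1) + 1i * 8 * ka / (3 * pi))
}

# Input admittance of the closed piriform side branch at each frequency.
branch_admittance <- function(branch, w, losses, sound_speed) {
  T11 <- rep(1 + 0i, length(w)); T12 <- rep(0 + 0i, length(w))
  T21 <- rep(0 + 0i, length(w)); T22 <- rep(1 + 0i, length(w))
  for (a in branch$branch_areas) {
    K <- section_chain(a, branch$branch_section_length, w, losses, sound_speed)
    t11 <- T11 * K$A + T12 * K$C; t12 <- T11 * K$B + T12 * K$D
    t21 <- T21 * K$A + T22 * K$C; t22 <- T21 * K$B + T22 * K$D
    T11 <- t11; T12 <- t12; T21 <- t21; T22 <- t22
  }
  T21 / T11  # closed far end: U_out = 0 => Y_in = U_in/P_in = T21/T11
}

# Cumulative chain matrix glottis -> lips, with the branch shunt inserted at
# its attachment junction. Returns list(T11..T22) over the frequency vector.
tract_chain <- function(af, branch, losses, w) {
  g <- af$grid
  n <- g$n_sections
  attach <- if (is.null(branch)) 0L else branch_attach_index(branch, g)
  Yb <- if (is.null(branch)) NULL else branch_admittance(branch, w, losses, g$sound_speed)
  T11 <- rep(1 + 0i, length(w)); T12 <- rep(0 + 0i, length(w))
  T21 <- rep(0 + 0i, length(w)); T22 <- rep(1 + 0i, length(w))
  for (i in seq_len(n)) {
    K <- section_chain(af$areas[i], g$section_length, w, losses, g$sound_speed)
    t11 <- T11 * K$A + T12 * K$C; t12 <- T11 * K$B + T12 * K$D
    t21 <- T21 * K$A + T22 * K$C; t22 <- T21 * K$B + T22 * K$D
    T11 <- t11; T12 <- t12; T21 <- t21; T22 <- t22
    if (i == attach) {
      # shunt admittance: [[1,0],[Yb,1]]
      T11 <- T11 + T12 * Yb
      T21 <- T21 + T22 * Yb
    }
  }
  list(T11 = T11, T12 = T12, T21 = T21, T22 = T22)
}

check_positive_areas <- function(af) {
  if (any(af$areas <= 0)) {
    vt_stop(paste0(
      "area function contains non-positive sections (",
      paste(which(af$areas <= 0), collapse = ", "),
      "); the frequency-domain solver needs a strictly positive tract - ",
      "use the time-domain synthesizer for occlusions, or floor the areas"),
      "vt_degenerate_tract")
  }
}

#' Frequency response of an area function
#'
#' Evaluates the transfer function from glottal volume velocity to lip
#' volume velocity of a tubelet area function with a chain-matrix
#' (two-port cascade) transmission-line model. The glottis is treated as an
#' ideal flow source (closed-end approximation), the lips are terminated by
#' the radiation load of the loss configuration, and the piriform side
#' branch, when supplied, enters as a parallel admittance at its attachment
#' junction.
#'
#' @param af An [area_function()] with strictly positive areas.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @param f_grid Frequency grid in Hz, strictly increasing, inside
#'   (0, sampling_rate/2); default 50-5000 Hz in 10 Hz steps.
#' @return An object of class `frequency_response`: a list with
#'   `frequencies`, `complex_transfer`, `magnitude_db`, and an `evaluator`
#'   closure that recomputes the complex transfer at arbitrary frequencies
#'   (used for continuous peak refinement).
#' @examples
#' tube <- area_function(rep(3, 44))
#' fr <- frequency_response(tube, losses = loss_config(lossless = TRUE))
#' find_resonances(fr)$f_R  # near 501, 1503, 2506 Hz
#' @export
frequency_response <- function(af, branch = NULL, losses = loss_config(),
                               f_grid = seq(50, 5000, by = 10)) {
  check_positive_areas(af)
  if (any(f_grid <= 0) || any(f_grid >= af$grid$sampling_rate / 2) ||
      any(diff(f_grid) <= 0)) {
    vt_stop("f_grid must be strictly increasing inside (0, Fs/2)",
            "vt_invalid_parameter")
  }
  eval_h <- function(f) {
    w <- 2 * pi * f
    Tm <- tract_chain(af, branch, losses, w)
    Zr <- radiation_impedance(af$areas[af$grid$n_sections], w, losses,
                              af$grid$sound_speed)
    1 / (Tm$T21 * Zr + Tm$T22)  # U_lips / U_glottis
  }
  H <- eval_h(f_grid)
  structure(
    list(frequencies = f_grid, complex_transfer = H,
         magnitude_db = 20 * log10(abs(H)), evaluator = eval_h),
    class = "frequency_response"
  )
}

#' @export
as_tibble.frequency_response <- function(x, ...) {
  tibble::tibble(frequency_hz = x$frequencies, magnitude_db = x$magnitude_db)
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %d points, %.0f-%.0f Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Locate vocal tract resonances in a frequency response
#'
#' Picks the `n` lowest-frequency local maxima of the magnitude response.
#' Each peak is refined by parabolic interpolation on the dB grid and, when
#' the response carries a continuous evaluator, polished by golden-section
#' maximization of the true magnitude within one grid step. Merged/tied
#' samples keep the lower-frequency maximum.
#'
#' @param fr A [frequency_response()].
#' @param n Number of resonances (default 3).
#' @return An object of class `resonance_set` with field `f_R` (Hz,
#'   strictly increasing).
#' @export
find_resonances <- function(fr, n = 3) {
  f <- fr$frequencies
  m <- fr$magnitude_db
  k <- length(m)
  int <- 2:(k - 1)
  is_peak <- m[int] > m[int - 1] & m[int] >= m[int + 1]
  idx <- int[is_peak]
  if (length(idx) < n) {
    vt_stop(sprintf(
      "found only %d magnitude peaks but %d resonances requested; use a denser or wider frequency grid",
      length(idx), n), "vt_resolution_error")
  }
  idx <- idx[seq_len(n)]
  fres <- vapply(idx, function(i) {
    y1 <- m[i - 1]; y2 <- m[i]; y3 <- m[i + 1]
    denom <- (y1 - 2 * y2 + y3)
    delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 1), -1)
    fpar <- f[i] + delta * (f[i + 1] - f[i])
    if (!is.null(fr$evaluator)) {
      lo <- f[i - 1]; hi <- f[i + 1]
      opt <- stats::optimize(function(x) abs(fr$evaluator(x)),
                             lower = lo, upper = hi, maximum = TRUE,
                             tol = 1e-4)
      opt$maximum
    } else {
      fpar
    }
  }, numeric(1))
  if (any(diff(fres) <= 0)) {
    vt_stop("refined resonances are not strictly increasing", "vt_resolution_error")
  }
  structure(list(f_R = fres), class = "resonance_set")
}

#' @export
print.resonance_set <- function(x, ...) {
  cat("<resonance_set> f_R:", paste(sprintf("%.1f", x$f_R), collapse = ", "), "Hz\n")
  invisible(x)
}

#' @export
tidy.resonance_set <- function(x, ...) {
  tibble::tibble(resonance = seq_along(x$f_R), frequency_hz = x$f_R)
}

#' Modal pressure and flow distributions at a resonance
#'
#' Evaluates the per-section acoustic pressure and volume velocity of the
#' tract driven at a resonance frequency, by back-propagating the chain
#' matrices from the lip termination toward the glottis (lip flow set to 1;
#' the normalization cancels in the sensitivity-function energy ratio).
#' Values are the average of the two section edges.
#'
#' @param af An [area_function()] with strictly positive areas.
#' @param branch A [side_branch()] or `NULL`.
#' @param losses A [loss_config()].
#' @param f_R Vector of drive frequencies in Hz (one column per frequency
#'   in the result).
#' @return A list with complex matrices `pressures` and `flows`
#'   (`n_sections` x `length(f_R)`).
#' @export
modal_distributions <- function(af, branch = NULL, losses = loss_config(), f_R) {
  check_positive_areas(af)
  if (any(f_R <= 0)) vt_stop("f_R must be positive", "vt_invalid_parameter")
  g <- af$grid
  n <- g$n_sections
  attach <- if (is.null(branch)) 0L else branch_attach_index(branch, g)
  P <- matrix(0 + 0i, n, length(f_R))
  U <- matrix(0 + 0i, n, length(f_R))
  for (j in seq_along(f_R)) {
    w <- 2 * pi * f_R[j]
    Zr <- radiation_impedance(af$areas[n], w, losses, g$sound_speed)
    u <- 1 + 0i
    p <- Zr * u
    Yb <- if (is.null(branch)) 0 + 0i else
      branch_admittance(branch, w, losses, g$sound_speed)
    for (i in n:1) {
      K <- section_chain(af$areas[i], g$section_length, w, losses, g$sound_speed)
      p_in <- K$A * p + K$B * u
      u_in <- K$C * p + K$D * u
      P[i, j] <- (p + p_in) / 2
      U[i, j] <- (u + u_in) / 2
      p <- p_in; u <- u_in
      if (i == attach + 1L && attach > 0L) {
        # crossing the branch junction (lip-side edge of section `attach`)
        u <- u + Yb * p
      }
    }
  }
  list(pressures = P, flows = U)
}
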