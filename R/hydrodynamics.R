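#' Prolate ellipsoid geometry of a solute molecule
#'
#' Semi-axes of the prolate ellipsoid approximating the molecular surface.
#' `2a` and `2b` are the lengths of the long and short axes; the axial
#' ratio is \eqn{\rho = b/a \le 1}.
#'
#' @param a semi-long axis. In metres, or in Angstrom with `unit = "angstrom"`
#'   (the default, matching how molecular dimensions are usually quoted).
#' @param b semi-short axis, same unit; must satisfy \eqn{0 < b \le a}.
#' @param unit `"angstrom"` or `"m"`.
#' @return object of class `"ellipsoid_geometry"` with fields `a`, `b`
#'   (metres) and `rho`.
#' @examples
#' ellipsoid_geometry(3.67, 2.11)  # glycine
#' @export
ellipsoid_geometry <- function(a, b, unit = c("angstrom", "m")) {
  unit <- match.arg(unit)
  scale <- if (unit == "angstrom") 1e-10 else 1
  a <- as.numeric(a)[1L] * scale
  b <- as.numeric(b)[1L] * scale
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("semi-axes must be finite and positive", call. = FALSE)
  if (b > a)
    stop("prolate geometry requires b <= a (axial ratio rho = b/a <= 1)",
         call. = FALSE)
  structure(list(a = a, b = b, rho = b / a), class = "ellipsoid_geometry")
}

#' Solvent conditions for hydrodynamic predictions
#'
#' @param temperature absolute temperature in K.
#' @param viscosity solvent shear viscosity in Pa s. Default is the
#'   literature value for pure water at 293 K, 1.002e-3 Pa s.
#' @return object of class `"solvent_conditions"`.
#' @export
solvent_conditions <- function(temperature = 293, viscosity = 1.002e-3) {
  temperature <- as.numeric(temperature)[1L]
  viscosity <- as.numeric(viscosity)[1L]
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("viscosity must be positive (Pa s)", call. = FALSE)
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "solvent_conditions")
}

#' Permittivities for the macroscopic-field correction
#'
#' The internal-field correction relating the microscopic rotational time to
#' the measured dielectric relaxation time uses the static permittivity of
#' the solution and the high-frequency limit of the process under study (for
#' the slow solute process this is the permittivity at the high-frequency
#' end of that process, not the overall \eqn{\varepsilon_\infty}).
#'
#' @param static_permittivity \eqn{\varepsilon_s \ge 1}.
#' @param high_freq_permittivity process high-frequency limit, \eqn{\ge 1}
#'   and \eqn{\le \varepsilon_s}.
#' @return object of class `"correction_context"`.
#' @export
correction_context <- function(static_permittivity, high_freq_permittivity) {
  es <- as.numeric(static_permittivity)[1L]
  ei <- as.numeric(high_freq_permittivity)[1L]
  if (!is.finite(es) || !is.finite(ei) || es < 1 || ei < 1)
    stop("permittivities must be finite and >= 1", call. = FALSE)
  if (es < ei)
    stop("static permittivity must be >= the high-frequency permittivity",
         call. = FALSE)
  structure(list(static_permittivity = es, high_freq_permittivity = ei),
            class = "correction_context")
}

#' Perrin rotational relaxation time of a prolate ellipsoid
#'
#' Stokes-Einstein-Debye rotational relaxation time extended to a prolate
#' ellipsoid with the electric dipole parallel to the long axis:
#' \deqn{\tau_{rot} = \frac{8\pi\eta a^3}{3 k_B T}\,
#'   \frac{1-\rho^4}{(2-\rho^2)\,S/\sqrt{1-\rho^2} - 1}, \quad
#'   S = \ln\frac{1+\sqrt{1-\rho^2}}{\rho},}
#' with \eqn{\rho = b/a}. As \eqn{\rho \to 1} this reduces to the Debye
#' sphere value \eqn{4\pi\eta a^3/(k_B T)}; the sphere formula is used
#' directly when \eqn{|1-\rho| < 10^{-9}} to avoid the 0/0 limit.
#'
#' @param geometry an [ellipsoid_geometry].
#' @param solvent a [solvent_conditions].
#' @return rotational relaxation time in seconds.
#' @examples
#' g <- ellipsoid_geometry(3.67, 2.11)
#' perrin_tau_rot(g, solvent_conditions()) * 1e12  # ~67.7 ps
#' @export
perrin_tau_rot <- function(geometry, solvent = solvent_conditions()) {
  stopifnot(inherits(geometry, "ellipsoid_geometry"),
            inherits(solvent, "solvent_conditions"))
  a <- geometry$a; rho <- geometry$rho
  eta <- solvent$viscosity; temp <- solvent$temperature
  if (abs(1 - rho) < 1e-9)
    return(4 * pi * eta * a^3 / (.kB * temp))
  q <- sqrt(1 - rho^2)
  S <- log((1 + q) / rho)
  (8 * pi * eta * a^3 / (3 * .kB * temp)) *
    (1 - rho^4) / ((2 - rho^2) * S / q - 1)
}

#' Macroscopic-field correction of a rotational relaxation time
#'
#' Converts the microscopic rotational time \eqn{\tau_{rot}} to the
#' dielectric relaxation time that a permittivity measurement observes:
#' \deqn{\tau_{DR} = \frac{3\varepsilon_s}{2\varepsilon_s +
#'   \varepsilon_\infty}\,\tau_{rot}.}
#' The factor lies in \[1, 1.5) and equals 1 when
#' \eqn{\varepsilon_s = \varepsilon_\infty}.
#'
#' @param tau_rot rotational relaxation time in seconds, > 0.
#' @param context a [correction_context].
#' @return corrected dielectric relaxation time in seconds.
#' @export
macroscopic_correction <- function(tau_rot, context) {
  stopifnot(inherits(context, "correction_context"))
  if (!is.finite(tau_rot) || tau_rot <= 0)
    stop("tau_rot must be positive", call. = FALSE)
  tau_rot * correction_factor(context)
}

#' @rdname macroscopic_correction
#' @export
correction_factor <- function(context) {
  stopifnot(inherits(context, "correction_context"))
  es <- context$static_permittivity
  3 * es / (2 * es + context$high_freq_permittivity)
}

#' Predict the observable dielectric relaxation time of a solute
#'
#' Composition of [perrin_tau_rot()] and [macroscopic_correction()]: the
#' relaxation time expected for the slow (solute rotational-diffusion)
#' process of a dielectric spectrum, given the solute's ellipsoid geometry,
#' the solvent viscosity and temperature, and the permittivities entering
#' the internal-field correction. The bare molecular geometry is used; no
#' hydration shell is added.
#'
#' @inheritParams perrin_tau_rot
#' @inheritParams macroscopic_correction
#' @return predicted relaxation time in seconds (use `* 1e12` for ps).
#' @examples
#' predict_tau_a(ellipsoid_geometry(3.67, 2.11), solvent_conditions(),
#'               correction_context(120, 91.3)) * 1e12  # ~74 ps
#' @export
predict_tau_a <- function(geometry, solvent = solvent_conditions(),
                          context) {
  macroscopic_correction(perrin_tau_rot(geometry, solvent), context)
}

#' Local-to-solvent viscosity ratio from relaxation times
#'
#' Under the Stokes-Einstein-Debye law the rotational time is linear in the
#' viscosity felt by the rotating molecule, so the ratio of an observed
#' solute relaxation time to the one predicted with the pure-solvent
#' viscosity estimates the local viscosity in solvent units. A ratio near 1
#' in a macroscopically viscous solution indicates that the solute probes
#' bulk-water-like friction despite the macroscopic network.
#'
#' @param tau_observed fitted relaxation time of the solute process, s.
#' @param tau_predicted [predict_tau_a()] value for the same solute, s.
#' @return dimensionless ratio \eqn{\eta_{local}/\eta_{solvent}}.
#' @export
local_viscosity_ratio <- function(tau_observed, tau_predicted) {
  if (!is.finite(tau_observed) || tau_observed <= 0 ||
      !is.finite(tau_predicted) || tau_predicted <= 0)
    stop("relaxation times must be positive", call. = FALSE)
  tau_observed / tau_predicted
}
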