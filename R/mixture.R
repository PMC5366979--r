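#' Rigid-rod macromolecule description
#'
#' Dimensions and composition of a rod-like macromolecule in solution.
#' Defaults describe atelocollagen: a 1.5 nm diameter, 300 nm long triple
#' helix of molar mass 300 kg/mol with three chains of ~1000 amino acid
#' residues each.
#'
#' @param diameter rod diameter in m.
#' @param length rod length in m.
#' @param molar_mass molar mass in kg/mol.
#' @param residues_per_molecule number of amino acid residues per molecule.
#' @return object of class `"rod_molecule"`.
#' @export
rod_molecule <- function(diameter = 1.5e-9, length = 300e-9,
                         molar_mass = 300, residues_per_molecule = 3000) {
  vals <- c(diameter, length, molar_mass, residues_per_molecule)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rod parameters must be finite and positive", call. = FALSE)
  structure(list(diameter = diameter, length = length,
                 molar_mass = molar_mass,
                 residues_per_molecule = residues_per_molecule),
            class = "rod_molecule")
}

#' @rdname rod_molecule
#' @param rod a `rod_molecule`.
#' @return `rod_volume`: the cylinder volume \eqn{\pi (d/2)^2 L} in m^3.
#' @export
rod_volume <- function(rod) {
  stopifnot(inherits(rod, "rod_molecule"))
  pi * (rod$diameter / 2)^2 * rod$length
}

#' Solution composition by weight
#'
#' @param collagen_wt_percent solute (rod macromolecule) concentration in
#'   weight percent, in \[0, 100).
#' @param solution_density solution mass density in kg/m^3 (default 1000,
#'   appropriate for dilute aqueous solutions).
#' @param water_molar_mass molar mass of water in kg/mol.
#' @return object of class `"solution_composition"` with the weight
#'   fraction stored as a dimensionless number.
#' @export
solution_composition <- function(collagen_wt_percent,
                                 solution_density = 1000,
                                 water_molar_mass = 0.018015) {
  wt <- as.numeric(collagen_wt_percent)[1L] / 100
  if (!is.finite(wt) || wt < 0 || wt >= 1)
    stop("collagen_wt_percent must lie in [0, 100)", call. = FALSE)
  structure(list(collagen_wt_fraction = wt,
                 solution_density = solution_density,
                 water_molar_mass = water_molar_mass),
            class = "solution_composition")
}

#' Volume fraction of rod solute per weight percent
#'
#' The solute volume fraction contributed by each weight percent of a rod
#' macromolecule: \eqn{\phi/\mathrm{wt\%} = 0.01\,\rho_{sol}/M \cdot N_A
#' \cdot \pi r^2 L}. For collagen defaults this is 0.0106, i.e. 0.01 to one
#' significant figure — each wt% of collagen excludes about 1% of the
#' solution volume from the water phase.
#'
#' @param rod a [rod_molecule].
#' @param density solution density in kg/m^3.
#' @param report if `TRUE`, round to one significant figure (the precision
#'   at which such order-of-magnitude estimates are usually quoted).
#' @return dimensionless volume fraction per wt%.
#' @export
volume_fraction_per_wt <- function(rod = rod_molecule(), density = 1000,
                                   report = FALSE) {
  stopifnot(inherits(rod, "rod_molecule"))
  phi <- 0.01 * density / rod$molar_mass * .NA * rod_volume(rod)
  if (report) signif(phi, 1) else phi
}

#' Dielectric-constant decrement from solute volume exclusion
#'
#' Ideal volume-exclusion mixing estimate of the drop of the solution's
#' dielectric constant below that of pure water:
#' \eqn{\Delta\varepsilon = \mathrm{wt\%} \cdot (\phi/\mathrm{wt\%}) \cdot
#' \varepsilon_{water}}. At 4 wt% collagen with \eqn{\phi/\mathrm{wt\%}} =
#' 0.01 and \eqn{\varepsilon_{water}} = 80.2 the decrement is 3.2 — small
#' enough to escape a measurement with a few-percent accuracy.
#'
#' @param wt_percent solute concentration in wt%.
#' @param phi_per_wt volume fraction per wt%
#'   (see [volume_fraction_per_wt()]).
#' @param eps_solvent dielectric constant of the pure solvent; default 80.2,
#'   the literature value for water at 293 K.
#' @return dimensionless decrement of the dielectric constant.
#' @export
dielectric_decrement <- function(wt_percent, phi_per_wt = 0.01,
                                 eps_solvent = 80.2) {
  if (any(c(wt_percent, phi_per_wt, eps_solvent) < 0))
    stop("inputs must be non-negative", call. = FALSE)
  wt_percent * phi_per_wt * eps_solvent
}

#' Mole fraction of bound water
#'
#' Fraction of all water molecules sitting in the first hydration layer of
#' the rod macromolecule, assuming a fixed number of bound waters per amino
#' acid residue: per unit solution mass, bound waters =
#' waters/residue x residues/molecule x moles of rod; total water comes
#' from the non-rod mass. For collagen at 4 wt% with 3000 residues and 2
#' waters per residue this is 1.5% — an upper-end estimate, since reports
#' put the count at one to a few waters per residue.
#'
#' @param composition a [solution_composition].
#' @param rod a [rod_molecule].
#' @param waters_per_residue bound water molecules per residue, \eqn{\ge 0}.
#' @return dimensionless mole fraction (0.015 means 1.5%).
#' @export
bound_water_mole_fraction <- function(composition, rod = rod_molecule(),
                                      waters_per_residue = 2) {
  stopifnot(inherits(composition, "solution_composition"),
            inherits(rod, "rod_molecule"))
  if (waters_per_residue < 0)
    stop("waters_per_residue must be >= 0", call. = FALSE)
  wt <- composition$collagen_wt_fraction
  if (wt >= 1 || (1 - wt) <= 0)
    stop("no water phase: weight fraction must be < 1", call. = FALSE)
  n_rod <- wt / rod$molar_mass                  # mol per kg solution
  n_water <- (1 - wt) / composition$water_molar_mass
  waters_per_residue * rod$residues_per_molecule * n_rod / n_water
}

#' Number of rods in a cube of solution
#'
#' Rod number density times the cube volume:
#' \eqn{N = (w\rho_{sol}/M)\,N_A \cdot s^3}. A cube with side equal to the
#' collagen length (300 nm) at 4 wt% holds about 2000 rods, supporting the
#' picture of a dense entangled rod network that raises the macroscopic
#' viscosity while leaving most water free.
#'
#' @param composition a [solution_composition].
#' @param rod a [rod_molecule].
#' @param cube_side cube edge length in m (default 300 nm).
#' @param report if `TRUE`, round to one significant figure.
#' @return expected number of rods (real-valued).
#' @export
rods_in_cube <- function(composition, rod = rod_molecule(),
                         cube_side = 300e-9, report = FALSE) {
  stopifnot(inherits(composition, "solution_composition"),
            inherits(rod, "rod_molecule"))
  if (cube_side <= 0)
    stop("cube_side must be positive", call. = FALSE)
  number_density <- composition$collagen_wt_fraction *
    composition$solution_density / rod$molar_mass * .NA
  n <- number_density * cube_side^3
  if (report) signif(n, 1) else n
}

#' All mixture estimates for a rod-macromolecule solution
#'
#' Convenience wrapper returning the four order-of-magnitude estimators in
#' one list, each as an exact value and a one-significant-figure report
#' value.
#'
#' @inheritParams bound_water_mole_fraction
#' @param eps_solvent solvent dielectric constant for the decrement.
#' @param cube_side cube edge for the rod count, m.
#' @return named list with components `volume_fraction_per_wt`,
#'   `dielectric_decrement`, `bound_water_percent`, `rods_in_cube`, each a
#'   list with `exact` and `reported`.
#' @export
mixture_estimates <- function(composition, rod = rod_molecule(),
                              waters_per_residue = 2, eps_solvent = 80.2,
                              cube_side = 300e-9) {
  phi <- volume_fraction_per_wt(rod, composition$solution_density)
  wt_pct <- composition$collagen_wt_fraction * 100
  # the decrement chain uses the one-significant-figure volume fraction,
  # the precision at which such estimates are quoted
  dec <- dielectric_decrement(wt_pct, signif(phi, 1), eps_solvent)
  bw <- bound_water_mole_fraction(composition, rod, waters_per_residue)
  rods <- rods_in_cube(composition, rod, cube_side)
  list(
    volume_fraction_per_wt = list(exact = phi, reported = signif(phi, 1)),
    dielectric_decrement = list(exact = dec, reported = signif(dec, 2)),
    bound_water_percent = list(exact = 100 * bw,
                               reported = signif(100 * bw, 2)),
    rods_in_cube = list(exact = rods, reported = signif(rods, 1)))
}
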