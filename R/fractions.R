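# Physical constants used by the geometry helpers.
.avogadro <- 6.02214076e23   # mol^-1
.speed_of_light_cm_s <- 2.99792458e10  # cm/s

#' Protein volume fraction from mass concentration
#'
#' \eqn{f = c / (1000 \rho)} with the concentration `c` in mg/mL and the
#' protein mass density `rho` in g/cm^3.  This is the plain
#' concentration-over-density convention, not a partial-specific-volume
#' treatment.
#'
#' @param c_mg_per_ml protein mass concentration, mg/mL.
#' @param rho_g_per_cm3 protein mass density, g/cm^3 (BSA ~ 1.41).
#' @return dimensionless volume fraction in (0, 1).
#' @examples
#' protein_volume_fraction(334, 1.41)  # 0.237 for concentrated BSA
#' protein_volume_fraction(50, 1.41)   # 0.0355 for dilute BSA
#' @export
protein_volume_fraction <- function(c_mg_per_ml, rho_g_per_cm3 = 1.41) {
  stopifnot(is.numeric(c_mg_per_ml), is.numeric(rho_g_per_cm3))
  if (any(c_mg_per_ml <= 0) || any(rho_g_per_cm3 <= 0))
    stop("concentration and density must be positive", call. = FALSE)
  f <- c_mg_per_ml / (1000 * rho_g_per_cm3)
  if (any(f >= 1))
    stop("concentration >= 1000 * density is non-physical (volume fraction >= 1)",
         call. = FALSE)
  f
}

#' Hydration-shell volume fraction in the dilute solution
#'
#' In the concentrated solution essentially all water belongs to dynamic
#' hydration shells, so the shell fraction there is \eqn{1 - f_p}.  Scaling
#' by the concentration ratio (shells track protein copies) gives the shell
#' fraction of the dilute solution:
#' \deqn{f_{sh} = (1 - f_p)\, c_{dilute} / c_{conc}.}
#' Assumes non-overlapping shells at the dilute concentration; a warning is
#' emitted by [phase_fractions()] when the combined protein + shell fraction
#' exceeds 0.5 and that assumption degrades.
#'
#' @param f_p protein volume fraction in the concentrated solution, in (0,1).
#' @param c_dilute,c_conc concentrations in mg/mL with
#'   `c_dilute <= c_conc`.
#' @return shell volume fraction in (0, 1).
#' @examples
#' shell_volume_fraction(0.237, 50, 334)  # 0.114
#' @export
shell_volume_fraction <- function(f_p, c_dilute, c_conc) {
  stopifnot(is.numeric(f_p), is.numeric(c_dilute), is.numeric(c_conc))
  if (any(f_p <= 0) || any(f_p >= 1))
    stop("f_p must lie strictly between 0 and 1", call. = FALSE)
  if (any(c_dilute <= 0) || any(c_conc <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (any(c_dilute > c_conc))
    stop("c_dilute must not exceed c_conc", call. = FALSE)
  (1 - f_p) * c_dilute / c_conc
}

#' Phase-fraction triple for the two-solution experiment
#'
#' Bundles the three volume fractions the effective-medium equations need:
#' `f_p` (protein in the concentrated solution), `f` (protein in the dilute
#' solution) and `f_sh` (hydration shells in the dilute solution).  Either
#' give the fractions directly or let them be computed from concentrations
#' and density.
#'
#' @param f_p,f,f_sh fractions given directly (all three or none).
#' @param c_conc,c_dilute concentrations in mg/mL (used when fractions are
#'   not given directly).
#' @param density protein mass density in g/cm^3.
#' @return object of class `"phase_fractions"`: a list with elements `f_p`,
#'   `f`, `f_sh`.
#' @examples
#' phase_fractions(c_conc = 334, c_dilute = 50, density = 1.41)
#' @export
phase_fractions <- function(f_p = NULL, f = NULL, f_sh = NULL,
                            c_conc = NULL, c_dilute = NULL, density = 1.41) {
  direct <- !is.null(f_p) || !is.null(f) || !is.null(f_sh)
  if (direct) {
    if (is.null(f_p) || is.null(f) || is.null(f_sh))
      stop("give all three of f_p, f, f_sh, or none", call. = FALSE)
  } else {
    if (is.null(c_conc) || is.null(c_dilute))
      stop("either the fraction triple or both concentrations are required",
           call. = FALSE)
    f_p <- protein_volume_fraction(c_conc, density)
    f <- protein_volume_fraction(c_dilute, density)
    f_sh <- shell_volume_fraction(f_p, c_dilute, c_conc)
  }
  if (!(f_p > 0 && f_p < 1)) stop("need 0 < f_p < 1", call. = FALSE)
  if (!(f > 0 && f < f_p)) stop("need 0 < f < f_p", call. = FALSE)
  if (!(f_sh > 0)) stop("need f_sh > 0", call. = FALSE)
  if (!(f + f_sh < 1)) stop("need f + f_sh < 1", call. = FALSE)
  if (f + f_sh > 0.5)
    warning("f + f_sh > 0.5: hydration shells likely overlap; ",
            "the shell-scaling assumption is degraded", call. = FALSE)
  structure(list(f_p = f_p, f = f, f_sh = f_sh), class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, digits = 3, ...) {
  cat(sprintf("<phase_fractions> f_p = %.*g, f = %.*g, f_sh = %.*g\n",
              digits, x$f_p, digits, x$f, digits, x$f_sh))
  invisible(x)
}

#' Effective protein-layer thickness in a pressed pellet
#'
#' \eqn{d = m / (\rho S)}: the thickness of the pure-protein layer a pellet
#' would contain if its protein mass were compacted at full density over the
#' pellet face.
#'
#' @param mass_mg protein mass in the pellet, mg.
#' @param area_cm2 pellet face area, cm^2.
#' @param rho_g_per_cm3 protein density, g/cm^3.
#' @return thickness in micrometres.
#' @examples
#' pellet_layer_thickness(15, 1.33, 1.41)  # 80 um
#' @export
pellet_layer_thickness <- function(mass_mg, area_cm2, rho_g_per_cm3 = 1.41) {
  stopifnot(is.numeric(mass_mg), is.numeric(area_cm2),
            is.numeric(rho_g_per_cm3))
  if (any(mass_mg <= 0) || any(area_cm2 <= 0) || any(rho_g_per_cm3 <= 0))
    stop("mass, area and density must all be positive", call. = FALSE)
  d_cm <- (mass_mg / 1000) / (rho_g_per_cm3 * area_cm2)
  d_cm * 1e4
}

#' Equivalent-sphere diameter of a protein globule
#'
#' Treats one protein molecule of molar mass MW as a sphere of density rho:
#' \eqn{V = MW/(N_A \rho)}, \eqn{d = (6V/\pi)^{1/3}}.
#'
#' @param mw_kDa molar mass in kilodaltons.
#' @param rho_g_per_cm3 protein density, g/cm^3.
#' @return diameter in nanometres.
#' @examples
#' equivalent_sphere_diameter(66.5, 1.41)  # 5.3 nm for BSA
#' @export
equivalent_sphere_diameter <- function(mw_kDa, rho_g_per_cm3 = 1.41) {
  stopifnot(is.numeric(mw_kDa), is.numeric(rho_g_per_cm3))
  if (any(mw_kDa <= 0) || any(rho_g_per_cm3 <= 0))
    stop("molecular weight and density must be positive", call. = FALSE)
  v_cm3 <- (mw_kDa * 1000) / (.avogadro * rho_g_per_cm3)  # g/mol / (1/mol * g/cm3)
  (6 * v_cm3 / pi)^(1 / 3) * 1e7   # cm -> nm
}

#' Hydration-shell to protein volume ratio
#'
#' For a spherical core of diameter `core_diameter_nm` carrying a shell of
#' thickness `shell_thickness_nm`:
#' \deqn{\frac{V_{shell}}{V_{core}} = \frac{(r+t)^3 - r^3}{r^3}, \quad r = d/2.}
#'
#' @param core_diameter_nm protein sphere diameter, nm.
#' @param shell_thickness_nm hydration-shell thickness, nm (1.5-2 nm is the
#'   dynamic-shell range seen in THz studies of globular proteins).
#' @return dimensionless volume ratio (0 when the thickness is 0).
#' @examples
#' hydration_volume_ratio(5.3, 1.5)  # ~2.8
#' hydration_volume_ratio(5.3, 2.0)  # ~4.4
#' @export
hydration_volume_ratio <- function(core_diameter_nm, shell_thickness_nm) {
  stopifnot(is.numeric(core_diameter_nm), is.numeric(shell_thickness_nm))
  if (any(core_diameter_nm <= 0))
    stop("core diameter must be positive", call. = FALSE)
  if (any(shell_thickness_nm < 0))
    stop("shell thickness must be non-negative", call. = FALSE)
  r <- core_diameter_nm / 2
  ((r + shell_thickness_nm)^3 - r^3) / r^3
}
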