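# Formula-level biomechanical derivations: buoyancy-corrected force of the
# hanging mass, per-branch tension, applied stress and instantaneous elastic
# strain, effective tissue viscosity, dry-mass / cell-number changes,
# proliferation densities, and the glass-fiber cantilever calibration.
#
# Unit discipline: masses mg, forces uN, stresses Pa, lengths mm, volumes mm^3,
# densities mg/mm^3 for tissue and g/cm^3 for weights/medium. All conversions
# happen inside these functions.

#' Buoyancy-corrected force of a submerged hanging mass
#'
#' `F = m g (1 - rho_medium / rho_object)`. For 1-2 mg stainless-steel weights
#' in aqueous medium this evaluates to 8.6-17.1 uN (9-17 uN to the nearest
#' integer), the minimal tensile force transmitted to the gut loop.
#'
#' @param mass_mg hanging mass (mg).
#' @param object_density_g_cm3 density of the weight; default stainless steel.
#' @param medium_density_g_cm3 density of the surrounding medium (PBS/DMEM).
#' @param g gravitational acceleration (m/s^2).
#' @return force in microNewton.
#' @export
buoyant_force <- function(mass_mg, object_density_g_cm3 = 7.8,
                          medium_density_g_cm3 = 1.0, g = 9.81) {
  stopifnot(all(mass_mg >= 0), object_density_g_cm3 > 0,
            medium_density_g_cm3 > 0)
  if (object_density_g_cm3 <= medium_density_g_cm3) {
    stop("object density must exceed medium density (the weight would float)")
  }
  # mg * m/s^2 = 1e-6 kg m/s^2 = uN
  mass_mg * g * (1 - medium_density_g_cm3 / object_density_g_cm3)
}

#' Tension borne by one gut branch
#'
#' The mesentery + omphalomesenteric artery absorb a fraction of the total
#' transmitted force; the remainder is shared by the gut branches (jejunum and
#' ileum arms of the hairpin loop).
#'
#' @param force_total_uN total transmitted force (uN).
#' @param absorbed_fraction fraction absorbed by mesentery + OMA, in `[0, 1)`.
#' @param branch_count number of gut branches sharing the rest.
#' @return per-branch force (uN).
#' @export
branch_tension <- function(force_total_uN, absorbed_fraction = 0.25,
                           branch_count = 2L) {
  stopifnot(all(force_total_uN >= 0), absorbed_fraction >= 0,
            absorbed_fraction < 1, branch_count >= 1)
  force_total_uN * (1 - absorbed_fraction) / branch_count
}

#' Longitudinal stress applied by a hanging force
#'
#' `sigma = F / S` with `S = pi d^2 / 4` the initial cross-section of the gut.
#'
#' @param force_uN applied force (uN).
#' @param diameter_mm initial gut diameter (mm).
#' @return stress in Pa (uN/mm^2 = Pa).
#' @export
applied_stress <- function(force_uN, diameter_mm) {
  stopifnot(all(force_uN >= 0))
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  force_uN / (pi * diameter_mm^2 / 4)
}

#' Instantaneous elastic strain under applied stress
#'
#' `epsilon = sigma / E` with an effective tissue modulus; the default 1 kPa is
#' the unique value consistent with both reported stress/strain pairs
#' (70-100 Pa <-> 7-10% and 100-140 Pa <-> 10-14%).
#'
#' @param stress_Pa applied stress (Pa).
#' @param modulus_Pa effective elastic modulus (Pa).
#' @return strain as a fraction.
#' @export
elastic_strain <- function(stress_Pa, modulus_Pa = 1000) {
  stopifnot(modulus_Pa > 0)
  stress_Pa / modulus_Pa
}

#' Effective tissue viscosity from irreversible elongation
#'
#' `eta = sigma * dT / (dl/l)`: the ratio of applied stress to irreversible
#' strain rate over the culture period.
#'
#' @param stress_Pa applied stress (Pa).
#' @param duration_h culture duration (hours).
#' @param strain_irreversible irreversible relative elongation `dl/l` (> 0).
#' @return effective viscosity in Pa.s.
#' @export
effective_viscosity <- function(stress_Pa, duration_h, strain_irreversible) {
  stopifnot(all(stress_Pa >= 0), all(duration_h > 0))
  if (any(strain_irreversible <= 0)) {
    stop("no irreversible elongation: strain must be > 0")
  }
  stress_Pa * duration_h * 3600 / strain_irreversible
}

#' Relative change between two measurements
#'
#' @param before,after numeric values; `before` must be nonzero.
#' @return `(after - before) / before`.
#' @export
relative_change <- function(before, after) {
  if (any(before == 0)) stop("relative change undefined for before = 0")
  (after - before) / before
}

#' Dry-mass change induced by culture
#'
#' `(m_f - rho_ref V_i) / (rho_ref V_i)`: the initial dry mass is deduced from
#' the initial volume via the reference dry density of native E8 guts.
#'
#' @param m_f_mg measured final dry mass (mg).
#' @param V_i_mm3 initial gut volume (mm^3).
#' @param rho_ref_mg_mm3 reference dry density (mg/mm^3).
#' @return fractional dry-mass change.
#' @export
dry_mass_change <- function(m_f_mg, V_i_mm3, rho_ref_mg_mm3 = 0.100) {
  stopifnot(all(V_i_mm3 > 0), rho_ref_mg_mm3 > 0)
  relative_change(rho_ref_mg_mm3 * V_i_mm3, m_f_mg)
}

#' Cell-number change induced by culture
#'
#' `(N_f - n_ref V_i) / (n_ref V_i)`: the initial cell number is deduced from
#' the initial volume via the reference cell density of native E8 guts.
#'
#' @param N_f measured final total cell count.
#' @param V_i_mm3 initial gut volume (mm^3).
#' @param n_ref_cells_mm3 reference cell density (cells/mm^3).
#' @return fractional cell-number change.
#' @export
cell_number_change <- function(N_f, V_i_mm3, n_ref_cells_mm3 = 4.15e5) {
  stopifnot(all(V_i_mm3 > 0), n_ref_cells_mm3 > 0)
  relative_change(n_ref_cells_mm3 * V_i_mm3, N_f)
}

#' Dry-mass fraction of tissue
#'
#' @param rho_mg_mm3 dry density (mg/mm^3); 0.100 mg/mm^3 means 10% dry mass,
#'   90% water.
#' @param water_density_mg_mm3 density of water (1 mg/mm^3).
#' @return dry-mass percentage.
#' @export
dry_mass_fraction <- function(rho_mg_mm3, water_density_mg_mm3 = 1.0) {
  stopifnot(all(rho_mg_mm3 >= 0), water_density_mg_mm3 > 0)
  if (any(rho_mg_mm3 >= water_density_mg_mm3)) {
    stop("dry density must be below the density of water")
  }
  100 * rho_mg_mm3 / water_density_mg_mm3
}

#' Fit the deflection-force characteristic of a cantilever fiber
#'
#' Ordinary least squares of deflection (degrees) versus force (N, computed
#' from the attached masses); the slope is the fiber sensitivity in deg/N.
#'
#' @param points data.frame with columns `mass_mg` and `deflection_deg`.
#' @param g gravitational acceleration (m/s^2).
#' @return a [cantilever_calibration()].
#' @export
fit_cantilever <- function(points, g = 9.81) {
  stopifnot(is.data.frame(points),
            all(c("mass_mg", "deflection_deg") %in% names(points)),
            nrow(points) >= 2)
  if (length(unique(points$mass_mg)) < 2) {
    stop("calibration requires at least 2 distinct masses")
  }
  force_N <- points$mass_mg * 1e-6 * g
  fit <- stats::lm(points$deflection_deg ~ force_N)
  co <- stats::coef(fit)
  ss <- suppressWarnings(summary(fit))  # noise-free data: perfect-fit warning
  r2 <- if (stats::var(points$deflection_deg) == 0) 1 else ss$r.squared
  cantilever_calibration(
    sensitivity_deg_per_N = unname(co[2]),
    intercept_deg = unname(co[1]),
    r_squared = r2,
    points = data.frame(force_N = force_N,
                        deflection_deg = points$deflection_deg),
    slope_se = ss$coefficients[2, 2])
}

#' Convert a measured fiber deflection to dry mass
#'
#' Inverse of the calibration map: `m = (deflection - intercept) /
#' (sensitivity * g)`, converted to mg.
#'
#' @param deflection_deg measured stationary deflection (degrees).
#' @param calib a [cantilever_calibration()].
#' @param g gravitational acceleration (m/s^2).
#' @return dry mass in mg.
#' @export
deflection_to_dry_mass <- function(deflection_deg, calib, g = 9.81) {
  stopifnot(inherits(calib, "cantilever_calibration"))
  if (any(deflection_deg < calib$intercept_deg - 1e-9)) {
    stop("deflection below calibration intercept")
  }
  force_N <- (deflection_deg - calib$intercept_deg) / calib$sensitivity_deg_per_N
  force_N / g * 1e6  # kg -> mg is 1e6
}

#' Proliferation density on a section
#'
#' Number of PH3-positive (mitotic) cells divided by the section area. When
#' given vectors, also returns the per-sample mean over slices.
#'
#' @param ph3_count PH3-positive cell count(s) per slice.
#' @param section_area_mm2 slice area(s) in mm^2.
#' @return list with `per_slice` (cells/mm^2) and `mean`.
#' @export
proliferation_density <- function(ph3_count, section_area_mm2) {
  stopifnot(all(ph3_count >= 0))
  if (any(section_area_mm2 <= 0)) stop("section area must be positive")
  per <- ph3_count / section_area_mm2
  list(per_slice = per, mean = mean(per))
}

#' Percentage of proliferating cells found in the epithelium
#'
#' @param count_epithelium PH3-positive cells in the epithelium.
#' @param count_total total PH3-positive cells on the section.
#' @return percentage.
#' @export
epithelial_fraction <- function(count_epithelium, count_total) {
  stopifnot(all(count_epithelium >= 0))
  if (any(count_total <= 0)) stop("total count must be positive")
  if (any(count_epithelium > count_total)) {
    stop("epithelial count cannot exceed total count")
  }
  100 * count_epithelium / count_total
}
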