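#' Stiffness parameter beta
#'
#' The pressure-independent wall stiffness index
#' \deqn{\beta = \ln(\mathrm{SBP}/\mathrm{DBP}) \,/\,
#'       [(D_{max} - D_{min})/D_{min}],}
#' the slope of the log-pressure vs fractional-distension relation.
#' Invariant under common rescaling of both pressures and of both
#' diameters.
#'
#' @param sbp_mmhg,dbp_mmhg systolic and diastolic pressure, mmHg
#'   (`sbp > dbp > 0`).
#' @param dmax_mm,dmin_mm maximum/minimum internal diameter, mm
#'   (`dmax > dmin > 0`); a [diameter_measurement] may be passed as
#'   `dmax_mm` instead.
#' @return beta (dimensionless).
#' @examples
#' stiffness_beta(120, 80, 20, 19)  # ln(1.5) * 19 ~= 7.70
#' @export
stiffness_beta <- function(sbp_mmhg, dbp_mmhg, dmax_mm, dmin_mm = NULL) {
  if (inherits(dmax_mm, "diameter_measurement")) {
    dmin_mm <- dmax_mm$dmin_mm
    dmax_mm <- dmax_mm$dmax_mm
  }
  if (!(dbp_mmhg > 0) || sbp_mmhg < dbp_mmhg) {
    stop("pressure order violated: need SBP >= DBP > 0 (got SBP ",
         sbp_mmhg, ", DBP ", dbp_mmhg, ")", call. = FALSE)
  }
  if (!(dmin_mm > 0) || dmax_mm <= dmin_mm) {
    stop("degenerate diameter strain: need Dmax > Dmin > 0 (got Dmax ",
         dmax_mm, ", Dmin ", dmin_mm, ")", call. = FALSE)
  }
  log(sbp_mmhg / dbp_mmhg) / ((dmax_mm - dmin_mm) / dmin_mm)
}

#' Percent change of aortic diameter over the cardiac cycle
#'
#' `100 * (Dmax - Dmin) / Dmin`, the fractional systolic distension of
#' the vessel expressed in percent.
#'
#' @inheritParams stiffness_beta
#' @return percent diameter change.
#' @export
diameter_change <- function(dmax_mm, dmin_mm = NULL) {
  if (inherits(dmax_mm, "diameter_measurement")) {
    dmin_mm <- dmax_mm$dmin_mm
    dmax_mm <- dmax_mm$dmax_mm
  }
  if (!(dmin_mm > 0) || dmax_mm < dmin_mm) {
    stop("need Dmax >= Dmin > 0 (got Dmax ", dmax_mm, ", Dmin ", dmin_mm,
         ")", call. = FALSE)
  }
  100 * (dmax_mm - dmin_mm) / dmin_mm
}

#' Bramwell-Hill local pulse wave velocity
#'
#' \deqn{\mathrm{PWV} = \sqrt{A_d \, \mathrm{PP} / (\rho \, \Delta A)}}
#' with `Ad` the diastolic cross-sectional area, `dA` the systolic minus
#' diastolic area difference, `PP` the local pulse pressure and `rho` the
#' blood density.  Cross-sections are taken circular, `A = pi (D/2)^2`,
#' so PWV is invariant under common rescaling of the two diameters (the
#' areas enter only as a ratio).
#'
#' @inheritParams stiffness_beta
#' @param pp_mmhg local pulse pressure, mmHg (> 0); converted internally
#'   to Pa.
#' @param rho_kg_m3 blood density, kg/m3 (default 1060).
#' @return PWV in m/s.
#' @examples
#' bramwell_hill_pwv(20, 19, pp_mmhg = 40)  # ~6.82 m/s
#' @export
bramwell_hill_pwv <- function(dmax_mm, dmin_mm = NULL, pp_mmhg,
                              rho_kg_m3 = 1060) {
  if (inherits(dmax_mm, "diameter_measurement")) {
    dmin_mm <- dmax_mm$dmin_mm
    dmax_mm <- dmax_mm$dmax_mm
  }
  if (!(dmin_mm > 0) || dmax_mm <= dmin_mm) {
    stop("degenerate area difference: need Dmax > Dmin > 0 (got Dmax ",
         dmax_mm, ", Dmin ", dmin_mm, ")", call. = FALSE)
  }
  if (!(pp_mmhg > 0)) {
    stop("pulse pressure must be > 0 (got ", pp_mmhg, ")", call. = FALSE)
  }
  d_max_m <- convert_units(dmax_mm, "mm", "m")
  d_min_m <- convert_units(dmin_mm, "mm", "m")
  ad <- pi * (d_min_m / 2)^2
  delta_a <- pi * (d_max_m / 2)^2 - ad
  pp_pa <- convert_units(pp_mmhg, "mmHg", "Pa")
  sqrt(ad * pp_pa / (rho_kg_m3 * delta_a))
}
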