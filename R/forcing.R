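#' Aerosol optical properties for the direct-forcing box expression
#'
#' @param ssa Single-scattering albedo (0, 1]; 1 = purely scattering.
#' @param mass_extinction_m2_g Mass extinction efficiency, m^2/g (default
#'   8.5, a standard dry-sulphate value).
#' @param backscatter_fraction Upscatter fraction (0, 1] (default 0.29).
#' @return Object of class `aerosol_optics`.
#' @export
aerosol_optics <- function(ssa = 0.999, mass_extinction_m2_g = 8.5,
                           backscatter_fraction = 0.29) {
  if (ssa <= 0 || ssa > 1) stop("`ssa` must be in (0, 1]", call. = FALSE)
  if (backscatter_fraction <= 0 || backscatter_fraction > 1) {
    stop("`backscatter_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (mass_extinction_m2_g <= 0) {
    stop("`mass_extinction_m2_g` must be positive", call. = FALSE)
  }
  structure(list(ssa = ssa, mass_extinction_m2_g = mass_extinction_m2_g,
                 backscatter_fraction = backscatter_fraction),
            class = "aerosol_optics")
}

#' Cloud droplet number from sulphate and sea salt
#'
#' Empirical multi-component relation
#' `D_n = a + b * C_NSS + c * C_SSLT` with a physically meaningful pristine
#' asymptote `a`. Fitting constants a = 31, b = 93.5 per ug/m^3 non-sea-salt
#' sulphate, c = 16.5 per ug/m^3 sea salt; with these constants the result
#' is read as droplets per cm^3 (only droplet-number ratios enter the cloud
#'-albedo term, so the unit choice cancels there).
#'
#' @param c_nss Non-sea-salt sulphate concentration, ug/m^3.
#' @param c_sslt Sea-salt concentration, ug/m^3.
#' @param a,b,c Fitting constants.
#' @return Droplet number concentration (vectorised), strictly positive.
#' @examples
#' droplet_number(0, 0)  # 31, the pristine asymptote
#' @export
droplet_number <- function(c_nss, c_sslt, a = 31, b = 93.5, c = 16.5) {
  if (any(c_nss < 0, na.rm = TRUE) || any(c_sslt < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (a <= 0 || b <= 0 || c <= 0) {
    stop("fitting constants must be positive", call. = FALSE)
  }
  a + b * c_nss + c * c_sslt
}

#' Cloud-albedo change from a droplet-number change (Twomey effect)
#'
#' Susceptibility form `dA = A0 (1 - A0) / 3 * ln(Dn1 / Dn0)`; at fixed
#' liquid water, more and smaller droplets brighten the cloud. The
#' perturbed albedo `A0 + dA` is clamped to \[0, 1\].
#'
#' @param a0 Unperturbed cloud albedo in (0, 1).
#' @param dn0,dn1 Droplet numbers before and after (same units, > 0).
#' @return Albedo change (vectorised).
#' @export
twomey_albedo_change <- function(a0, dn0, dn1) {
  if (any(dn0 <= 0, na.rm = TRUE) || any(dn1 <= 0, na.rm = TRUE)) {
    stop("droplet numbers must be positive", call. = FALSE)
  }
  if (any(a0 <= 0 | a0 >= 1, na.rm = TRUE)) {
    stop("`a0` must lie in (0, 1)", call. = FALSE)
  }
  da <- a0 * (1 - a0) / 3 * log(dn1 / dn0)
  clamp(a0 + da, 0, 1) - a0
}

#' First-indirect (cloud-albedo) forcing of a sulphate perturbation
#'
#' Droplet numbers are computed with and without the ship sulphate
#' perturbation, the Twomey susceptibility gives the cloud-albedo change,
#' and the flux change per cell is
#' `F = -insolation * cloud_fraction * dA * T_atm^2`. In the `detached`
#' mixing mode the in-cloud convection is assumed not to lift the sulphates
#' into the upper cloud, so only a fraction `d` of the non-sea-salt
#' sulphate is seen by the cloud before the droplet relation is applied.
#'
#' @param meteo A `meteo_fields`.
#' @param grid The `world_grid` (for area weighting).
#' @param c_nss_base Non-sea-salt sulphate without the perturbation, ug/m^3.
#' @param c_nss_pert With the perturbation.
#' @param mixing_mode `"well_mixed"` or `"detached"`.
#' @param detachment Fraction `d` of sulphate seen by the cloud in detached
#'   mode (default 0.25).
#' @param cloud_albedo Unperturbed cloud albedo (scalar or field), default
#'   0.5.
#' @param t_atm Atmospheric transmittance above the cloud, default 0.76.
#' @param params Droplet-relation constants, `list(a, b, c)`.
#' @return List with `cell_mw_m2` (field, mW/m^2) and area-weighted
#'   `global_mw_m2`. Negative = cooling.
#' @export
indirect_forcing <- function(meteo, grid, c_nss_base, c_nss_pert,
                             mixing_mode = c("well_mixed", "detached"),
                             detachment = 0.25, cloud_albedo = 0.5,
                             t_atm = 0.76,
                             params = list(a = 31, b = 93.5, c = 16.5)) {
  mixing_mode <- match.arg(mixing_mode)
  scale <- if (mixing_mode == "detached") detachment else 1
  if (detachment < 0 || detachment > 1) {
    stop("`detachment` must be in [0, 1]", call. = FALSE)
  }
  dn0 <- droplet_number(scale * c_nss_base, meteo$sea_salt,
                        params$a, params$b, params$c)
  dn1 <- droplet_number(scale * c_nss_pert, meteo$sea_salt,
                        params$a, params$b, params$c)
  da <- twomey_albedo_change(cloud_albedo, dn0, dn1)
  f <- -meteo$insolation * meteo$cloud_fraction * da * t_atm^2 * 1000  # mW
  list(cell_mw_m2 = f, global_mw_m2 = area_weighted_mean(grid, f),
       mixing_mode = mixing_mode)
}

# Clear-sky box bracket; its sign decides cooling vs warming over a
# reflective surface.
direct_bracket <- function(ssa, albedo, backscatter) {
  (1 - albedo)^2 - (2 * albedo / backscatter) * (1 / ssa - 1)
}

#' SSA at which the direct-forcing bracket changes sign
#'
#' Analytic root of the clear-sky box bracket in single-scattering albedo:
#' `omega* = 1 / (1 + backscatter (1 - R_s)^2 / (2 R_s))`. Unique in (0, 1)
#' for any surface albedo `R_s > 0`, and increasing in `R_s`: brighter
#' surfaces tip partially absorbing aerosol into a warming agent sooner.
#'
#' @param albedo Underlying surface albedo (> 0).
#' @param backscatter Upscatter fraction.
#' @return Tipping SSA.
#' @export
tipping_ssa <- function(albedo, backscatter = 0.29) {
  if (any(albedo <= 0)) stop("`albedo` must be positive for a tipping point",
                             call. = FALSE)
  1 / (1 + backscatter * (1 - albedo)^2 / (2 * albedo))
}

#' Direct radiative forcing of an aerosol optical-depth change
#'
#' Single-band clear-sky box expression (Haywood-Shine type): per cell
#' `F = -(S/4) T_atm^2 (1 - f_cloud) omega beta_bar daod *
#' [(1 - R_s)^2 - (2 R_s / beta_bar)(1/omega - 1)]` with `R_s` the
#' underlying surface albedo and `beta_bar` the upscatter fraction. Purely
#' scattering aerosol over a dark surface cools; over bright surfaces the
#' bracket changes sign at the tipping SSA (see [tipping_ssa()]).
#'
#' @param daod Aerosol optical-depth change field (>= 0 for added aerosol).
#' @param optics An `aerosol_optics`.
#' @param meteo A `meteo_fields`.
#' @param grid The `world_grid`.
#' @param s0 Solar constant, W/m^2.
#' @param t_atm Atmospheric transmittance.
#' @return List with `cell_mw_m2` and area-weighted `global_mw_m2`.
#' @export
direct_forcing <- function(daod, optics, meteo, grid, s0 = 1361,
                           t_atm = 0.76) {
  stopifnot(inherits(optics, "aerosol_optics"))
  if (optics$ssa <= 0) stop("`ssa` must be positive", call. = FALSE)
  br <- direct_bracket(optics$ssa, meteo$albedo, optics$backscatter_fraction)
  f <- -(s0 / 4) * t_atm^2 * (1 - meteo$cloud_fraction) * optics$ssa *
    optics$backscatter_fraction * daod * br * 1000  # mW/m^2
  list(cell_mw_m2 = f, global_mw_m2 = area_weighted_mean(grid, f))
}

#' Optical depth of a concentration change
#'
#' Column mass (concentration times mixing height) times the mass
#' extinction efficiency.
#'
#' @param dconc Concentration change field, ug/m^3.
#' @param meteo A `meteo_fields` (mixing height).
#' @param optics An `aerosol_optics`.
#' @return AOD change field (dimensionless).
#' @export
aod_of_concentration <- function(dconc, meteo, optics) {
  dconc * meteo$mixing_height * 1e-6 * optics$mass_extinction_m2_g
}

#' Direct forcing across a list of single-scattering albedos
#'
#' @param daod AOD change field.
#' @param ssa_values Vector of SSA values in (0, 1].
#' @param meteo A `meteo_fields`.
#' @param grid The `world_grid`.
#' @param ... Passed to [aerosol_optics()] / [direct_forcing()].
#' @return data.frame with columns `ssa` and `global_mw_m2`; over
#'   reflective scenes the forcing moves toward warming as SSA decreases.
#' @export
ssa_sensitivity <- function(daod, ssa_values, meteo, grid, ...) {
  out <- vapply(ssa_values, function(w) {
    direct_forcing(daod, aerosol_optics(ssa = w), meteo, grid, ...)$global_mw_m2
  }, 0)
  data.frame(ssa = ssa_values, global_mw_m2 = out)
}

#' Scenario comparison table of forcing components
#'
#' @param f_bau,f_action Named lists with elements `direct` and `indirect`
#'   (global mW/m^2 for each scenario).
#' @return data.frame with rows direct, indirect, net; columns `bau`,
#'   `action`, `net_change` (= action - bau; positive = reduced cooling) and
#'   `percent_change` relative to the BAU magnitude.
#' @export
forcing_report <- function(f_bau, f_action) {
  for (f in list(f_bau, f_action)) {
    if (!all(c("direct", "indirect") %in% names(f))) {
      stop("forcing inputs need `direct` and `indirect` components",
           call. = FALSE)
    }
  }
  bau <- c(direct = f_bau$direct, indirect = f_bau$indirect)
  act <- c(direct = f_action$direct, indirect = f_action$indirect)
  bau <- c(bau, net = sum(bau))
  act <- c(act, net = sum(act))
  delta <- act - bau
  pct <- ifelse(bau != 0, 100 * delta / abs(bau), NA_real_)
  data.frame(component = c("direct", "indirect", "net"),
             bau = unname(bau), action = unname(act),
             net_change = unname(delta), percent_change = unname(pct))
}
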