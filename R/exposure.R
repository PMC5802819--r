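#' Atmospheric species lifetimes
#'
#' E-folding lifetimes against all sinks, used by the steady-state exposure
#' surrogate. Defaults: 1.5 days for SO2 (whose primary sink is oxidation to
#' sulphate), 2.8 days for sulphate (removed by dry and wet deposition),
#' 2.0 days for nitrate and 2.5 days for primary particles.
#'
#' @param tau_so2,tau_so4,tau_no3,tau_primary Lifetimes in days, all > 0.
#' @return Object of class `species_lifetimes`.
#' @export
species_lifetimes <- function(tau_so2 = 1.5, tau_so4 = 2.8, tau_no3 = 2.0,
                              tau_primary = 2.5) {
  vals <- c(tau_so2 = tau_so2, tau_so4 = tau_so4, tau_no3 = tau_no3,
            tau_primary = tau_primary)
  if (any(vals <= 0)) stop("all lifetimes must be positive", call. = FALSE)
  structure(as.list(vals), class = "species_lifetimes")
}

# Redistribute a per-cell column mass with an isotropic exponential kernel,
# e-folding length per source cell; normalised over the (closed) domain so
# total mass is conserved exactly.
spread_mass <- function(grid, mass, ell_m) {
  src <- which(mass > 0)
  if (length(src) == 0) return(mass * 0)
  r_earth <- 6371000
  coslat <- cos(mean(grid$lat) * pi / 180)
  x <- rep(grid$lon, each = grid$n_lat) * pi / 180 * r_earth * coslat
  y <- rep(grid$lat, times = grid$n_lon) * pi / 180 * r_earth
  out <- mass * 0
  ell <- rep_len(as.vector(ell_m), length(mass))
  for (i in src) {
    if (ell[i] <= 0) {
      out[i] <- out[i] + mass[i]
      next
    }
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    w <- exp(-d / ell[i]) * as.vector(grid$cell_area_m2)
    out <- out + mass[i] * w / sum(w)
  }
  matrix(out, nrow = grid$n_lat, ncol = grid$n_lon)
}

#' Steady-state concentration fields from an emission inventory
#'
#' A lifetime-based surrogate for a chemical-transport model. Per species
#' and cell, the emission rate Q (ug/s) sustains a steady-state column mass
#' `Q * tau`, which is spread over the domain by an isotropic exponential
#' kernel with e-folding length `wind_speed * tau` (advective mixing during
#' the species lifetime) and converted to a near-surface concentration by
#' dividing by cell area times mixing height. A fraction of emitted SO2
#' sulphur (default 0.5, i.e. oxidation and deposition sinks of equal
#' strength) is converted to sulphate mass and handled with the sulphate
#' lifetime; a fraction of emitted NOx nitrogen forms aerosol nitrate; and
#' ammonium accompanies sulphate and nitrate at neutralisation
#' stoichiometry. Concentrations are linear in emissions by construction.
#'
#' @param emis An `emission_grid`.
#' @param meteo A `meteo_fields` on the same grid.
#' @param lifetimes A `species_lifetimes`.
#' @param so2_to_so4 Fraction of emitted SO2-sulphur oxidised to sulphate.
#' @param nox_to_no3 Fraction of emitted NOx-nitrogen forming aerosol
#'   nitrate.
#' @param ammonium Fraction of full ammonium-neutralisation stoichiometry to
#'   apply (1 = ammonium sulphate + ammonium nitrate).
#' @return Object of class `concentration_field` with component matrices
#'   (ug/m^3) `so4`, `no3`, `nh4`, `primary`, zero `sslt`/`background`
#'   (ship-attributable only), `total`, and the `scenario` tag.
#' @export
steady_state_concentration <- function(emis, meteo, lifetimes = species_lifetimes(),
                                       so2_to_so4 = 0.5, nox_to_no3 = 0.1,
                                       ammonium = 1) {
  stopifnot(inherits(emis, "emission_grid"), inherits(lifetimes, "species_lifetimes"))
  grid <- emis$grid
  if (any(meteo$mixing_height <= 0)) {
    stop("mixing height must be positive everywhere", call. = FALSE)
  }
  period_s <- max(emis$period_hours, 1e-12) * 3600
  day_s <- 86400
  rate <- function(species) emis$species[[species]] * 1e12 / period_s  # ug/s

  conc_of <- function(q_ug_s, tau_days) {
    tau <- tau_days * day_s
    colmass <- q_ug_s * tau                       # ug per cell column
    spread <- spread_mass(grid, colmass, meteo$wind_speed * tau)
    spread / (grid$cell_area_m2 * meteo$mixing_height)
  }

  # sulphate: primary SO4 plus oxidised share of SO2-S (S -> SO4 mass x3)
  q_so4 <- rate("SO4_primary") + rate("SO2") * 0.5 * so2_to_so4 * 3
  c_so4 <- conc_of(q_so4, lifetimes$tau_so4)
  # nitrate from NOx (NO2-equivalent mass): N = 14/46, NO3 = N x 62/14
  q_no3 <- rate("NOx") * (14 / 46) * nox_to_no3 * (62 / 14)
  c_no3 <- conc_of(q_no3, lifetimes$tau_no3)
  c_nh4 <- ammonium * (c_so4 * 36 / 96 + c_no3 * 18 / 62)
  c_prim <- conc_of(rate("PM_EC_OC_ash"), lifetimes$tau_primary)

  components <- list(so4 = c_so4, no3 = c_no3, nh4 = c_nh4,
                     primary = c_prim,
                     sslt = empty_field(grid), background = empty_field(grid))
  structure(list(grid = grid, scenario = emis$scenario,
                 components = components,
                 total = Reduce(`+`, components)),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> scenario %s, mean total %.3g ug/m3\n",
              x$scenario, mean(x$total)))
  invisible(x)
}

#' Ammonium-nitrate compensation of a sulphate reduction
#'
#' When sulphate declines, some ammonia is freed to form ammonium nitrate,
#' partially offsetting the PM reduction. The surrogate offsets a fixed
#' fraction `kappa` of the local sulphate reduction (default 1%), raised to
#' `kappa_high` (default 15%) in designated high-ammonia cells, and is
#' further capped by the locally available ammonia equivalent.
#'
#' @param delta_so4 Sulphate change field (scenario minus baseline, ug/m^3);
#'   negative where sulphate declines.
#' @param kappa Offset fraction of the sulphate reduction.
#' @param kappa_high Offset fraction in high-ammonia cells.
#' @param high_ammonia Logical mask of high-ammonia cells (default none).
#' @param ammonia_equiv Available ammonia-equivalent nitrate mass (ug/m^3,
#'   field or scalar); must be non-negative.
#' @return Nitrate offset field (>= 0), zero where sulphate did not decline.
#' @export
nitrate_compensation <- function(delta_so4, kappa = 0.01, kappa_high = 0.15,
                                 high_ammonia = NULL, ammonia_equiv = Inf) {
  if (any(ammonia_equiv < 0)) {
    stop("`ammonia_equiv` must be non-negative", call. = FALSE)
  }
  if (kappa < 0 || kappa_high > 1) {
    stop("offset fractions must lie in [0, 1]", call. = FALSE)
  }
  kf <- matrix(kappa, nrow(delta_so4), ncol(delta_so4))
  if (!is.null(high_ammonia)) kf[high_ammonia] <- kappa_high
  pmin(kf * pmax(-delta_so4, 0), ammonia_equiv)
}

#' Assemble total PM2.5 from ship components and background
#'
#' @param ship A ship-attributable `concentration_field`.
#' @param background A `background_pm` (sea-salt + terrestrial components).
#' @return A `concentration_field` whose `total` is the exact component sum,
#'   with a `sulphate_share` diagnostic attribute (area mean of
#'   sulphate / total).
#' @export
assemble_pm25 <- function(ship, background) {
  stopifnot(inherits(ship, "concentration_field"))
  comp <- ship$components
  if (!all(dim(background$total) == dim(ship$total))) {
    stop("background grid does not match the concentration grid", call. = FALSE)
  }
  if (any(vapply(comp, function(m) any(m < 0), TRUE))) {
    stop("negative ship component concentrations", call. = FALSE)
  }
  comp$sslt <- background$sslt
  comp$background <- background$other
  total <- Reduce(`+`, comp)
  out <- structure(list(grid = ship$grid, scenario = ship$scenario,
                        components = comp, total = total),
                   class = "concentration_field")
  attr(out, "sulphate_share") <- mean(comp$so4 / pmax(total, 1e-12))
  out
}

#' Difference of two total-PM2.5 fields
#'
#' @param c1 Scenario `concentration_field` (the one with more emissions).
#' @param c0 Counterfactual `concentration_field`.
#' @return Matrix `c1$total - c0$total`.
#' @export
concentration_delta <- function(c1, c0) {
  if (!all(dim(c1$total) == dim(c0$total))) {
    stop("concentration fields on different grids", call. = FALSE)
  }
  c1$total - c0$total
}

#' Sulphur burden and mean lifetime diagnostic
#'
#' At steady state the atmospheric burden of each species equals its
#' emission (= sink) rate times its lifetime; the mean sulphur lifetime is
#' the sink-flux-weighted average of the species lifetimes.
#'
#' @param emis An `emission_grid`.
#' @param lifetimes A `species_lifetimes`.
#' @return List with `burden_tonnes_s` (steady-state sulphur burden,
#'   tonnes S), `mean_lifetime_days`, and the per-species sulphur emission
#'   rates `rate_tonnes_s_day`.
#' @export
burden_diagnostic <- function(emis, lifetimes = species_lifetimes()) {
  stopifnot(inherits(emis, "emission_grid"))
  period_days <- max(emis$period_hours, 1e-12) / 24
  rate <- c(SO2 = sum(emis$species$SO2) * (32 / 64) / period_days,
            SO4 = sum(emis$species$SO4_primary) / 3 / period_days)
  tau <- c(SO2 = lifetimes$tau_so2, SO4 = lifetimes$tau_so4)
  burden <- sum(rate * tau)
  mean_tau <- if (sum(rate) > 0) burden / sum(rate) else NA_real_
  list(burden_tonnes_s = burden, mean_lifetime_days = mean_tau,
       rate_tonnes_s_day = rate)
}
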