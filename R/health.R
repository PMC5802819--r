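#' Concentration-response model specification
#'
#' Endpoint-specific slope of log relative risk per ug/m^3 of PM2.5 with its
#' 95% confidence interval. Defaults are the chronic-exposure coefficients
#' used throughout the package: cardiovascular mortality
#' beta = 0.023111 (0.013103, 0.033647), lung-cancer mortality
#' beta = 0.031481 (0.006766, 0.055962) — both for the 30+ cohort — and
#' childhood-asthma morbidity beta = 0.002469 (0.001291, 0.003633) for the
#' 14-and-under cohort. Two functional forms are supported: the
#' (conventionally named) linear form `RR = exp(beta * (C1 - C0))` and the
#' log-linear form `RR = ((C1 + 1) / (C0 + 1))^beta`. Published log-linear
#' coefficients for these endpoints are not bundled; when `form =
#' "log_linear"` is requested with the default betas a warning notes that
#' the linear-form coefficients are being reused.
#'
#' @param endpoint `"CV"`, `"LC"` or `"ASTHMA"`.
#' @param form `"linear"` or `"log_linear"`.
#' @param beta,ci_low,ci_high Optional overrides of the default
#'   coefficients, per ug/m^3.
#' @return Object of class `cr_model`.
#' @examples
#' cr_model("LC")$beta
#' @export
cr_model <- function(endpoint = c("CV", "LC", "ASTHMA"),
                     form = c("linear", "log_linear"),
                     beta = NULL, ci_low = NULL, ci_high = NULL) {
  endpoint <- match.arg(endpoint)
  form <- match.arg(form)
  defaults <- list(
    CV = c(0.023111, 0.013103, 0.033647),
    LC = c(0.031481, 0.006766, 0.055962),
    ASTHMA = c(0.002469, 0.001291, 0.003633))
  d <- defaults[[endpoint]]
  if (form == "log_linear" && is.null(beta)) {
    warning("no bundled log-linear coefficients for ", endpoint,
            "; reusing the linear-form beta", call. = FALSE)
  }
  beta <- if (is.null(beta)) d[1] else beta
  ci_low <- if (is.null(ci_low)) d[2] else ci_low
  ci_high <- if (is.null(ci_high)) d[3] else ci_high
  if (!(ci_low <= beta && beta <= ci_high)) {
    stop("require ci_low <= beta <= ci_high", call. = FALSE)
  }
  structure(list(endpoint = endpoint, form = form, beta = beta,
                 ci_low = ci_low, ci_high = ci_high,
                 cohort = if (endpoint == "ASTHMA") "under14" else "age30plus"),
            class = "cr_model")
}

#' Relative risk of an exposure increment
#'
#' Linear form: `RR = exp(beta * (C1 - C0))`. Log-linear form:
#' `RR = ((C1 + 1) / (C0 + 1))^beta`. Both equal 1 when `C1 = C0`.
#'
#' @param model A `cr_model` (or a bare beta, interpreted as linear form).
#' @param c0 Counterfactual concentration, ug/m^3 (>= 0).
#' @param c1 Scenario concentration, ug/m^3 (>= 0).
#' @param beta Optional beta override (used for CI bounds).
#' @return Relative risk (vectorised).
#' @examples
#' relative_risk(cr_model("LC"), 0, 1)  # 1.031982
#' @export
relative_risk <- function(model, c0, c1, beta = NULL) {
  if (is.numeric(model)) model <- list(form = "linear", beta = model)
  if (any(c0 < 0, na.rm = TRUE) || any(c1 < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  b <- if (is.null(beta)) model$beta else beta
  switch(model$form,
         linear = exp(b * (c1 - c0)),
         log_linear = ((c1 + 1) / (c0 + 1))^b,
         stop("unknown C-R form", call. = FALSE))
}

#' Attributable fraction from a relative risk
#'
#' `AF = (RR - 1) / RR`: the share of the endpoint's incidence attributable
#' to the exposure increment.
#'
#' @param rr Relative risk (> 0).
#' @return Attributable fraction (vectorised).
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0, na.rm = TRUE)) stop("`rr` must be positive", call. = FALSE)
  (rr - 1) / rr
}

#' Attributable fraction, direct linear form
#'
#' `AF = 1 - exp(beta * (C0 - C1))`; algebraically identical to composing
#' [relative_risk()] (linear form) with [attributable_fraction()].
#'
#' @param beta Slope per ug/m^3.
#' @param c0,c1 Counterfactual and scenario concentrations, ug/m^3.
#' @return Attributable fraction.
#' @export
af_linear <- function(beta, c0, c1) {
  1 - exp(beta * (c0 - c1))
}

#' Excess annual cases from attributable fraction, incidence and population
#'
#' `E = AF * B * P` with the incidence rate converted from per-100,000
#' cohort persons per year to per person-year.
#'
#' @param af Attributable fraction.
#' @param b_per_100k Incidence rate per 100,000 cohort persons per year.
#' @param p Exposed cohort population, persons.
#' @return Annual excess cases (vectorised).
#' @examples
#' excess_cases(0.1, 500, 1e5)  # 50
#' @export
excess_cases <- function(af, b_per_100k, p) {
  if (any(b_per_100k < 0, na.rm = TRUE) || any(p < 0, na.rm = TRUE)) {
    stop("incidence and population must be non-negative", call. = FALSE)
  }
  af * (b_per_100k / 1e5) * p
}

#' Convert an age-standardised rate to a crude rate
#'
#' @param asr Age-standardised rate.
#' @param nonasr_to_asr_ratio Crude:ASR ratio from the population structure.
#' @return Crude rate `asr * ratio`.
#' @export
asr_to_crude <- function(asr, nonasr_to_asr_ratio) {
  if (any(asr <= 0) || any(nonasr_to_asr_ratio <= 0)) {
    stop("`asr` and ratio must be positive", call. = FALSE)
  }
  asr * nonasr_to_asr_ratio
}

#' Gridded cohort population
#'
#' Applies each country's cohort fraction uniformly to its cells. Cells
#' whose country lacks a fraction fall back to the mean fraction with a
#' warning; sea or unassigned cells get zero cohort population.
#'
#' @param world A `synthetic_world`.
#' @param cohort `"age30plus"` or `"under14"`.
#' @return Matrix of cohort persons per cell.
#' @export
cohort_population <- function(world, cohort = c("age30plus", "under14")) {
  cohort <- match.arg(cohort)
  col <- if (cohort == "age30plus") "frac_30plus" else "frac_under14"
  frac <- world$cohorts[[col]][match(world$country_id, world$cohorts$country)]
  if (any(is.na(frac) & !is.na(world$country_id))) {
    warning("missing cohort fraction for some countries; using the mean",
            call. = FALSE)
    frac[is.na(frac) & !is.na(world$country_id)] <- mean(world$cohorts[[col]])
  }
  frac[is.na(frac)] <- 0
  matrix(world$population * frac, nrow = world$grid$n_lat)
}

#' Gridded health burden of a concentration pair
#'
#' Per cell: `E = [1 - exp(beta (C0 - C1))] * B * P` (or the log-linear
#' analogue), with central, low and high estimates from the beta confidence
#' interval. Incidence is resolved per country with a global-mean fallback.
#'
#' @param model A `cr_model`.
#' @param c0,c1 Counterfactual and scenario total-PM2.5 fields (matrices,
#'   ug/m^3).
#' @param world A `synthetic_world`.
#' @param incidence An `incidence_table`.
#' @return Object of class `burden_result`: per-cell fields `E`, `E_low`,
#'   `E_high`, the endpoint/cohort, and global totals.
#' @export
health_burden <- function(model, c0, c1, world, incidence) {
  stopifnot(inherits(model, "cr_model"), inherits(world, "synthetic_world"))
  p <- cohort_population(world, model$cohort)
  b <- incidence_rate(incidence, world$country_id, model$endpoint)
  b <- matrix(b, nrow = world$grid$n_lat)
  b[is.na(world$country_id)] <- 0
  one <- function(beta) {
    af <- attributable_fraction(relative_risk(model, c0, c1, beta = beta))
    excess_cases(af, b, p)
  }
  e <- one(model$beta); lo <- one(model$ci_low); hi <- one(model$ci_high)
  structure(list(endpoint = model$endpoint, cohort = model$cohort,
                 form = model$form, world = world,
                 E = e, E_low = lo, E_high = hi,
                 total = sum(e), total_low = sum(lo), total_high = sum(hi)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> %s (%s, %s): %.1f cases/yr (CI %.1f; %.1f)\n",
              x$endpoint, x$form, x$cohort, x$total, x$total_low, x$total_high))
  invisible(x)
}

#' Aggregate a gridded burden to country, region and global tables
#'
#' @param burden A `burden_result`.
#' @param region_scheme Optional data.frame mapping `country` to `region`;
#'   default puts every country in one `"global"` region. Every country must
#'   be mapped.
#' @return List of data.frames `country`, `region`, `global`, each with
#'   `E_low`, `E_central`, `E_high` and (for regions) percent `share` of the
#'   global central estimate.
#' @export
aggregate_burden <- function(burden, region_scheme = NULL) {
  w <- burden$world
  cid <- as.vector(w$country_id)
  keep <- !is.na(cid)
  by_country <- function(field) {
    v <- rowsum(as.vector(field)[keep], cid[keep])
    data.frame(country = as.integer(rownames(v)), value = v[, 1])
  }
  ce <- by_country(burden$E)
  country <- data.frame(country = ce$country,
                        E_low = by_country(burden$E_low)$value,
                        E_central = ce$value,
                        E_high = by_country(burden$E_high)$value)
  if (is.null(region_scheme)) {
    region_scheme <- data.frame(country = country$country, region = "global")
  }
  m <- match(country$country, region_scheme$country)
  if (anyNA(m)) {
    stop("countries missing from the region scheme: ",
         paste(country$country[is.na(m)], collapse = ", "), call. = FALSE)
  }
  country$region <- region_scheme$region[m]
  region <- do.call(rbind, lapply(split(country, country$region), function(d) {
    data.frame(region = d$region[1], E_low = sum(d$E_low),
               E_central = sum(d$E_central), E_high = sum(d$E_high))
  }))
  rownames(region) <- NULL
  glob <- data.frame(E_low = sum(country$E_low),
                     E_central = sum(country$E_central),
                     E_high = sum(country$E_high))
  region$share <- if (glob$E_central > 0) {
    100 * region$E_central / glob$E_central
  } else NA_real_
  list(country = country[, c("country", "region", "E_low", "E_central",
                             "E_high")],
       region = region, global = glob)
}

#' Percentage reduction between two burdens
#'
#' `100 * (a - b) / a`; undefined (NA, with a message) for a zero baseline.
#'
#' @param a Baseline value (> 0 for a defined result).
#' @param b Comparison value.
#' @param digits Optional rounding of the reported percentage.
#' @return Percentage reduction.
#' @examples
#' percent_reduction(403300, 266300)  # ~34
#' @export
percent_reduction <- function(a, b, digits = NULL) {
  if (any(a == 0)) {
    message("zero baseline: percent reduction undefined")
    return(NA_real_)
  }
  out <- 100 * (a - b) / a
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Report-style rounding for burden tables
#'
#' Mortality to the nearest 100 cases, asthma morbidity to the nearest
#' 100,000 cases.
#'
#' @param x Value(s) to round.
#' @param endpoint `"CV"`, `"LC"`, `"COMBINED"` or `"ASTHMA"`.
#' @return Rounded value.
#' @export
report_round <- function(x, endpoint) {
  unit <- if (endpoint == "ASTHMA") 1e5 else 100
  round(x / unit) * unit
}
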