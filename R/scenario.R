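#' Define a synthetic study scenario
#'
#' A scenario bundles every knob of the synthetic-data generator: the tract
#' mosaic (number of counties, tracts per county, demographic groups, the
#' per-county segregation parameter `mixing_theta`), the planted
#' concentration model (per-component intercepts `alpha_m` and dissimilarity
#' elasticities `beta_m`, region offsets, between-county and within-year
#' log-scale noise), the monitoring realism (every-third-day schedule,
#' missingness, detection limits, urban fraction), and a single master seed.
#'
#' The planted model is log-linear: for county \eqn{j} and component \eqn{m},
#' \deqn{\log \mu_{jm} = \alpha_m + \beta_m \log DI_j + \gamma_{region(j)} +
#'   N(0, \sigma_{annual}^2)}
#' and daily values are lognormal around \eqn{\mu_{jm}} with log-scale SD
#' `sigma_daily`. Metals are in ng/m3, PM2.5 in ug/m3.
#'
#' Defaults describe a plausible national monitoring study: elasticities for
#' the anthropogenic metals (Cu, Zn, Ni, Cr, Pb, V) around 0.9--1.6
#' (9--16\% concentration increase per 10\% increase in DI) and for the
#' crustal metals (Fe, Mn, Ti) around 0.4--0.7, with PM2.5 in between.
#'
#' @param n_counties number of counties to simulate.
#' @param tracts_per_county census tracts per county (>= 2 for a usable DI).
#' @param groups demographic group labels; must contain "NHW" and "NHB".
#' @param group_shares county-level population shares, one per group, summing
#'   to 1.
#' @param mixing_theta segregation knob in \[0, 1\], scalar or one value per
#'   county; 0 gives perfectly even tracts (DI = 0), 1 complete separation
#'   (DI = 1).
#' @param county_population persons per county, scalar or per county.
#' @param components component labels; include "PM25" if mass proportions
#'   will be computed downstream.
#' @param alpha_m named log-concentration intercepts (log ng/m3; log ug/m3
#'   for PM25), one per component.
#' @param beta_m named DI elasticities, one per component.
#' @param region_effects named additive log-scale offsets; counties are
#'   assigned to regions round-robin.
#' @param sigma_annual between-county log-scale noise SD (>= 0).
#' @param sigma_daily within-year daily log-scale noise SD (>= 0).
#' @param mdl named detection limits per component, in the component's
#'   concentration units.
#' @param missing_rate probability that a scheduled sample is missing.
#' @param urban_fraction expected fraction of counties classified urban.
#' @param monitors_per_county monitors simulated per county.
#' @param year calendar year of the simulated records.
#' @param period demographic table period label.
#' @param seed master integer seed; all streams derive from it.
#' @return An object of class `synthetic_scenario` (a validated list).
#' @export
#' @examples
#' sc <- synthetic_scenario(n_counties = 10, seed = 42)
#' sc$beta_m[["Pb"]]
synthetic_scenario <- function(n_counties = 100,
                               tracts_per_county = 20,
                               groups = c("NHW", "NHB", "Hispanic", "Asian",
                                          "NativeAmerican"),
                               group_shares = c(NHW = 0.60, NHB = 0.13,
                                                Hispanic = 0.18, Asian = 0.06,
                                                NativeAmerican = 0.03),
                               mixing_theta = NULL,
                               county_population = 100000,
                               components = c("Cu", "Zn", "Ni", "Cr", "Pb",
                                              "V", "Fe", "Mn", "Ti", "PM25"),
                               alpha_m = c(Cu = log(3), Zn = log(8),
                                           Ni = log(1), Cr = log(1),
                                           Pb = log(5), V = log(1.5),
                                           Fe = log(80), Mn = log(3),
                                           Ti = log(4), PM25 = log(12)),
                               beta_m = c(Cu = 1.2, Zn = 1.4, Ni = 1.0,
                                          Cr = 1.1, Pb = 0.904, V = 1.3,
                                          Fe = 0.71, Mn = 0.5, Ti = 0.41,
                                          PM25 = 0.512),
                               region_effects = c(Midwest = 0, Northeast = 0.1,
                                                  South = 0.15, West = -0.1),
                               sigma_annual = 0.3,
                               sigma_daily = 0.5,
                               mdl = c(Cu = 0.3, Zn = 0.3, Ni = 0.2, Cr = 0.2,
                                       Pb = 0.3, V = 0.2, Fe = 1.0, Mn = 0.3,
                                       Ti = 0.5, PM25 = 0.5),
                               missing_rate = 0.1,
                               urban_fraction = 0.5,
                               monitors_per_county = 1,
                               year = 2019,
                               period = "2014-2018",
                               seed = 1) {
  if (is.null(mixing_theta)) {
    # span the DI range while keeping DI > 0 so logs are defined
    mixing_theta <- seq(0.05, 0.95, length.out = n_counties)
  }
  sc <- structure(list(
    n_counties = as.integer(n_counties),
    tracts_per_county = as.integer(tracts_per_county),
    groups = groups,
    group_shares = group_shares,
    mixing_theta = rep_len(mixing_theta, n_counties),
    county_population = rep_len(county_population, n_counties),
    components = components,
    alpha_m = alpha_m[components],
    beta_m = beta_m[components],
    region_effects = region_effects,
    sigma_annual = sigma_annual,
    sigma_daily = sigma_daily,
    mdl = mdl[components],
    missing_rate = missing_rate,
    urban_fraction = urban_fraction,
    monitors_per_county = as.integer(monitors_per_county),
    year = as.integer(year),
    period = period,
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a synthetic scenario
#'
#' Checks range invariants (`mixing_theta`, `missing_rate`,
#' `urban_fraction` in \[0, 1\]; noise SDs >= 0; positive populations and
#' tract counts; NHW/NHB present; per-component parameters complete).
#' Signals a `segmetals_invalid_scenario` error on the first violation.
#'
#' @param sc a `synthetic_scenario`.
#' @return `sc`, invisibly, if valid.
#' @export
validate_scenario <- function(sc) {
  bad <- function(msg) sm_abort(msg, "segmetals_invalid_scenario")
  if (sc$n_counties < 1) bad("n_counties must be >= 1")
  if (sc$tracts_per_county < 1) bad("tracts_per_county must be >= 1")
  if (!all(c("NHW", "NHB") %in% sc$groups)) bad("groups must include NHW and NHB")
  if (!setequal(names(sc$group_shares), sc$groups)) {
    bad("group_shares must be named by the group labels")
  }
  if (abs(sum(sc$group_shares) - 1) > 1e-8) bad("group_shares must sum to 1")
  if (any(sc$mixing_theta < 0 | sc$mixing_theta > 1)) {
    bad("mixing_theta must lie in [0, 1]")
  }
  if (any(sc$county_population <= 0)) bad("county populations must be positive")
  if (sc$missing_rate < 0 || sc$missing_rate > 1) {
    bad("missing_rate must lie in [0, 1]")
  }
  if (sc$urban_fraction < 0 || sc$urban_fraction > 1) {
    bad("urban_fraction must lie in [0, 1]")
  }
  if (sc$sigma_annual < 0 || sc$sigma_daily < 0) bad("sigma_* must be >= 0")
  for (fld in c("alpha_m", "beta_m", "mdl")) {
    v <- sc[[fld]]
    if (length(v) != length(sc$components) || any(is.na(v)) ||
        !setequal(names(v), sc$components)) {
      bad(sprintf("%s must provide one finite value per component", fld))
    }
  }
  if (any(sc$mdl <= 0)) bad("mdl values must be positive")
  if (sc$monitors_per_county < 1) bad("monitors_per_county must be >= 1")
  invisible(sc)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic study scenario\n")
  cat(sprintf("  counties: %d (%d tracts each), seed %d, year %d\n",
              x$n_counties, x$tracts_per_county, x$seed, x$year))
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  components: %s\n", paste(x$components, collapse = ", ")))
  cat(sprintf("  mixing_theta in [%.2f, %.2f]; sigma_annual %.2f; sigma_daily %.2f\n",
              min(x$mixing_theta), max(x$mixing_theta),
              x$sigma_annual, x$sigma_daily))
  cat(sprintf("  missing_rate %.2f; urban_fraction %.2f\n",
              x$missing_rate, x$urban_fraction))
  invisible(x)
}
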