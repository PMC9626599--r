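#' Generate census-tract demographic tables with controllable segregation
#'
#' Builds a tract mosaic for every county in the scenario using a two-block
#' construction: a fraction `mixing_theta` of each minority group's county
#' population is packed into a dedicated first tract, with the remainder
#' spread evenly across all tracts; the reference NHW population avoids the
#' packed tract by the same fraction. In the continuum this makes the
#' NHB/NHW dissimilarity index equal `mixing_theta` exactly, so theta = 0
#' yields DI = 0, theta = 1 yields DI = 1, and DI is monotone in theta.
#' Counts are integers (largest-remainder rounding); county group totals are
#' made divisible by the tract count so theta = 0 gives exactly even tracts.
#'
#' @param scenario a [synthetic_scenario()].
#' @param allow_single_tract generate single-tract counties (only useful to
#'   exercise the downstream exclusion rule); by default they are refused.
#' @return A data.frame with one row per tract: `tract_id`, `county_id`
#'   (5-character FIPS-style), `period`, one population column per group,
#'   and `total`.
#' @export
#' @examples
#' tr <- generate_tracts(synthetic_scenario(n_counties = 4, seed = 7))
#' head(tr)
generate_tracts <- function(scenario, allow_single_tract = FALSE) {
  validate_scenario(scenario)
  nt <- scenario$tracts_per_county
  if (nt < 2 && !allow_single_tract) {
    sm_abort(paste0("tracts_per_county = ", nt, " would make every county a ",
                    "single-tract county, which the segregation analysis ",
                    "excludes; pass allow_single_tract = TRUE to force it"),
             "segmetals_invalid_scenario")
  }
  groups <- scenario$groups
  out <- vector("list", scenario$n_counties)
  for (ci in seq_len(scenario$n_counties)) {
    theta <- scenario$mixing_theta[ci]
    pop <- scenario$county_population[ci]
    # county totals divisible by the tract count: theta = 0 is exactly even
    totals <- pmax(nt * round(scenario$group_shares[groups] * pop / nt), nt)
    alloc <- matrix(0, nrow = nt, ncol = length(groups),
                    dimnames = list(NULL, groups))
    for (g in groups) {
      ng <- totals[[g]]
      even <- rep((1 - theta) * ng / nt, nt)
      packed <- numeric(nt)
      if (g == "NHW") {
        if (nt > 1) packed[-1] <- theta * ng / (nt - 1) else packed[1] <- theta * ng
      } else {
        packed[1] <- theta * ng
      }
      alloc[, g] <- round_preserve_sum(even + packed)
    }
    out[[ci]] <- data.frame(
      tract_id = sprintf("%s%06d", fips_id(ci), seq_len(nt)),
      county_id = fips_id(ci),
      period = scenario$period,
      alloc,
      total = as.integer(rowSums(alloc)),
      check.names = FALSE
    )
  }
  tracts <- do.call(rbind, out)
  rownames(tracts) <- NULL
  if (any(colSums(tracts[groups]) <= 0)) {
    sm_abort("a demographic group received non-positive total population",
             "segmetals_invalid_scenario")
  }
  tracts
}

#' Every-third-day sampling calendar
#'
#' Day-of-year 1, 4, 7, ... of the given year: 122 scheduled days in a
#' 365-day year, matching the roughly 121 samples per year expected of a
#' speciated PM2.5 monitor on a 1-in-3 day schedule.
#'
#' @param year calendar year.
#' @return Vector of `Date`s.
#' @export
sampling_calendar <- function(year) {
  start <- as.Date(sprintf("%d-01-01", year))
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) - start) + 1L
  start + seq(1L, ndays, by = 3L) - 1L
}

#' Generate daily monitor records with a planted DI-concentration model
#'
#' For every county and component the true annual mean follows the planted
#' log-linear model
#' `log(mu) = alpha_m + beta_m * log(DI) + region effect + N(0, sigma_annual)`;
#' daily concentrations are lognormal around `mu` (log-scale SD
#' `sigma_daily`, mean-preserving parameterisation). Records follow the
#' every-third-day calendar; each scheduled sample is independently dropped
#' with probability `missing_rate`. Values below the detection limit are
#' kept as generated — censoring is a downstream flag, never a truncation.
#'
#' Every (county, monitor, component) tuple draws from its own seed stream
#' derived from the scenario seed, so regeneration is byte-identical and
#' adding a component does not perturb the others.
#'
#' @param scenario a [synthetic_scenario()].
#' @param di_by_county named numeric vector mapping county_id to its
#'   dissimilarity index (all > 0 unless `zero_di` says otherwise).
#' @param zero_di policy for counties with DI = 0: `"error"` (default)
#'   aborts naming the county; `"drop"` omits those counties.
#' @return A list with `records` (one row per monitor-date-component:
#'   `monitor_id`, `county_id`, `date`, `component`, `concentration`,
#'   `mdl`, `valid`, `urban`, `region`, `latitude`, `longitude`, `unit`)
#'   and `truth` (class `synthetic_truth`: per county-component planted
#'   elasticity, realized DI, true annual mean, plus the seed).
#' @export
generate_monitor_records <- function(scenario, di_by_county,
                                     zero_di = c("error", "drop")) {
  validate_scenario(scenario)
  zero_di <- match.arg(zero_di)
  ids <- names(di_by_county)
  if (is.null(ids)) sm_abort("di_by_county must be named by county_id",
                             "segmetals_invalid_scenario")
  zero <- di_by_county <= 0
  if (any(zero)) {
    if (zero_di == "error") {
      sm_abort(paste0("DI is zero (log undefined) for county ",
                      paste(ids[zero], collapse = ", "),
                      "; pass zero_di = \"drop\" to omit such counties"),
               "segmetals_zero_di")
    }
    di_by_county <- di_by_county[!zero]
    ids <- ids[!zero]
  }
  n <- length(ids)
  regions <- rep_len(names(scenario$region_effects), n)
  urban <- with_stream(stream_seed(scenario$seed, "urban"),
                       stats::runif(n) < scenario$urban_fraction)
  cal <- sampling_calendar(scenario$year)
  comps <- scenario$components

  rec <- vector("list", n * scenario$monitors_per_county * length(comps))
  truth <- vector("list", n * length(comps))
  k <- 0L; tk <- 0L
  for (j in seq_len(n)) {
    cid <- ids[j]
    di <- di_by_county[[j]]
    for (m in seq_len(scenario$monitors_per_county)) {
      mon_id <- sprintf("%s-M%02d", cid, m)
      latlon <- with_stream(stream_seed(scenario$seed, "site", cid, m), {
        c(stats::runif(1, 25, 49), stats::runif(1, -124, -67))
      })
      for (cm in comps) {
        mu <- NULL
        if (m == 1L) {
          # annual truth is a county-component property, drawn once
          eps <- with_stream(stream_seed(scenario$seed, "annual", cid, cm),
                             stats::rnorm(1, 0, scenario$sigma_annual))
          mu <- exp(scenario$alpha_m[[cm]] + scenario$beta_m[[cm]] * log(di) +
                      scenario$region_effects[[regions[j]]] + eps)
          tk <- tk + 1L
          truth[[tk]] <- data.frame(
            county_id = cid, component = cm, beta = scenario$beta_m[[cm]],
            di = di, true_annual_mean = mu, region = regions[j],
            urban = urban[j]
          )
        } else {
          mu <- truth[[which(vapply(truth[seq_len(tk)], function(t)
            t$county_id == cid && t$component == cm, logical(1)))[1]]]$true_annual_mean
        }
        daily <- with_stream(stream_seed(scenario$seed, "daily", cid, m, cm), {
          keep <- stats::runif(length(cal)) >= scenario$missing_rate
          conc <- stats::rlnorm(sum(keep),
                                meanlog = log(mu) - scenario$sigma_daily^2 / 2,
                                sdlog = scenario$sigma_daily)
          list(dates = cal[keep], conc = conc)
        })
        if (length(daily$conc) == 0L) next
        k <- k + 1L
        rec[[k]] <- data.frame(
          monitor_id = mon_id, county_id = cid, date = daily$dates,
          component = cm, concentration = daily$conc,
          mdl = scenario$mdl[[cm]], valid = TRUE, urban = urban[j],
          region = regions[j], latitude = latlon[1], longitude = latlon[2],
          unit = if (cm == "PM25") "ug/m3" else "ng/m3"
        )
      }
    }
  }
  records <- do.call(rbind, rec[seq_len(k)])
  rownames(records) <- NULL
  truth <- do.call(rbind, truth[seq_len(tk)])
  rownames(truth) <- NULL
  truth <- structure(list(table = truth, seed = scenario$seed),
                     class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Planted truth: %d county-component pairs (seed %d)\n",
              nrow(x$table), x$seed))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `tracts.csv`, `monitor_records.csv` (ingestion schemas of the QC
#' and segregation stages) and `truth.json`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @param minority_group,reference_group pair used for the planted DI.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_dataset <- function(scenario, dir,
                                    minority_group = "NHB",
                                    reference_group = "NHW") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tracts <- generate_tracts(scenario)
  di <- di_all_pairs(tracts, minority_group, reference_group)
  di_ok <- di[di$status == "ok", ]
  dimap <- stats::setNames(di_ok$di, di_ok$county_id)
  gen <- generate_monitor_records(scenario, dimap)
  paths <- list(
    tracts = file.path(dir, "tracts.csv"),
    monitor_records = file.path(dir, "monitor_records.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(tracts, paths$tracts, row.names = FALSE)
  utils::write.csv(gen$records, paths$monitor_records, row.names = FALSE)
  jsonlite::write_json(list(seed = gen$truth$seed, table = gen$truth$table),
                       paths$truth, dataframe = "columns", digits = NA)
  invisible(paths)
}
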