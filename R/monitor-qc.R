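#' Keep only valid daily monitor records
#'
#' Retains exactly the rows flagged valid with a non-missing concentration
#' (no null codes or missing values), preserving row order. An empty result
#' is allowed.
#'
#' @param records daily monitor record table with `valid` and
#'   `concentration` columns.
#' @return The filtered table.
#' @export
filter_valid <- function(records) {
  keep <- records$valid %in% TRUE & !is.na(records$concentration)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute concentrations below the detection limit
#'
#' `"keep"` leaves the table untouched (below-MDL values are retained so
#' the data are not skewed toward higher concentrations); `"mdl_over_sqrt2"`
#' is the conventional sensitivity substitution, replacing every
#' concentration strictly below its MDL with MDL divided by the square root
#' of two. Rows at or above the MDL are never altered.
#'
#' @param records daily monitor record table with `concentration` and `mdl`.
#' @param strategy `"keep"` or `"mdl_over_sqrt2"`.
#' @return The (possibly) imputed table.
#' @export
#' @examples
#' r <- data.frame(concentration = c(0.5, 1.5), mdl = 1)
#' impute_below_mdl(r, "mdl_over_sqrt2")$concentration  # 0.7071, 1.5
impute_below_mdl <- function(records, strategy = c("keep", "mdl_over_sqrt2")) {
  strategy <- tryCatch(match.arg(strategy), error = function(e) {
    sm_abort(paste0("unknown MDL strategy '", strategy[1], "'"),
             "segmetals_config_error")
  })
  if (strategy == "keep") return(records)
  below <- !is.na(records$concentration) & records$concentration < records$mdl
  records$concentration[below] <- records$mdl[below] / sqrt(2)
  records
}

#' Annual mean concentration per monitor and component
#'
#' Averages valid daily samples into a monitor-component annual mean,
#' applying the completeness rule: a monitor-component-year is retained only
#' if it reports strictly more than `min_completeness` of the expected
#' number of samples (the every-third-day schedule expects about 121 per
#' year). Below-MDL values are included in the mean. 61 of 121 samples is
#' retained (0.504 > 0.5); 60 is rejected.
#'
#' @param records valid daily records (pass through [filter_valid()] first).
#' @param year calendar year to average.
#' @param min_completeness completeness threshold; retention requires
#'   `n_samples / expected_n > min_completeness`, strictly.
#' @param expected_n expected samples per monitor-year: a single number, or
#'   a named vector by `monitor_id` when monitors follow different
#'   calendars.
#' @return Data.frame with one row per monitor x component:
#'   `monitor_id`, `county_id`, `year`, `component`, `mean_concentration`,
#'   `n_samples`, `expected_n`, `completeness`, `retained`, plus carried
#'   site metadata (`urban`, `region`, `latitude`, `longitude`, `unit`
#'   when present). If the year is absent from the data an empty table is
#'   returned with a notice, not an error.
#' @export
annual_monitor_mean <- function(records, year, min_completeness = 0.5,
                                expected_n = 121) {
  yr <- as.integer(format(as.Date(records$date), "%Y"))
  recs <- records[yr == year, , drop = FALSE]
  if (nrow(recs) == 0) {
    message("annual_monitor_mean: no records for year ", year,
            "; returning empty result")
    return(data.frame(monitor_id = character(), county_id = character(),
                      year = integer(), component = character(),
                      mean_concentration = numeric(), n_samples = integer(),
                      expected_n = numeric(), completeness = numeric(),
                      retained = logical()))
  }
  carry <- intersect(c("urban", "region", "latitude", "longitude", "unit"),
                     names(recs))
  out <- recs |>
    dplyr::group_by(.data$monitor_id, .data$county_id, .data$component) |>
    dplyr::summarise(
      mean_concentration = mean(.data$concentration),
      n_samples = dplyr::n(),
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      .groups = "drop"
    ) |>
    as.data.frame()
  exp_n <- if (length(expected_n) > 1 || !is.null(names(expected_n))) {
    unname(expected_n[out$monitor_id])
  } else {
    rep(expected_n, nrow(out))
  }
  out$year <- as.integer(year)
  out$expected_n <- exp_n
  out$completeness <- out$n_samples / exp_n
  out$retained <- out$completeness > min_completeness
  out
}

#' Annual county-level exposure from retained monitor means
#'
#' Counties with several retained monitors get the unweighted arithmetic
#' mean across monitors. Mass proportions are the ratio of annual county
#' means — county metal mean over county PM2.5 mean — after converting both
#' to a common mass unit (metals ng/m3, PM2.5 ug/m3; the factor of 1000 is
#' applied once here). A county-year without a retained PM2.5 value gets
#' `NA` mass proportion.
#'
#' @param monitor_means output of [annual_monitor_mean()]; only rows with
#'   `retained = TRUE` contribute.
#' @return Data.frame with one row per county x year x component:
#'   `county_id`, `year`, `component`, `mean_concentration`,
#'   `mass_proportion` (`NA` for PM25 itself), `n_monitors`, `n_samples`,
#'   `completeness`, and `urban` (a county is urban if any of its monitors
#'   is) when site metadata were carried.
#' @export
county_annual_exposure <- function(monitor_means) {
  mm <- monitor_means[monitor_means$retained %in% TRUE, , drop = FALSE]
  if (nrow(mm) == 0) return(mm)
  if ("unit" %in% names(mm)) {
    bad <- (mm$component == "PM25" & mm$unit != "ug/m3") |
      (mm$component != "PM25" & mm$unit != "ng/m3")
    if (any(bad)) {
      sm_abort(paste0("unit mismatch: expected ng/m3 for metals and ug/m3 ",
                      "for PM25, got ", paste(unique(mm$unit[bad]),
                                              collapse = ", ")),
               "segmetals_unit_error")
    }
  }
  has_urban <- "urban" %in% names(mm)
  out <- mm |>
    dplyr::group_by(.data$county_id, .data$year, .data$component) |>
    dplyr::summarise(
      mean_concentration = mean(.data$mean_concentration),
      n_monitors = dplyr::n(),
      n_samples = sum(.data$n_samples),
      completeness = mean(.data$completeness),
      dplyr::across(dplyr::any_of("urban"), any),
      dplyr::across(dplyr::any_of("region"), dplyr::first),
      .groups = "drop"
    ) |>
    as.data.frame()
  pm <- out[out$component == "PM25", c("county_id", "year",
                                       "mean_concentration")]
  names(pm)[3] <- "pm25_mean"
  out <- merge(out, pm, by = c("county_id", "year"), all.x = TRUE,
               sort = FALSE)
  # metals are in ng/m3, PM2.5 in ug/m3: harmonize to ng/m3 once
  out$mass_proportion <- ifelse(
    out$component == "PM25", NA_real_,
    out$mean_concentration / (out$pm25_mean * 1000)
  )
  out$pm25_mean <- NULL
  out <- out[order(out$county_id, out$year, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Urban to nonurban exposure ratio with a stratified bootstrap CI
#'
#' Point estimate is the mean over urban counties divided by the mean over
#' nonurban counties for one component; the confidence interval resamples
#' counties with replacement independently within the urban and nonurban
#' strata (percentile 2.5/97.5).
#'
#' @param county_exposures output of [county_annual_exposure()] including an
#'   `urban` column.
#' @param component component label to compare.
#' @param mode `"concentration"` or `"mass_proportion"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed (the bootstrap is deterministic given it).
#' @return List: `ratio`, `ci_low`, `ci_high`, `n_urban`, `n_nonurban`.
#' @export
urban_nonurban_ratio <- function(county_exposures, component,
                                 mode = c("concentration", "mass_proportion"),
                                 n_boot = 1000, seed = 1) {
  mode <- match.arg(mode)
  ce <- county_exposures[county_exposures$component == component, ,
                         drop = FALSE]
  val <- if (mode == "concentration") ce$mean_concentration else
    ce$mass_proportion
  keep <- !is.na(val)
  val <- val[keep]; urb <- ce$urban[keep]
  u <- val[urb]; r <- val[!urb]
  if (length(u) == 0) sm_abort("no urban counties for this component",
                               "segmetals_insufficient_data")
  if (length(r) == 0) sm_abort("no nonurban counties for this component",
                               "segmetals_insufficient_data")
  ratio <- mean(u) / mean(r)
  reps <- with_stream(stream_seed(seed, "urban_ratio", component, mode), {
    um <- matrix(u[sample.int(length(u), length(u) * n_boot, replace = TRUE)],
                 ncol = n_boot)
    rm <- matrix(r[sample.int(length(r), length(r) * n_boot, replace = TRUE)],
                 ncol = n_boot)
    colMeans(um) / colMeans(rm)
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  list(ratio = ratio, ci_low = ci[1], ci_high = ci[2],
       n_urban = length(u), n_nonurban = length(r))
}
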