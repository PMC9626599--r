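#' Dissimilarity index of residential segregation for one county
#'
#' The index of dissimilarity between a minority and a reference group,
#' computed over a county's census tracts:
#' \deqn{D = 0.5 \sum_i \left| \frac{x_i}{X} - \frac{y_i}{Y} \right|}
#' where \eqn{x_i}, \eqn{y_i} are tract populations of the minority and
#' reference group and \eqn{X}, \eqn{Y} the county totals. D ranges from 0
#' (perfect evenness: every tract mirrors the county's group proportions)
#' to 1 (complete separation), and reads as the fraction of the minority
#' population that would have to move to even out the county.
#'
#' @param tracts tract demographic table (as from [generate_tracts()] or an
#'   ACS-style CSV): one row per tract with `tract_id`, `county_id` and one
#'   population column per group.
#' @param county_id the county to evaluate.
#' @param minority_group,reference_group group column names.
#' @return A one-row data.frame: `county_id`, `period` (if present),
#'   `minority_group`, `reference_group`, `di`, `n_tracts`,
#'   `minority_total`, `reference_total`.
#'
#' Single-tract counties signal a `segmetals_excluded_county` condition
#' (the index is degenerate there, not an internal failure); a zero county
#' total for either group signals `segmetals_undefined_index` naming the
#' group, since both denominators of D must be positive.
#' @export
#' @examples
#' tr <- data.frame(tract_id = c("a", "b"), county_id = "01001",
#'                  NHB = c(90, 10), NHW = c(10, 90))
#' dissimilarity_index(tr, "01001", "NHB", "NHW")$di  # 0.8
dissimilarity_index <- function(tracts, county_id,
                                minority_group = "NHB",
                                reference_group = "NHW") {
  for (g in c(minority_group, reference_group)) {
    if (!g %in% names(tracts)) {
      sm_abort(paste0("group column '", g, "' not present in tract table"),
               "segmetals_config_error")
    }
  }
  ct <- tracts[tracts$county_id == county_id, , drop = FALSE]
  if (nrow(ct) == 0) {
    sm_abort(paste0("county ", county_id, " not present in tract table"),
             "segmetals_config_error")
  }
  if (nrow(ct) < 2) {
    sm_abort(paste0("county ", county_id, " has a single census tract and ",
                    "is excluded from the segregation analysis"),
             "segmetals_excluded_county")
  }
  x <- ct[[minority_group]]
  y <- ct[[reference_group]]
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) {
    zero <- if (X <= 0) minority_group else reference_group
    sm_abort(paste0("dissimilarity index undefined for county ", county_id,
                    ": total ", zero, " population is zero"),
             "segmetals_undefined_index")
  }
  di <- 0.5 * sum(abs(x / X - y / Y))
  data.frame(
    county_id = county_id,
    period = if ("period" %in% names(ct)) ct$period[1] else NA_character_,
    minority_group = minority_group,
    reference_group = reference_group,
    di = di,
    n_tracts = nrow(ct),
    minority_total = X,
    reference_total = Y
  )
}

#' Classify a dissimilarity index into a segregation category
#'
#' Fixed thresholds follow the conventional reading of county segregation:
#' well integrated for DI in \[0, 0.3), moderately segregated in
#' \[0.3, 0.6), highly segregated in \[0.6, 1\]. Intervals are left-closed
#' (right-closed at the top) so every DI maps to exactly one category. The
#' `"tertiles"` scheme instead cuts at the empirical 33.3/66.7 percentiles
#' of a reference DI distribution, for sensitivity analyses.
#'
#' @param di numeric vector of dissimilarity indices in \[0, 1\].
#' @param scheme `"fixed_thresholds"` or `"tertiles"`.
#' @param reference_dis DI values defining the tertile cut points (required
#'   for `"tertiles"`).
#' @return Factor with levels `well_integrated`, `moderately_segregated`,
#'   `highly_segregated`.
#' @export
#' @examples
#' categorize_rrs(c(0.1, 0.3, 0.6, 1.0))
categorize_rrs <- function(di, scheme = c("fixed_thresholds", "tertiles"),
                           reference_dis = NULL) {
  scheme <- match.arg(scheme)
  if (any(is.na(di)) || any(di < 0 | di > 1)) {
    sm_abort("di values must lie in [0, 1]", "segmetals_domain_error")
  }
  lv <- c("well_integrated", "moderately_segregated", "highly_segregated")
  cuts <- if (scheme == "fixed_thresholds") {
    c(0.3, 0.6)
  } else {
    if (length(reference_dis) == 0) {
      sm_abort("tertiles scheme requires non-empty reference_dis",
               "segmetals_config_error")
    }
    stats::quantile(reference_dis, c(1, 2) / 3, names = FALSE)
  }
  idx <- 1L + (di >= cuts[1]) + (di >= cuts[2])
  factor(lv[idx], levels = lv)
}

#' Dissimilarity index for every county and minority group
#'
#' Evaluates [dissimilarity_index()] for each county in the tract table
#' crossed with each requested minority group against a common reference
#' group. Counties the index cannot serve (single tract, or a zero group
#' total) are tabulated with a status instead of failing the run.
#'
#' @param tracts tract demographic table.
#' @param minority_groups character vector of minority group columns.
#' @param reference_group reference group column (default NHW).
#' @return Data.frame with one row per county x minority group:
#'   the [dissimilarity_index()] fields plus `status`
#'   (`"ok"`, `"excluded_single_tract"`, `"undefined_index"`) and `reason`.
#' @export
di_all_pairs <- function(tracts, minority_groups, reference_group = "NHW") {
  for (g in c(minority_groups, reference_group)) {
    if (!g %in% names(tracts)) {
      sm_abort(paste0("unknown group label '", g, "'"),
               "segmetals_config_error")
    }
  }
  counties <- unique(tracts$county_id)
  rows <- list()
  for (cid in counties) {
    for (g in minority_groups) {
      res <- tryCatch(
        cbind(dissimilarity_index(tracts, cid, g, reference_group),
              status = "ok", reason = NA_character_),
        segmetals_excluded_county = function(e) data.frame(
          county_id = cid, period = NA_character_, minority_group = g,
          reference_group = reference_group, di = NA_real_,
          n_tracts = sum(tracts$county_id == cid),
          minority_total = NA_real_, reference_total = NA_real_,
          status = "excluded_single_tract", reason = conditionMessage(e)
        ),
        segmetals_undefined_index = function(e) data.frame(
          county_id = cid, period = NA_character_, minority_group = g,
          reference_group = reference_group, di = NA_real_,
          n_tracts = sum(tracts$county_id == cid),
          minority_total = NA_real_, reference_total = NA_real_,
          status = "undefined_index", reason = conditionMessage(e)
        )
      )
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
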