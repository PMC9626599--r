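#' Percent change in concentration per 10\% increase in DI
#'
#' Converts a log-log elasticity into the percent change in concentration
#' associated with a 10\% (multiplicative, x1.1) increase in the
#' dissimilarity index: \eqn{(1.1^\beta - 1) \times 100}. The elasticity is
#' invariant to the logarithm base used in fitting, so this map is too.
#'
#' @param beta elasticity (slope of log concentration on log DI).
#' @return Percent change (numeric, vectorised).
#' @export
#' @examples
#' pct_change_per_10pct_di(c(0, 1, 2))  # 0, 10, 21
pct_change_per_10pct_di <- function(beta) {
  (1.1^beta - 1) * 100
}

#' Log-log association between segregation and concentration
#'
#' Ordinary least squares of log concentration on log DI across counties,
#' optionally stratified by urban classification and adjusted for region
#' fixed effects and/or log-transformed racial-composition covariates.
#' The slope is the elasticity \eqn{\beta}; it is reported together with
#' the percent change per 10\% DI increase, \eqn{(1.1^\beta - 1) \times
#' 100}, whose CI is obtained by the same monotone transform of the slope
#' CI endpoints. Counties with non-positive DI or concentration are
#' excluded with a notice (their logs are undefined).
#'
#' @param data data.frame with one row per county: `concentration`, `di`,
#'   and as needed `urban` (logical), `region`, `pct_nhb`, `pct_nhw`.
#' @param covariates any of `"region_fixed_effects"`, `"log_pct_nhb"`,
#'   `"log_pct_nhw"`. Region fixed effects are one-hot with the
#'   alphabetically first region as baseline; the percent-composition
#'   covariates enter log-transformed by default so their coefficients
#'   convert by the same per-10\% map.
#' @param stratum `"all"`, `"urban"` or `"rural"` (requires `urban`).
#' @param component label recorded in the output row.
#' @param conf_level confidence level for the slope CI.
#' @param robust use heteroskedasticity-robust (HC1) standard errors
#'   instead of the classical OLS ones.
#' @param log_composition if `FALSE`, enter `pct_nhb`/`pct_nhw` on the raw
#'   percent scale instead of log-transformed.
#' @return One-row data.frame: `component`, `stratum`, `covariates`,
#'   `beta`, `slope_se`, `pct_per_10pct_di`, `ci_low`, `ci_high` (percent
#'   scale), `p_value`, `n_counties`, `n_excluded`; the fitted `lm` object
#'   is in attribute `"fit"`.
#' @export
fit_loglog <- function(data, covariates = character(),
                       stratum = c("all", "urban", "rural"),
                       component = NA_character_, conf_level = 0.95,
                       robust = FALSE, log_composition = TRUE) {
  stratum <- match.arg(stratum)
  known <- c("region_fixed_effects", "log_pct_nhb", "log_pct_nhw")
  if (!all(covariates %in% known)) {
    sm_abort(paste0("unknown covariate: ",
                    paste(setdiff(covariates, known), collapse = ", ")),
             "segmetals_config_error")
  }
  d <- data
  if (stratum != "all") {
    if (!"urban" %in% names(d)) {
      sm_abort("stratified fit requires an 'urban' column",
               "segmetals_config_error")
    }
    d <- d[if (stratum == "urban") d$urban %in% TRUE else !(d$urban %in% TRUE),
           , drop = FALSE]
  }
  usable <- is.finite(d$concentration) & is.finite(d$di) &
    d$concentration > 0 & d$di > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    message("fit_loglog: excluded ", n_excluded,
            " counties with non-positive DI or concentration")
  }
  d <- d[usable, , drop = FALSE]
  terms <- "log(di)"
  if ("region_fixed_effects" %in% covariates) {
    d$region <- factor(d$region, levels = sort(unique(d$region)))
    terms <- c(terms, "region")
  }
  for (cv in c("log_pct_nhb", "log_pct_nhw")) {
    if (cv %in% covariates) {
      col <- sub("^log_", "", cv)
      if (!col %in% names(d)) {
        sm_abort(paste0("covariate column '", col, "' missing"),
                 "segmetals_config_error")
      }
      if (log_composition) {
        keep <- d[[col]] > 0
        if (any(!keep)) {
          message("fit_loglog: excluded ", sum(!keep),
                  " counties with non-positive ", col)
          n_excluded <- n_excluded + sum(!keep)
          d <- d[keep, , drop = FALSE]
        }
        terms <- c(terms, paste0("log(", col, ")"))
      } else {
        terms <- c(terms, col)
      }
    }
  }
  fml <- stats::as.formula(paste("log(concentration) ~",
                                 paste(terms, collapse = " + ")))
  n_par <- 2L + ("region_fixed_effects" %in% covariates) *
    max(0L, length(unique(d$region)) - 1L) +
    sum(c("log_pct_nhb", "log_pct_nhw") %in% covariates)
  if (nrow(d) < 3 || nrow(d) <= n_par) {
    sm_abort(paste0("insufficient data: ", nrow(d), " usable counties for ",
                    n_par, " parameters"), "segmetals_insufficient_data")
  }
  fit <- stats::lm(fml, data = d)
  vc <- if (robust) sandwich_hc1(fit) else stats::vcov(fit)
  beta <- stats::coef(fit)[["log(di)"]]
  se <- sqrt(vc["log(di)", "log(di)"])
  df <- fit$df.residual
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  alpha <- 1 - conf_level
  half <- stats::qt(1 - alpha / 2, df) * se
  out <- data.frame(
    component = component, stratum = stratum,
    covariates = if (length(covariates)) paste(covariates, collapse = "+")
                 else "none",
    beta = beta, slope_se = se,
    pct_per_10pct_di = pct_change_per_10pct_di(beta),
    ci_low = pct_change_per_10pct_di(beta - half),
    ci_high = pct_change_per_10pct_di(beta + half),
    p_value = p, n_counties = nrow(d), n_excluded = n_excluded
  )
  attr(out, "fit") <- fit
  out
}

# HC1 heteroskedasticity-robust covariance (delegates to sandwich).
#' @noRd
sandwich_hc1 <- function(fit) {
  if (!requireNamespace("sandwich", quietly = TRUE)) {
    sm_abort("robust = TRUE requires the sandwich package",
             "segmetals_config_error")
  }
  sandwich::vcovHC(fit, type = "HC1")
}
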