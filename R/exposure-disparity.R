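#' Population-weighted mean exposure for one segregation category
#'
#' \deqn{Y_i = \frac{\sum_j P_j x_j}{\sum_j P_j}}
#' over the counties in category \eqn{i}, where \eqn{P_j} is the total
#' population of county \eqn{j} and \eqn{x_j} its annual mean concentration
#' or mass proportion. The result is always bounded by the minimum and
#' maximum county value.
#'
#' @param records data.frame of county weight records: `county_id`,
#'   `population` (> 0), `rrs_category`, `x` (the exposure value).
#' @param category category label to average.
#' @return The scalar population-weighted mean.
#' @export
#' @examples
#' r <- data.frame(county_id = 1:2, population = c(100, 300),
#'                 rrs_category = "highly_segregated", x = c(2, 6))
#' population_weighted_mean(r, "highly_segregated")  # 5
population_weighted_mean <- function(records, category) {
  sub <- records[records$rrs_category == category, , drop = FALSE]
  if (nrow(sub) == 0) {
    sm_abort(paste0("no counties in category '", category, "'"),
             "segmetals_insufficient_data")
  }
  if (any(sub$population <= 0)) {
    sm_abort("county populations must be positive", "segmetals_domain_error")
  }
  sum(sub$population * sub$x) / sum(sub$population)
}

#' Relative disparity: coefficient of variation of category means
#'
#' \deqn{RD = \sqrt{Var(Y)} / \mu(Y)} over the vector of per-category
#' population-weighted means. Being scale-free, RD compares disparities
#' between components and years independently of their magnitudes; RD = 0
#' means perfect equality across segregation levels. By default `Var` is
#' the population variance (divide by K, the number of categories); the
#' sample variance (divide by K - 1) is available by switch and rescales
#' RD by sqrt(K/(K-1)).
#'
#' @param category_means numeric vector of per-category means (>= 2 values,
#'   positive mean).
#' @param var_type `"population"` (divide by K) or `"sample"` (K - 1).
#' @return The scalar relative disparity, with the variance convention in
#'   attribute `"var_type"`.
#' @export
#' @examples
#' relative_disparity(c(1, 2, 3))  # 0.40825
relative_disparity <- function(category_means,
                               var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  k <- length(category_means)
  if (k < 2) sm_abort("relative disparity needs >= 2 category means",
                      "segmetals_insufficient_data")
  if (any(!is.finite(category_means))) {
    sm_abort("category means must be finite", "segmetals_domain_error")
  }
  mu <- mean(category_means)
  if (mu <= 0) sm_abort("mean of category means must be positive",
                        "segmetals_domain_error")
  v <- sum((category_means - mu)^2) / if (var_type == "population") k else k - 1
  structure(sqrt(v) / mu, var_type = var_type)
}

#' Ratio of category mean exposures with a stratified bootstrap CI
#'
#' Point estimate is the mean exposure of category `cat_a` divided by that
#' of `cat_b`, either unweighted across counties or population-weighted.
#' The CI resamples counties with replacement independently within each
#' category at its observed size (percentile 2.5/97.5).
#'
#' @param records county weight records as for [population_weighted_mean()].
#' @param cat_a,cat_b category labels (numerator, denominator).
#' @param weighting `"unweighted"` or `"population"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return List: `ratio`, `ci_low`, `ci_high`, `n_a`, `n_b`.
#' @export
ratio_of_category_means <- function(records, cat_a, cat_b,
                                    weighting = c("unweighted", "population"),
                                    n_boot = 1000, seed = 1) {
  weighting <- match.arg(weighting)
  a <- records[records$rrs_category == cat_a, , drop = FALSE]
  b <- records[records$rrs_category == cat_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    sm_abort("both categories must be non-empty",
             "segmetals_insufficient_data")
  }
  cmean <- function(d, idx = seq_len(nrow(d))) {
    if (weighting == "unweighted") mean(d$x[idx]) else
      sum(d$population[idx] * d$x[idx]) / sum(d$population[idx])
  }
  mb <- cmean(b)
  if (mb == 0) sm_abort("denominator category mean is zero",
                        "segmetals_domain_error")
  ratio <- cmean(a) / mb
  reps <- with_stream(stream_seed(seed, "cat_ratio", cat_a, cat_b), {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(nrow(a), nrow(a), replace = TRUE)
      ib <- sample.int(nrow(b), nrow(b), replace = TRUE)
      cmean(a, ia) / cmean(b, ib)
    }, numeric(1))
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  list(ratio = ratio, ci_low = ci[1], ci_high = ci[2],
       n_a = nrow(a), n_b = nrow(b))
}

#' Stratified bootstrap confidence interval for the relative disparity
#'
#' Each replicate resamples counties with replacement independently within
#' each segregation category (at the observed per-category size unless
#' overridden), recomputes the population-weighted category means and then
#' the relative disparity; the CI is the percentile 2.5/97.5 of the
#' replicate distribution. Deterministic given the seed.
#'
#' @param records county weight records as for [population_weighted_mean()].
#' @param n_boot bootstrap replicates (10,000 by default).
#' @param stratum_sizes optional named per-category resample sizes; defaults
#'   to the observed county counts.
#' @param seed integer seed.
#' @param var_type variance convention passed to [relative_disparity()].
#' @return List: `ci_low`, `ci_high`, `rd` (the point estimate), `n_boot`,
#'   `seed`, `stratum_sizes`, and `replicates` (the bootstrap rd values).
#' @export
bootstrap_rd_ci <- function(records, n_boot = 10000, stratum_sizes = NULL,
                            seed = 1, var_type = "population") {
  cats <- sort(unique(as.character(records$rrs_category)))
  if (length(cats) < 2) {
    sm_abort("need >= 2 non-empty categories for a disparity CI",
             "segmetals_insufficient_data")
  }
  split_px <- lapply(cats, function(cc) {
    s <- records[records$rrs_category == cc, , drop = FALSE]
    if (nrow(s) == 0) sm_abort(paste0("category '", cc, "' has no counties"),
                               "segmetals_insufficient_data")
    list(p = s$population, x = s$x)
  })
  names(split_px) <- cats
  sizes <- vapply(split_px, function(s) length(s$x), integer(1))
  if (!is.null(stratum_sizes)) {
    sizes[names(stratum_sizes)] <- as.integer(stratum_sizes)
  }
  point <- relative_disparity(
    vapply(cats, function(cc) population_weighted_mean(records, cc),
           numeric(1)),
    var_type = var_type
  )
  ymat <- with_stream(stream_seed(seed, "rd_boot"), {
    vapply(cats, function(cc) {
      s <- split_px[[cc]]
      m <- sizes[[cc]]
      idx <- matrix(sample.int(length(s$x), m * n_boot, replace = TRUE),
                    nrow = m)
      colSums(matrix(s$p[idx] * s$x[idx], nrow = m)) /
        colSums(matrix(s$p[idx], nrow = m))
    }, numeric(n_boot))
  })
  mu <- rowMeans(ymat)
  k <- length(cats)
  denom <- if (var_type == "population") k else k - 1
  rd_reps <- sqrt(rowSums((ymat - mu)^2) / denom) / mu
  ci <- stats::quantile(rd_reps, c(0.025, 0.975), names = FALSE)
  list(ci_low = ci[1], ci_high = ci[2], rd = as.numeric(point),
       n_boot = n_boot, seed = seed, stratum_sizes = sizes,
       replicates = rd_reps)
}

#' Disparity summary for one component, year and exposure mode
#'
#' Convenience wrapper producing one summary row: per-category
#' population-weighted means, the relative disparity, and its stratified
#' bootstrap CI.
#'
#' @param records county weight records as for [population_weighted_mean()].
#' @param component,year,mode labels recorded in the output.
#' @param n_boot,seed,var_type passed to [bootstrap_rd_ci()].
#' @return One-row data.frame: `component`, `year`, `mode`, one
#'   `mean_<category>` column per category, `rd`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `var_type`.
#' @export
disparity_summary <- function(records, component, year,
                              mode = c("concentration", "mass_proportion"),
                              n_boot = 10000, seed = 1,
                              var_type = "population") {
  mode <- match.arg(mode)
  cats <- sort(unique(as.character(records$rrs_category)))
  means <- vapply(cats, function(cc) population_weighted_mean(records, cc),
                  numeric(1))
  ci <- bootstrap_rd_ci(records, n_boot = n_boot, seed = seed,
                        var_type = var_type)
  out <- data.frame(component = component, year = year, mode = mode,
                    rd = ci$rd, ci_low = ci$ci_low, ci_high = ci$ci_high,
                    n_boot = n_boot, seed = seed, var_type = var_type)
  for (cc in cats) out[[paste0("mean_", cc)]] <- means[[cc]]
  out
}
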