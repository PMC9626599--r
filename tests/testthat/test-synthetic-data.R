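# Synthetic-data generator: tract mosaics and monitor time series.

small_scenario <- function(...) {
  args <- list(n_counties = 3, tracts_per_county = 4,
               county_population = 4000, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_scenario, args)
}

test_that("scenario validation rejects out-of-range knobs", {
  expect_error(small_scenario(mixing_theta = 1.2),
               class = "segmetals_invalid_scenario")
  expect_error(small_scenario(missing_rate = -0.1),
               class = "segmetals_invalid_scenario")
  expect_error(small_scenario(county_population = 0),
               class = "segmetals_invalid_scenario")
  expect_error(small_scenario(sigma_annual = -1),
               class = "segmetals_invalid_scenario")
  expect_error(synthetic_scenario(groups = c("NHW", "Hispanic"),
                                  group_shares = c(NHW = 0.5, Hispanic = 0.5)),
               class = "segmetals_invalid_scenario")
  expect_error(small_scenario(tracts_per_county = 0),
               class = "segmetals_invalid_scenario")
})

test_that("tract mosaics hit both ends of the DI range and are monotone in theta", {
  # theta = 0: every tract mirrors the county proportions, DI exactly 0
  tr0 <- generate_tracts(small_scenario(mixing_theta = 0))
  for (cid in unique(tr0$county_id)) {
    expect_identical(dissimilarity_index(tr0, cid, "NHB", "NHW")$di, 0)
  }
  # theta = 1, 2 tracts: disjoint occupancy, DI exactly 1
  tr1 <- generate_tracts(synthetic_scenario(
    n_counties = 1, tracts_per_county = 2, county_population = 1000,
    mixing_theta = 1, seed = 11))
  expect_identical(dissimilarity_index(tr1, "00001", "NHB", "NHW")$di, 1)
  # theta grid: realized DI non-decreasing
  thetas <- c(0, 0.25, 0.5, 0.75, 1)
  dis <- vapply(thetas, function(th) {
    tr <- generate_tracts(synthetic_scenario(
      n_counties = 1, tracts_per_county = 8, county_population = 20000,
      mixing_theta = th, seed = 11))
    dissimilarity_index(tr, "00001", "NHB", "NHW")$di
  }, numeric(1))
  expect_true(all(diff(dis) >= 0))
  # continuum construction puts DI close to theta itself
  expect_lt(max(abs(dis - thetas)), 0.01)
})

test_that("county group totals are positive and tracts are deterministic", {
  sc <- small_scenario()
  tr <- generate_tracts(sc)
  totals <- aggregate(tr[c("NHB", "NHW")], by = list(tr$county_id), sum)
  expect_true(all(totals$NHB > 0 & totals$NHW > 0))
  expect_identical(tr, generate_tracts(sc))
  expect_error(generate_tracts(small_scenario(tracts_per_county = 1)),
               class = "segmetals_invalid_scenario")
  expect_silent(tr1 <- generate_tracts(small_scenario(tracts_per_county = 1),
                                       allow_single_tract = TRUE))
  expect_identical(nrow(tr1), 3L)
})

test_that("regenerating monitor records with the same seed is byte-identical", {
  sc <- small_scenario(components = c("Pb", "PM25"),
                       alpha_m = c(Pb = log(5), PM25 = log(12)),
                       beta_m = c(Pb = 0.9, PM25 = 0.5),
                       mdl = c(Pb = 0.3, PM25 = 0.5))
  di <- c("00001" = 0.2, "00002" = 0.5, "00003" = 0.8)
  g1 <- generate_monitor_records(sc, di)
  g2 <- generate_monitor_records(sc, di)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$table, g2$truth$table)
  # truth covers every county-component pair
  expect_identical(nrow(g1$truth$table), 6L)
})

test_that("zero DI triggers a domain error naming the county unless dropped", {
  sc <- small_scenario(components = "Pb", alpha_m = c(Pb = 1),
                       beta_m = c(Pb = 1), mdl = c(Pb = 0.3))
  di <- c("00001" = 0.4, "00002" = 0, "00003" = 0.6)
  expect_error(generate_monitor_records(sc, di), "00002",
               class = "segmetals_zero_di")
  g <- generate_monitor_records(sc, di, zero_di = "drop")
  expect_setequal(unique(g$records$county_id), c("00001", "00003"))
})

test_that("full schedule yields >= 121 records that pass the completeness filter", {
  sc <- small_scenario(components = "Pb", alpha_m = c(Pb = 1),
                       beta_m = c(Pb = 1), mdl = c(Pb = 0.3),
                       missing_rate = 0)
  g <- generate_monitor_records(sc, c("00001" = 0.3, "00002" = 0.5,
                                      "00003" = 0.7))
  counts <- table(g$records$monitor_id)
  expect_true(all(counts >= 121))
  mm <- annual_monitor_mean(filter_valid(g$records), 2019)
  expect_true(all(mm$retained))
})

test_that("completeness failures under heavy missingness match the binomial tail", {
  # 200 monitors on a 122-day schedule, each day kept w.p. 0.4: a monitor
  # fails the strict >50%-of-121 rule iff it keeps <= 60 samples
  sc <- synthetic_scenario(n_counties = 1, tracts_per_county = 4,
                           county_population = 4000, mixing_theta = 0.5,
                           components = "Pb", alpha_m = c(Pb = 1),
                           beta_m = c(Pb = 1), mdl = c(Pb = 0.3),
                           missing_rate = 0.6, monitors_per_county = 200,
                           seed = 101)
  g <- generate_monitor_records(sc, c("00001" = 0.5))
  mm <- annual_monitor_mean(filter_valid(g$records), 2019)
  expect_identical(nrow(mm), 200L)
  p_fail <- pbinom(60, 122, 0.4)
  se <- sqrt(p_fail * (1 - p_fail) / 200)
  expect_lt(abs(mean(!mm$retained) - p_fail), 3 * se + 1e-12)
})

test_that("noiseless generator reproduces the planted log-linear model exactly", {
  sc <- small_scenario(components = "Pb", alpha_m = c(Pb = log(4)),
                       beta_m = c(Pb = 1), mdl = c(Pb = 0.3),
                       sigma_annual = 0, sigma_daily = 0, missing_rate = 0)
  di <- c("00001" = 0.25, "00002" = 0.5, "00003" = 0.75)
  g <- generate_monitor_records(sc, di)
  mm <- annual_monitor_mean(filter_valid(g$records), 2019)
  # region offsets still apply; compare against the full planted mean
  expected <- exp(log(4) + log(di) + sc$region_effects[
    rep_len(names(sc$region_effects), 3)])
  expect_equal(mm$mean_concentration[order(mm$county_id)],
               unname(expected), tolerance = 1e-12)
})

test_that("below-MDL fraction converges to the lognormal CDF at the MDL", {
  mdl <- 2.5
  sc <- synthetic_scenario(n_counties = 1, tracts_per_county = 4,
                           county_population = 4000, mixing_theta = 0.5,
                           components = "Pb", alpha_m = c(Pb = log(3)),
                           beta_m = c(Pb = 0.9), mdl = c(Pb = mdl),
                           sigma_daily = 0.5, missing_rate = 0,
                           monitors_per_county = 30, seed = 7)
  g <- generate_monitor_records(sc, c("00001" = 0.5))
  mu <- g$truth$table$true_annual_mean[1]
  p <- plnorm(mdl, meanlog = log(mu) - sc$sigma_daily^2 / 2,
              sdlog = sc$sigma_daily)
  frac <- mean(g$records$concentration < mdl)
  n <- nrow(g$records)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the sampling calendar is every third day, ~122 scheduled days", {
  cal <- sampling_calendar(2019)
  expect_identical(length(cal), 122L)
  expect_true(all(diff(as.integer(cal)) == 3))
  expect_identical(length(sampling_calendar(2020)), 122L)
})

test_that("the dataset writer round-trips through CSV", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(small_scenario(
    components = "Pb", alpha_m = c(Pb = 1), beta_m = c(Pb = 1),
    mdl = c(Pb = 0.3)), dir)
  tr <- read.csv(paths$tracts, colClasses = c(county_id = "character"))
  expect_identical(nrow(tr), 12L)
  rec <- read.csv(paths$monitor_records,
                  colClasses = c(county_id = "character"))
  expect_true(all(c("monitor_id", "date", "concentration", "mdl") %in%
                    names(rec)))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_identical(length(truth$table$county_id), 3L)
})
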