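# Population-weighted means, relative disparity, stratified bootstrap.

test_that("population-weighted mean follows the weighted-sum definition", {
  r <- make_weight_records(c(2, 6), population = c(100, 300))
  expect_equal(population_weighted_mean(r, "highly_segregated"), 5)
  # equal populations reduce to the arithmetic mean
  r2 <- make_weight_records(c(1, 4, 7), population = c(10, 10, 10))
  expect_equal(population_weighted_mean(r2, "highly_segregated"), 4)
  # single county: the weight cancels
  r3 <- make_weight_records(3.7, population = 12345)
  expect_equal(population_weighted_mean(r3, "highly_segregated"), 3.7)
  expect_error(population_weighted_mean(r, "well_integrated"),
               "well_integrated", class = "segmetals_insufficient_data")
})

test_that("population-weighted mean is bounded and split-invariant", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    r <- make_weight_records(runif(n, 0, 5),
                             population = sample(1:1000, n))
    y <- population_weighted_mean(r, "highly_segregated")
    expect_gte(y, min(r$x)); expect_lte(y, max(r$x))
    # splitting one county into two with the same x leaves Y unchanged
    j <- sample(n, 1)
    p1 <- r$population[j] %/% 2; p2 <- r$population[j] - p1
    if (p1 > 0) {
      split <- rbind(r[-j, ],
                     data.frame(county_id = c("a", "b"),
                                population = c(p1, p2),
                                rrs_category = "highly_segregated",
                                x = r$x[j]))
      expect_equal(population_weighted_mean(split, "highly_segregated"), y,
                   tolerance = 1e-12)
    }
  }
})

test_that("relative disparity is the population-SD coefficient of variation", {
  rd <- relative_disparity(c(1, 2, 3))
  expect_equal(as.numeric(rd), sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(as.numeric(rd), 5), 0.40825)
  expect_identical(as.numeric(relative_disparity(c(4, 4, 4))), 0)
  # scale invariance
  expect_equal(as.numeric(relative_disparity(7 * c(1, 2, 3))),
               as.numeric(rd), tolerance = 1e-12)
  # sample-variance switch rescales by sqrt(K/(K-1))
  expect_equal(as.numeric(relative_disparity(c(1, 2, 3), "sample")),
               as.numeric(rd) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(relative_disparity(5), class = "segmetals_insufficient_data")
  expect_error(relative_disparity(c(-2, -1, 0)),
               class = "segmetals_domain_error")
})

test_that("relative disparity increases under a mean-preserving spread", {
  spreads <- seq(0, 1.5, by = 0.25)
  rds <- vapply(spreads,
                function(d) as.numeric(relative_disparity(c(2 - d, 2, 2 + d))),
                numeric(1))
  expect_true(all(diff(rds) > 0))
})

test_that("ratio of category means and its stratified bootstrap", {
  r <- rbind(make_weight_records(c(9, 10, 11), category = "highly_segregated"),
             make_weight_records(c(1, 2, 3), category = "well_integrated"))
  out <- ratio_of_category_means(r, "highly_segregated", "well_integrated",
                                 n_boot = 400, seed = 5)
  expect_equal(out$ratio, 5)
  # symmetric categories: ratio 1, CI straddles 1
  r2 <- rbind(make_weight_records(c(1, 2, 3), category = "highly_segregated"),
              make_weight_records(c(1, 2, 3), category = "well_integrated"))
  out2 <- ratio_of_category_means(r2, "highly_segregated", "well_integrated",
                                  n_boot = 400, seed = 5)
  expect_equal(out2$ratio, 1)
  expect_true(out2$ci_low <= 1 && 1 <= out2$ci_high)
  # population weighting changes the estimate accordingly
  r3 <- rbind(make_weight_records(c(2, 6), population = c(100, 300),
                                  category = "highly_segregated"),
              make_weight_records(1, category = "well_integrated"))
  out3 <- ratio_of_category_means(r3, "highly_segregated", "well_integrated",
                                  weighting = "population",
                                  n_boot = 100, seed = 5)
  expect_equal(out3$ratio, 5)
  expect_error(
    ratio_of_category_means(r3, "highly_segregated", "missing_cat"),
    class = "segmetals_insufficient_data"
  )
})

test_that("bootstrap RD CI is deterministic and collapses without spread", {
  r <- rbind(make_weight_records(c(1, 1, 1), category = "well_integrated"),
             make_weight_records(c(1, 1), category = "highly_segregated"))
  ci <- bootstrap_rd_ci(r, n_boot = 200, seed = 9)
  expect_identical(c(ci$ci_low, ci$ci_high), c(0, 0))

  set.seed(33)
  r2 <- rbind(
    make_weight_records(rlnorm(15, log(2), 0.3), population = runif(15, 1, 9),
                        category = "well_integrated"),
    make_weight_records(rlnorm(25, log(5), 0.3), population = runif(25, 1, 9),
                        category = "moderately_segregated"),
    make_weight_records(rlnorm(10, log(9), 0.3), population = runif(10, 1, 9),
                        category = "highly_segregated")
  )
  ci_a <- bootstrap_rd_ci(r2, n_boot = 500, seed = 4)
  ci_b <- bootstrap_rd_ci(r2, n_boot = 500, seed = 4)
  expect_identical(ci_a$replicates, ci_b$replicates)
  expect_identical(c(ci_a$ci_low, ci_a$ci_high), c(ci_b$ci_low, ci_b$ci_high))
  expect_true(ci_a$ci_low < ci_a$rd && ci_a$rd < ci_a$ci_high)
  # shrinking within-category spread tightens the replicate distribution
  shrink <- function(s) {
    set.seed(33)
    rr <- rbind(
      make_weight_records(rlnorm(15, log(2), s), category = "well_integrated"),
      make_weight_records(rlnorm(25, log(5), s),
                          category = "moderately_segregated"),
      make_weight_records(rlnorm(10, log(9), s),
                          category = "highly_segregated")
    )
    ci <- bootstrap_rd_ci(rr, n_boot = 500, seed = 4)
    ci$ci_high - ci$ci_low
  }
  widths <- vapply(c(0.4, 0.1, 0.01), shrink, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 0.01)
})

test_that("stratum sizes default to observed counts and can be overridden", {
  set.seed(8)
  r <- rbind(make_weight_records(rlnorm(12), category = "well_integrated"),
             make_weight_records(rlnorm(30), category = "highly_segregated"))
  ci <- bootstrap_rd_ci(r, n_boot = 100, seed = 2)
  expect_identical(unname(ci$stratum_sizes[sort(names(ci$stratum_sizes))]),
                   c(30L, 12L))
  ci2 <- bootstrap_rd_ci(r, n_boot = 100, seed = 2,
                         stratum_sizes = c(well_integrated = 5))
  expect_identical(unname(ci2$stratum_sizes[["well_integrated"]]), 5L)
  one_cat <- make_weight_records(rlnorm(5))
  expect_error(bootstrap_rd_ci(one_cat, n_boot = 50, seed = 1),
               class = "segmetals_insufficient_data")
})

test_that("disparity_summary assembles category means and the CI", {
  set.seed(12)
  r <- rbind(make_weight_records(rlnorm(10, log(2), 0.2),
                                 category = "well_integrated"),
             make_weight_records(rlnorm(10, log(8), 0.2),
                                 category = "highly_segregated"))
  s <- disparity_summary(r, "Pb", 2019, "concentration", n_boot = 200,
                         seed = 6)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_well_integrated,
               population_weighted_mean(r, "well_integrated"))
  expect_equal(s$rd, as.numeric(relative_disparity(
    c(population_weighted_mean(r, "well_integrated"),
      population_weighted_mean(r, "highly_segregated")))))
})
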