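# Independent oracles and fixture builders shared across test files.

# Brute-force dissimilarity index in exact integer arithmetic:
# D = sum(|x_i * Y - y_i * X|) / (2 * X * Y). All quantities are integers
# well below 2^53, so the double-precision evaluation is exact.
di_oracle <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  stopifnot(X > 0, Y > 0)
  sum(abs(x * Y - y * X)) / (2 * X * Y)
}

# Naive double-summation Moran's I (the definition, evaluated literally).
moran_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- sum(W)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) acc <- acc + W[i, j] * z[i] * z[j]
  }
  (n / s0) * acc / sum(z^2)
}

# A random small county: n_tracts tracts, integer populations <= pop_max,
# guaranteed positive group totals.
random_small_county <- function(n_tracts = sample(2:5, 1), pop_max = 20) {
  repeat {
    x <- sample(0:pop_max, n_tracts, replace = TRUE)
    y <- sample(0:pop_max, n_tracts, replace = TRUE)
    if (sum(x) > 0 && sum(y) > 0) {
      return(data.frame(tract_id = as.character(seq_len(n_tracts)),
                        county_id = "99999", NHB = x, NHW = y))
    }
  }
}

# Manual spatial_weights object from a neighbour list (row-standardized).
manual_weights <- function(nb, ids = seq_along(nb)) {
  structure(list(
    ids = ids, nb = nb,
    w = lapply(nb, function(v) rep(1 / length(v), length(v))),
    k = NA_integer_, metric = "manual"
  ), class = "spatial_weights")
}

# 2x2 rook-contiguity grid: a bipartite graph on which a checkerboard
# pattern attains I = -1.
rook_2x2 <- function() manual_weights(list(c(2, 3), c(1, 4), c(1, 4), c(2, 3)))

# Daily record fixture: one monitor, one component, n distinct sampling
# days of the given year.
make_records <- function(n, concentration = 1, mdl = 0.5, valid = TRUE,
                         year = 2019, component = "Pb",
                         monitor_id = "00001-M01", county_id = "00001") {
  data.frame(
    monitor_id = monitor_id, county_id = county_id,
    date = as.Date(sprintf("%d-01-01", year)) + seq_len(n) - 1L,
    component = component,
    concentration = rep_len(concentration, n),
    mdl = rep_len(mdl, n),
    valid = rep_len(valid, n),
    urban = TRUE, region = "South", latitude = 35, longitude = -90,
    unit = if (component == "PM25") "ug/m3" else "ng/m3"
  )
}

# County weight records for the disparity functions.
make_weight_records <- function(x, population = rep(1, length(x)),
                                category = "highly_segregated") {
  data.frame(county_id = sprintf("%05d", seq_along(x)),
             population = population,
             rrs_category = rep_len(category, length(x)), x = x)
}
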