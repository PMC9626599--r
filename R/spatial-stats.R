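#' K-nearest-neighbour spatial weights on great-circle distance
#'
#' Each site's neighbours are its `k` nearest by haversine distance;
#' weights are row-standardized to 1/k. Neighbour sets may be asymmetric
#' (A nearest to B does not imply the converse), which is accepted for
#' Moran-type statistics. Distance ties are broken deterministically by
#' site order.
#'
#' @param coords data.frame or matrix with columns `latitude` and
#'   `longitude` (decimal degrees, WGS84).
#' @param k number of neighbours (must be < number of sites).
#' @param site_ids optional identifiers; default `1..n`.
#' @return An object of class `spatial_weights`: `ids`, `nb` (list of
#'   neighbour index vectors), `w` (matching weight vectors), `k`,
#'   `metric`.
#' @export
build_knn_weights <- function(coords, k = 8, site_ids = NULL) {
  coords <- as.data.frame(coords)
  if (!all(c("latitude", "longitude") %in% names(coords))) {
    sm_abort("coords must have latitude and longitude columns",
             "segmetals_config_error")
  }
  n <- nrow(coords)
  if (n <= k) sm_abort(paste0("k = ", k, " requires more than k sites (n = ",
                              n, ")"), "segmetals_parameter_error")
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180)) {
    sm_abort("coordinates out of range", "segmetals_domain_error")
  }
  ids <- site_ids %||% seq_len(n)
  dm <- geosphere::distm(cbind(coords$longitude, coords$latitude),
                         fun = geosphere::distHaversine)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))        # ties broken by site order
    ord <- ord[ord != i]
    nb[[i]] <- sort(ord[seq_len(k)])
  }
  structure(list(ids = ids, nb = nb,
                 w = replicate(n, rep(1 / k, k), simplify = FALSE),
                 k = k, metric = "haversine"),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: %d sites, k = %d nearest neighbours (%s), row-standardized\n",
              length(x$nb), x$k, x$metric))
  invisible(x)
}

# Dense row-standardized weight matrix (internal; used for fast permutation).
#' @noRd
weights_matrix <- function(weights) {
  n <- length(weights$nb)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, weights$nb[[i]]] <- weights$w[[i]]
  W
}

#' Global Moran's I with permutation inference
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij} z_i z_j}
#'   {\sum_i z_i^2}}
#' with \eqn{z} the mean-centered values and \eqn{S_0} the total weight.
#' The permutation p-value is one-sided (greater-or-equal) over random
#' relabelings of the values across sites, with the (r+1)/(n_perm+1)
#' estimator. Under the permutation null the expectation of I is
#' \eqn{-1/(n-1)}.
#'
#' @param values per-site numeric values (non-constant).
#' @param weights a [build_knn_weights()] object (or any
#'   `spatial_weights`).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return Object of class `moran_result`: `global_i`, `expected_i`,
#'   `p_permutation`, `n_permutations`, `seed`, `n`.
#' @export
moran_global <- function(values, weights, n_perm = 999, seed = 1) {
  n <- length(values)
  if (n != length(weights$nb)) {
    sm_abort("values and weights describe different numbers of sites",
             "segmetals_config_error")
  }
  if (stats::var(values) == 0) {
    sm_abort("Moran's I is undefined for constant values",
             "segmetals_degenerate_input")
  }
  W <- weights_matrix(weights)
  s0 <- sum(W)
  z <- values - mean(values)
  obs <- (n / s0) * sum(z * (W %*% z)) / sum(z^2)
  perm <- with_stream(stream_seed(seed, "moran_global"), {
    Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
    (n / s0) * colSums(Z * (W %*% Z)) / colSums(Z^2)
  })
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(list(global_i = obs, expected_i = -1 / (n - 1),
                 p_permutation = p, n_permutations = n_perm, seed = seed,
                 n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f under the null)\n",
              x$global_i, x$expected_i))
  cat(sprintf("  permutation p = %.4f (%d permutations, seed %d, n = %d)\n",
              x$p_permutation, x$n_permutations, x$seed, x$n))
  invisible(x)
}

#' Local Moran's I with conditional permutation and cluster labels
#'
#' \deqn{I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j}, \eqn{m_2 = \sum z^2 / n},
#' so that \eqn{\sum_i I_i = S_0 \cdot I_{global}}. Significance per site
#' is by conditional permutation: the site's own value is held fixed and
#' the remaining values are randomly assigned to its neighbours; the
#' p-value is one-sided in the direction of the observed statistic with
#' the (r+1)/(n_perm+1) estimator. Sites with p below `alpha` get a
#' cluster label from the sign pattern of (z_i, spatial lag of z_i):
#' HH, LL, HL or LH; others are "ns". No multiple-testing correction is
#' applied by default (descriptive use); `fdr = TRUE` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams moran_global
#' @param alpha per-site significance level for labelling.
#' @param fdr apply Benjamini-Hochberg adjustment before labelling.
#' @return Data.frame with one row per site: `site_id`, `local_i`,
#'   `z`, `lag_z`, `p_value`, `label` in HH/LL/HL/LH/ns.
#' @export
moran_local <- function(values, weights, n_perm = 999, seed = 1,
                        alpha = 0.05, fdr = FALSE) {
  n <- length(values)
  if (n != length(weights$nb)) {
    sm_abort("values and weights describe different numbers of sites",
             "segmetals_config_error")
  }
  if (stats::var(values) == 0) {
    sm_abort("local Moran's I is undefined for constant values",
             "segmetals_degenerate_input")
  }
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) sum(weights$w[[i]] * z[weights$nb[[i]]]),
                numeric(1))
  li <- z * lag / m2
  p <- with_stream(stream_seed(seed, "moran_local"), {
    vapply(seq_len(n), function(i) {
      k <- length(weights$nb[[i]])
      others <- z[-i]
      # n_perm random draws of k neighbour values from the n-1 others
      draws <- matrix(0, n_perm, k)
      for (r in seq_len(n_perm)) {
        draws[r, ] <- others[sample.int(n - 1, k)]
      }
      li_perm <- (z[i] / m2) * drop(draws %*% weights$w[[i]])
      if (li[i] >= 0) (sum(li_perm >= li[i]) + 1) / (n_perm + 1)
      else (sum(li_perm <= li[i]) + 1) / (n_perm + 1)
    }, numeric(1))
  })
  p_lab <- if (fdr) stats::p.adjust(p, "BH") else p
  lab <- ifelse(p_lab < alpha,
                paste0(ifelse(z > 0, "H", "L"), ifelse(lag > 0, "H", "L")),
                "ns")
  data.frame(site_id = weights$ids, local_i = li, z = z, lag_z = lag,
             p_value = p, label = lab)
}
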