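# Internal helpers: typed conditions and hierarchical RNG streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
sm_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "segmetals_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Derive a deterministic sub-stream seed from a master seed and key parts.
#'
#' Each (county, monitor, component) tuple gets its own stream so that adding
#' a component or county never perturbs the draws of the others. Plain
#' multiplicative hashing on a Mersenne prime, kept below 2^31 so the result
#' is always a valid R integer seed.
#' @noRd
stream_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG state.
#' @noRd
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Zero-padded 5-character FIPS-style county identifier.
#' @noRd
fips_id <- function(i) sprintf("%05d", as.integer(i))

#' Largest-remainder rounding: integer vector with the same sum as round(sum(x)).
#' Deterministic: ties broken by position.
#' @noRd
round_preserve_sum <- function(x) {
  stopifnot(all(x >= -1e-9))
  x <- pmax(x, 0)
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    frac <- x - fl
    take <- order(-frac, seq_along(x))[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}
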