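# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` means "use the current
# RNG stream" (no save/restore).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Canonicalize a word token into a node key
#'
#' Lower-cases the token and strips leading/trailing punctuation while keeping
#' internal hyphens and apostrophes, so that reoccurring words merge into a
#' single network node regardless of capitalization or attached punctuation
#' (e.g. \code{"Could"}, \code{"could,"} and \code{"could"} share one node).
#'
#' @param token Character vector of orthographic word tokens.
#' @return Character vector of canonical node keys.
#' @examples
#' canonicalize_token(c("Could", "day?", "re-entry", "rock's"))
#' @export
canonicalize_token <- function(token) {
  stopifnot(is.character(token))
  out <- tolower(token)
  out <- sub("^[[:punct:][:space:]]+", "", out)
  out <- sub("[[:punct:][:space:]]+$", "", out)
  out
}

# Truncated-normal draw via inverse CDF; vectorized, one uniform per value.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
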