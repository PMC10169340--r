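#' @import data.table
#' @importFrom stats approx isoreg median pchisq plogis pnorm ppoints ppois
#'   qlnorm qlogis qnorm qpois quantile rbinom rgamma rnorm rpois runif sd
#'   setNames uniroot var plnorm
#' @importFrom utils packageVersion head
#' @importFrom tools md5sum
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce and validate a two-date window
#'
#' Windows are closed on both ends at day resolution throughout the package.
#' @param w anything coercible to two `Date`s
#' @return a length-2 `Date` vector
#' @keywords internal
as_window <- function(w) {
  w <- as.Date(w)
  if (length(w) != 2L || anyNA(w)) {
    stop("window must be two valid dates", call. = FALSE)
  }
  if (w[2L] <= w[1L]) {
    stop("window end must be strictly after its start", call. = FALSE)
  }
  w
}

in_window <- function(dates, window) {
  dates >= window[1L] & dates <= window[2L]
}

#' Run code with the global RNG state preserved
#'
#' Used by internal machinery (e.g. the generator calibration) that needs its
#' own deterministic stream without disturbing the caller's RNG.
#' @keywords internal
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(code)
}

# One global seed expands into independent per-table substreams so that
# regenerating with more patients does not perturb draws of earlier tables.
substream_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1e6) * 1031 + k * 7919
  as.integer(s %% 2147483647)
}

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

days_between <- function(a, b) as.integer(b - a)
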