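# Physical constants and small numeric helpers shared across modules.

#' Energy conversion constants
#'
#' Fixed conversion factors used throughout the package:
#' \describe{
#'   \item{`HARTREE_TO_KCAL`}{627.509474 kcal/mol per Hartree.}
#'   \item{`EV_TO_KCAL`}{23.060548 kcal/mol per eV; this is the Faraday
#'     constant expressed so that a one-electron free energy in kcal/mol
#'     divides directly into volts.}
#'   \item{`KCAL_TO_KJ`}{4.184 kJ per kcal (thermochemical calorie).}
#' }
#' @name energy-constants
#' @keywords internal
NULL

HARTREE_TO_KCAL <- 627.509474
EV_TO_KCAL <- 23.060548
KCAL_TO_KJ <- 4.184

# default absolute potential of the standard hydrogen electrode (V)
SHE_DEFAULT <- 4.44

#' Round half away from zero
#'
#' Commercial rounding used when mirroring printed tables: 0.445 -> 0.45,
#' -0.445 -> -0.45. `base::round()` rounds half to even, which does not
#' match how results tables are conventionally typeset.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2)   # 2.68, not 2.67
#' round_half_up(-0.445, 2)  # -0.45
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Euclidean distance between two 3-vectors
dist3 <- function(a, b) vnorm(a - b)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
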