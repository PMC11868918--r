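#' @import methods
#' @importFrom stats lm coef optim sd rnorm runif rlnorm median dnorm
#'   wilcox.test quantile
#' @importFrom utils read.delim write.csv read.csv head tail
NULL

## Classed conditions: every operational failure carries a subclass of
## "cellAFM_error" so callers (and the pipeline) can branch on failure kind.
afmStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cellAFM_error", "error", "condition")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so seeded simulation calls are
#' reproducible without disturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' A small multiplicative hash keeps every derived seed a valid 32-bit
#' integer so one master seed reproducibly drives all pipeline stages.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stage/curve index.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, index) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) + 1
  x <- (x * 48271 + as.numeric(index) * 69621 + 12345) %% m
  as.integer(x %% (m - 1) + 1)
}

## Spherical-indenter Hertz force in nN.
## Units contract: E in Pa, nu dimensionless, R in um, delta in nm.
hertzForceNn <- function(delta_nm, E_pa, nu, R_um) {
  delta_nm <- pmax(delta_nm, 0)
  (4 / 3) * (E_pa / (1 - nu^2)) * sqrt(R_um * 1e-6) * (delta_nm * 1e-9)^1.5 * 1e9
}

stopifnotScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    afmStop(sprintf("'%s' must be a finite numeric scalar", name), "cellAFM_format_error")
  }
  if (positive && x <= 0) {
    afmStop(sprintf("'%s' must be > 0", name), "cellAFM_format_error")
  }
  invisible(x)
}
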