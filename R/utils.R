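#' @useDynLib lsmcount, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif sd median quantile setNames
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never disturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive finite numbers (dz, dy, dx) in um")
  as.numeric(spacing)
}

#' Physical volume of one voxel in cubic micrometers
#' @param spacing voxel spacing (dz, dy, dx) in um.
#' @return scalar, um^3.
#' @keywords internal
voxel_volume_um3 <- function(spacing) prod(check_spacing(spacing))

UM3_PER_MM3 <- 1e9
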