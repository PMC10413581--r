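#' Round half away from zero
#'
#' Fixed rounding rule used for reported segmentation ratios: ties at the last
#' kept digit move away from zero (so 0.98785 -> 0.9879, -0.36395 -> -0.3640),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 4) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_wmh <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "wmh_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
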