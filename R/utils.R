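#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves rounded away from
#' zero (so 85.5 -> 86), the convention used when reporting integer
#' percentages. Base [round()] uses round-half-even, which would report
#' 86.5 as 86.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every stochastic generator so that identical seeds give
# bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Centered disc mask on an nr x nc pixel grid. `radius_px` in pixels;
# the disc is centered between pixels so a radius of n/2 spans n pixels.
disc_mask <- function(nr, nc = nr, radius_px = min(nr, nc) / 2,
                      center = c((nr + 1) / 2, (nc + 1) / 2)) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius_px^2
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
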