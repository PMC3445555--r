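#' Fiber-bundle specification
#'
#' Geometry of the coherent imaging fiber bundle and the pixel grid it is
#' sampled on. The field of view is a centered disc of
#' `fov_diameter_um / pixel_size_um` pixels; fiber cores sit on a
#' triangular lattice with spacing `core_spacing_um`, which matches the
#' instrument's ~4 um lateral resolution.
#'
#' @param fov_diameter_um field-of-view diameter in micrometres
#'   (default 720, the instrument's circular field).
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @param core_spacing_um centre-to-centre fiber core spacing (um).
#' @param core_diameter_um fiber core diameter (um); must not exceed the
#'   spacing.
#' @param pattern_amplitude peak modulation of the honeycomb pattern as a
#'   fraction of the dynamic range, in `[0, 1)`.
#' @return an object of class `fiber_bundle_spec`.
#' @export
fiber_bundle_spec <- function(fov_diameter_um = 720,
                              pixel_size_um = 1,
                              core_spacing_um = 4,
                              core_diameter_um = 3,
                              pattern_amplitude = 0.2) {
  stopifnot_scalar(fov_diameter_um, "fov_diameter_um")
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  stopifnot_scalar(core_spacing_um, "core_spacing_um")
  stopifnot_scalar(core_diameter_um, "core_diameter_um")
  stopifnot_scalar(pattern_amplitude, "pattern_amplitude", positive = FALSE)
  if (core_diameter_um > core_spacing_um)
    stop("core_diameter_um must not exceed core_spacing_um")
  if (pattern_amplitude < 0 || pattern_amplitude >= 1)
    stop("pattern_amplitude must be in [0, 1)")
  structure(
    list(fov_diameter_um = fov_diameter_um,
         pixel_size_um = pixel_size_um,
         core_spacing_um = core_spacing_um,
         core_diameter_um = core_diameter_um,
         pattern_amplitude = pattern_amplitude),
    class = "fiber_bundle_spec")
}

# Image side length (pixels) and FOV radius (pixels) for a spec.
spec_npx <- function(spec) as.integer(ceiling(spec$fov_diameter_um / spec$pixel_size_um))
spec_fov_radius_px <- function(spec) spec$fov_diameter_um / spec$pixel_size_um / 2

#' Field-of-view mask for a bundle specification
#'
#' @param spec a [fiber_bundle_spec()].
#' @return logical matrix, `TRUE` inside the circular field of view.
#' @export
fov_mask <- function(spec) {
  n <- spec_npx(spec)
  disc_mask(n, n, spec_fov_radius_px(spec))
}

#' Fiber core centres inside the field of view
#'
#' Enumerates the triangular core lattice (basis vectors `(s, 0)` and
#' `(s/2, s*sqrt(3)/2)` with `s` the core spacing in pixels, anchored at
#' the image centre) and keeps the points falling inside the FOV disc.
#'
#' @param spec a [fiber_bundle_spec()].
#' @return two-column matrix of core centres in pixel coordinates
#'   (columns `x`, `y`; x rightward, y downward, 1-based).
#' @export
fiber_core_centers <- function(spec) {
  s <- spec$core_spacing_um / spec$pixel_size_um
  R <- spec_fov_radius_px(spec)
  n <- spec_npx(spec)
  cx <- (n + 1) / 2
  cy <- (n + 1) / 2
  h <- s * sqrt(3) / 2
  vmax <- ceiling(R / h) + 1L
  umax <- ceiling(R / s) + vmax + 1L
  g <- expand.grid(u = -umax:umax, v = -vmax:vmax)
  x <- cx + g$u * s + g$v * s / 2
  y <- cy + g$v * h
  keep <- (x - cx)^2 + (y - cy)^2 <= R^2
  cbind(x = x[keep], y = y[keep])
}

#' Render the honeycomb modulation pattern of the fiber bundle
#'
#' Produces the multiplicative background pattern a coherent fiber bundle
#' superimposes on every frame: bright Gaussian-profiled cores on a
#' triangular lattice. The returned image has mean exactly 1 inside the
#' field of view (so multiplying a frame by it preserves mean intensity),
#' peak deviation `pattern_amplitude`, and is 0 outside the FOV.
#'
#' @param spec a [fiber_bundle_spec()]. The core spacing must be resolvable,
#'   i.e. at least one pixel.
#' @return numeric matrix, the pattern image.
#' @export
make_fiber_pattern <- function(spec) {
  s <- spec$core_spacing_um / spec$pixel_size_um
  if (s < 1)
    stop("fiber pattern unresolvable: core_spacing_um < pixel_size_um")
  n <- spec_npx(spec)
  mask <- fov_mask(spec)
  if (spec$pattern_amplitude == 0) {
    p <- matrix(0, n, n)
    p[mask] <- 1
    return(p)
  }
  cx <- (n + 1) / 2
  h <- s * sqrt(3) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - cx # x = column
  y <- matrix(seq_len(n), n, n) - cx               # y = row
  # lattice coordinates: (x, y) = u*(s,0) + v*(s/2, h)
  v <- y / h
  u <- x / s - v / 2
  d2 <- matrix(Inf, n, n)
  for (du in 0:1) for (dv in 0:1) {
    u0 <- floor(u) + du
    v0 <- floor(v) + dv
    dx <- x - (u0 * s + v0 * s / 2)
    dy <- y - v0 * h
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sigma <- (spec$core_diameter_um / spec$pixel_size_um) / 4
  g <- exp(-d2 / (2 * sigma^2))
  g0 <- g - mean(g[mask])
  p <- 1 + spec$pattern_amplitude * g0 / max(abs(g0[mask]))
  p <- p - (mean(p[mask]) - 1)  # re-centre: unity mean inside FOV
  p[!mask] <- 0
  p
}
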