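#' Nucleus population parameters for synthetic frames
#'
#' Nuclei are rendered as non-overlapping ellipses (area-preserving
#' deformations of discs) with radii specified in micrometres so that the
#' rendered scene is invariant to the pixel grid. Defaults give nuclear
#' areas of roughly 80-450 px at 1 um/px, comfortably inside the 50-1500
#' px object-size window used downstream.
#'
#' @param radius_mean_um,radius_sd_um mean and s.d. of the equivalent
#'   circular radius (um).
#' @param radius_min_um,radius_max_um truncation bounds on the radius (um).
#' @param peak_intensity,peak_sd mean and s.d. of per-nucleus intensity
#'   (fraction of dynamic range).
#' @param background cytoplasmic background intensity.
#' @param ecc_max maximum eccentricity-like elongation; aspect ratios are
#'   drawn uniformly in `[1, 1 + ecc_max]`.
#' @return an object of class `nucleus_params`.
#' @export
nucleus_params <- function(radius_mean_um = 7, radius_sd_um = 1.2,
                           radius_min_um = 4.5, radius_max_um = 12,
                           peak_intensity = 0.75, peak_sd = 0.05,
                           background = 0.25, ecc_max = 0.3) {
  stopifnot(radius_min_um > 0, radius_max_um >= radius_min_um,
            peak_intensity > background, background >= 0,
            ecc_max >= 0)
  structure(list(radius_mean_um = radius_mean_um,
                 radius_sd_um = radius_sd_um,
                 radius_min_um = radius_min_um,
                 radius_max_um = radius_max_um,
                 peak_intensity = peak_intensity, peak_sd = peak_sd,
                 background = background, ecc_max = ecc_max),
            class = "nucleus_params")
}

#' Noise model for synthetic frames
#'
#' Poisson-like shot noise (the frame is treated as an expected photon
#' count of `photon_scale` at full scale) plus additive Gaussian read
#' noise. Either component can be disabled.
#'
#' @param photon_scale photons at full scale for shot noise; `Inf`
#'   disables shot noise.
#' @param read_sd standard deviation of Gaussian read noise (fraction of
#'   dynamic range); 0 disables it.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 500, read_sd = 0.01) {
  stopifnot(photon_scale > 0, read_sd >= 0)
  structure(list(photon_scale = photon_scale, read_sd = read_sd),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
no_noise <- function() noise_model(photon_scale = Inf, read_sd = 0)

# Rasterize one ellipse into linear pixel indices of an n x n grid.
# (cx, cy) in pixel coords (x = column, y = row); a, b semi-axes in px,
# theta orientation in radians.
ellipse_pixels <- function(cx, cy, a, b, theta, n) {
  r_out <- max(a, b)
  rows <- max(1L, floor(cy - r_out)):min(n, ceiling(cy + r_out))
  cols <- max(1L, floor(cx - r_out)):min(n, ceiling(cx + r_out))
  y <- matrix(rows, length(rows), length(cols)) - cy
  x <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  ct <- cos(theta); st <- sin(theta)
  u <- (x * ct + y * st) / a
  v <- (-x * st + y * ct) / b
  inside <- u * u + v * v <= 1
  ri <- matrix(rows, length(rows), length(cols))
  ci <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  (ci[inside] - 1L) * n + ri[inside]
}

# Place non-overlapping nuclei until the nuclear pixel count reaches the
# target. Returns a data frame of placed nuclei and the binary mask.
place_nuclei <- function(target_np, spec, nuclei, fov) {
  n <- spec_npx(spec)
  R <- spec_fov_radius_px(spec)
  cx0 <- (n + 1) / 2
  px <- 1 / spec$pixel_size_um   # px per um
  r_min <- nuclei$radius_min_um * px
  r_max <- nuclei$radius_max_um * px
  mask <- matrix(FALSE, n, n)
  placed <- list()
  pcx <- pcy <- prout <- numeric(0)
  np_cur <- 0
  k <- 0L
  fail_streak <- 0L
  while (TRUE) {
    rem <- target_np - np_cur
    if (rem <= 0) break
    r <- stats::rnorm(1, nuclei$radius_mean_um, nuclei$radius_sd_um) * px
    r <- min(max(r, r_min), r_max)
    if (pi * r^2 > rem) r <- max(r_min, sqrt(rem / pi))
    # stop rather than overshoot by more than the remaining deficit
    if (pi * r^2 > 2 * rem) break
    rho <- 1 + stats::runif(1, 0, nuclei$ecc_max)
    a <- r * sqrt(rho); b <- r / sqrt(rho)
    theta <- stats::runif(1, 0, pi)
    margin <- max(a, b)
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      rad <- sqrt(stats::runif(1)) * (R - margin - 1)
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- cx0 + rad * cos(ang)
      cy <- cx0 + rad * sin(ang)
      clear <- !length(pcx) ||
        !any((pcx - cx)^2 + (pcy - cy)^2 < (prout + margin + 1)^2)
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) {
      fail_streak <- fail_streak + 1L
      if (fail_streak >= 5L)
        stop("requested N/C exceeds the packing limit of non-overlapping nuclei")
      next
    }
    fail_streak <- 0L
    idx <- ellipse_pixels(cx, cy, a, b, theta, n)
    idx <- idx[fov[idx]]
    mask[idx] <- TRUE
    k <- k + 1L
    pcx[k] <- cx; pcy[k] <- cy; prout[k] <- margin
    placed[[k]] <- c(cx = cx, cy = cy, a = a, b = b, theta = theta,
                     rout = margin,
                     peak = min(1, max(nuclei$background + 0.05,
                       stats::rnorm(1, nuclei$peak_intensity,
                                    nuclei$peak_sd))),
                     area_px = length(idx))
    np_cur <- sum(mask)
  }
  list(mask = mask, placed = placed)
}

placed_mat <- function(placed) do.call(rbind, placed)

#' Render a synthetic microendoscopy frame with known ground truth
#'
#' Builds a scene of bright, non-overlapping nuclei on a dimmer
#' cytoplasmic background, multiplies it by the fiber-bundle honeycomb
#' pattern, adds shot and read noise, and clips to the dynamic range.
#' Nucleus count and size are adjusted so the realised ground-truth N/C
#' ratio lies within `nc_tol` of the request. Nuclei have hard edges, so
#' in the noiseless, pattern-free case the set of bright pixels *is* the
#' ground-truth mask.
#'
#' @param target_nc requested N/C area ratio (>= 0).
#' @param spec a [fiber_bundle_spec()].
#' @param nuclei a [nucleus_params()].
#' @param noise a [noise_model()], or [no_noise()].
#' @param seed integer seed; fully determines the frame.
#' @param nc_tol maximum absolute deviation of the realised true N/C from
#'   `target_nc` (default 0.005).
#' @return list with elements `frame` (an [hrme_frame()]), `truth`
#'   (list: `nuclear_mask`, `roi_mask`, `true_nc_ratio`), and `nuclei`
#'   (data frame of placed nuclei).
#' @export
render_frame <- function(target_nc, spec = fiber_bundle_spec(),
                         nuclei = nucleus_params(),
                         noise = noise_model(), seed = 1L,
                         nc_tol = 0.005) {
  if (target_nc < 0) stop("target_nc must be non-negative")
  fov <- fov_mask(spec)
  roi_area <- sum(fov)
  target_np <- round(target_nc / (1 + target_nc) * roi_area)
  if (target_np / roi_area > 0.40)
    stop("requested N/C exceeds the packing limit of non-overlapping nuclei")
  with_seed(seed, {
    pl <- place_nuclei(target_np, spec, nuclei, fov)
    np <- sum(pl$mask)
    true_nc <- np / (roi_area - np)
    if (abs(true_nc - target_nc) > nc_tol)
      stop(sprintf(
        "could not realise N/C %.3f within %.3f (achieved %.3f)",
        target_nc, nc_tol, true_nc))
    n <- spec_npx(spec)
    img <- matrix(0, n, n)
    img[fov] <- nuclei$background
    if (length(pl$placed)) {
      for (nu in pl$placed) {
        idx <- ellipse_pixels(nu["cx"], nu["cy"], nu["a"], nu["b"],
                              nu["theta"], n)
        idx <- idx[fov[idx]]
        img[idx] <- nu["peak"]
      }
    }
    if (spec$pattern_amplitude > 0)
      img <- img * make_fiber_pattern(spec)
    if (is.finite(noise$photon_scale))
      img[fov] <- stats::rpois(sum(fov),
                               img[fov] * noise$photon_scale) /
        noise$photon_scale
    if (noise$read_sd > 0)
      img[fov] <- img[fov] + stats::rnorm(sum(fov), 0, noise$read_sd)
    img <- pmin(pmax(img, 0), 1)
    img[!fov] <- 0
    nuc_df <- if (length(pl$placed))
      as.data.frame(placed_mat(pl$placed)) else
      data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                 b = numeric(0), theta = numeric(0), rout = numeric(0),
                 peak = numeric(0), area_px = numeric(0))
    list(frame = hrme_frame(img, spec$pixel_size_um, fov),
         truth = list(nuclear_mask = pl$mask, roi_mask = fov,
                      true_nc_ratio = true_nc),
         nuclei = nuc_df)
  })
}

#' Render a short synthetic movie with motion and blur schedules
#'
#' Renders one base scene and derives each movie frame from it by an
#' integer-pixel translation, optional Gaussian blur, and fresh noise.
#' This exercises representative-frame selection and quality control:
#' blurred frames fail the focus metric and translated frames raise the
#' motion score. Ground truth refers to the unshifted base scene.
#'
#' @param target_nc requested N/C ratio for the base scene.
#' @param spec a [fiber_bundle_spec()].
#' @param n_frames number of frames (>= 1).
#' @param motion_px `n_frames x 2` matrix of per-frame (dx, dy) pixel
#'   translations; `NULL` for a static movie.
#' @param blur_sigma numeric vector of per-frame Gaussian blur sigmas in
#'   pixels (0 = sharp); recycled to `n_frames`.
#' @param nuclei,noise,seed,nc_tol as in [render_frame()].
#' @param site_id site identifier stored on the movie.
#' @return list with `movie` (an [hrme_movie()]) and `truth` as in
#'   [render_frame()].
#' @export
render_movie <- function(target_nc, spec = fiber_bundle_spec(),
                         n_frames = 3L, motion_px = NULL,
                         blur_sigma = 0, nuclei = nucleus_params(),
                         noise = noise_model(), seed = 1L,
                         nc_tol = 0.005, site_id = NA_character_) {
  if (n_frames < 1L) stop("n_frames must be at least 1")
  base <- render_frame(target_nc, spec, nuclei, no_noise(), seed = seed,
                       nc_tol = nc_tol)
  blur_sigma <- rep_len(blur_sigma, n_frames)
  if (is.null(motion_px)) motion_px <- matrix(0, n_frames, 2)
  if (nrow(motion_px) != n_frames || ncol(motion_px) != 2)
    stop("motion_px must be an n_frames x 2 matrix")
  fov <- base$frame$fov
  frames <- with_seed(seed + 7L, lapply(seq_len(n_frames), function(i) {
    img <- shift_image(base$frame$pixels, round(motion_px[i, 1]),
                       round(motion_px[i, 2]))
    if (blur_sigma[i] > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = blur_sigma[i]))
    if (is.finite(noise$photon_scale))
      img[fov] <- stats::rpois(sum(fov),
                               pmax(img[fov], 0) * noise$photon_scale) /
        noise$photon_scale
    if (noise$read_sd > 0)
      img[fov] <- img[fov] + stats::rnorm(sum(fov), 0, noise$read_sd)
    img <- pmin(pmax(img, 0), 1)
    img[!fov] <- 0
    hrme_frame(img, spec$pixel_size_um, fov)
  }))
  list(movie = hrme_movie(frames, site_id = site_id),
       truth = base$truth)
}

# Integer-pixel translation with zero fill. dx shifts columns (x),
# dy shifts rows (y).
shift_image <- function(img, dx, dy) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - dy
  src_c <- seq_len(m) - dx
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
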