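#' Quality-control thresholds
#'
#' Thresholds for the three discard rules applied to each site's
#' representative frame: more than half of the field of view out of
#' focus, evidence of motion artifact, or significant debris. The 50%
#' out-of-focus bound is the published rule; the remaining defaults are
#' configuration, calibrated on synthetic sharp/blurred fixtures, since
#' the study's reviewer applied these rules visually.
#'
#' @param focus_min minimum contrast-normalized focus score for a tile to
#'   count as in focus (Laplacian variance divided by the squared mean
#'   FOV intensity).
#' @param oof_max maximum tolerated out-of-focus tile fraction (default
#'   0.5: "more than 50%" fails).
#' @param motion_max maximum tolerated motion score (1 - peak normalized
#'   cross-correlation with temporally adjacent frames).
#' @param debris_max maximum tolerated debris-covered fraction of the FOV.
#' @param tile_px side length of the square focus tiles, in pixels.
#' @param debris_min_px minimum connected-component area counted as
#'   debris (the object-size upper bound reused from segmentation).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(focus_min = 0.02, oof_max = 0.5,
                          motion_max = 0.2, debris_max = 0.05,
                          tile_px = 32L, debris_min_px = 1500L) {
  structure(list(focus_min = focus_min, oof_max = oof_max,
                 motion_max = motion_max, debris_max = debris_max,
                 tile_px = as.integer(tile_px),
                 debris_min_px = as.integer(debris_min_px)),
            class = "qc_thresholds")
}

# 4-neighbour Laplacian (second difference), replicate edges.
laplacian <- function(img) {
  n <- nrow(img); m <- ncol(img)
  up <- img[c(1L, seq_len(n - 1L)), ]
  dn <- img[c(seq_len(n - 1L) + 1L, n), ]
  lf <- img[, c(1L, seq_len(m - 1L))]
  rt <- img[, c(seq_len(m - 1L) + 1L, m)]
  4 * img - up - dn - lf - rt
}

# Per-tile focus scores: variance of the Laplacian within each tile,
# normalized by the squared mean FOV intensity so the score is invariant
# to multiplying the frame by a positive constant. Only tiles with at
# least half their pixels inside the FOV are scored.
tile_focus_scores <- function(frame, tile_px = 32L) {
  img <- frame$pixels
  fov <- frame$fov
  if (nrow(img) < tile_px || ncol(img) < tile_px)
    stop("frame is smaller than one focus tile")
  mu <- mean(img[fov])
  if (!is.finite(mu) || mu <= 0) return(numeric(0))
  L <- laplacian(img)
  nr <- nrow(img) %/% tile_px
  nc <- ncol(img) %/% tile_px
  scores <- numeric(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1L) * tile_px + 1L):(i * tile_px)
    cols <- ((j - 1L) * tile_px + 1L):(j * tile_px)
    inside <- fov[rows, cols]
    if (mean(inside) < 0.5) next
    scores <- c(scores, stats::var(L[rows, cols][inside]) / mu^2)
  }
  scores
}

# Peak normalized cross-correlation between two images over all circular
# shifts (FFT-based). Returns 0 if either image has zero variance.
ncc_peak <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  N <- length(a)
  sa <- stats::sd(a) * sqrt((N - 1) / N)
  sb <- stats::sd(b) * sqrt((N - 1) / N)
  if (sa == 0 || sb == 0) return(0)
  A <- stats::fft(a - mean(a))
  B <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / N
  max(cc) / (N * sa * sb)
}

# Fraction of the FOV covered by debris: connected components (8-conn)
# of saturated or occluding-dark pixels larger than debris_min_px.
# Intensities are normalized by the FOV maximum first, so the measure is
# invariant to positive rescaling.
debris_fraction <- function(frame, debris_min_px = 1500L) {
  img <- frame$pixels
  fov <- frame$fov
  mx <- max(img[fov])
  if (mx <= 0) return(1)
  rel <- img / mx
  cand <- fov & (rel >= 0.98 | rel <= 0.02)
  if (!any(cand)) return(0)
  lab <- label_mask(cand)
  areas <- tabulate(lab[lab > 0L])
  big <- which(areas > debris_min_px)
  if (!length(big)) return(0)
  sum(areas[big]) / sum(fov)
}

#' Evaluate the quality-control discard rules for one frame
#'
#' Applies the three discard rules: the frame fails if more than
#' `oof_max` (default 50%) of the field of view is out of focus, if its
#' motion score exceeds `motion_max`, or if debris covers more than
#' `debris_max` of the FOV. The motion score needs movie context; for a
#' single frame pass `motion` (defaults to 0), or use [qc_movie()].
#'
#' @param frame an [hrme_frame()].
#' @param thresholds a [qc_thresholds()].
#' @param motion precomputed motion score in `[0, 1]`.
#' @return list of class `qc_report`: `passed`, `out_of_focus_fraction`,
#'   `motion_score`, `debris_fraction`, `reasons` (character vector of
#'   fired rules, empty when passed).
#' @export
qc_evaluate <- function(frame, thresholds = qc_thresholds(), motion = 0) {
  scores <- tile_focus_scores(frame, thresholds$tile_px)
  oof <- if (length(scores)) mean(scores < thresholds$focus_min) else 1
  deb <- debris_fraction(frame, thresholds$debris_min_px)
  reasons <- character(0)
  if (oof > thresholds$oof_max) reasons <- c(reasons, "out_of_focus")
  if (motion > thresholds$motion_max) reasons <- c(reasons, "motion")
  if (deb > thresholds$debris_max) reasons <- c(reasons, "debris")
  structure(list(passed = length(reasons) == 0L,
                 out_of_focus_fraction = oof,
                 motion_score = motion,
                 debris_fraction = deb,
                 reasons = reasons),
            class = "qc_report")
}

# Motion score of frame i within a movie: 1 minus the best peak NCC with
# its temporally adjacent frames. 0 for a single-frame movie.
movie_motion_scores <- function(movie) {
  n <- length(movie)
  if (n == 1L) return(0)
  vapply(seq_len(n), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= n]
    best <- max(vapply(nb, function(j)
      ncc_peak(movie$frames[[i]]$pixels, movie$frames[[j]]$pixels),
      numeric(1)))
    max(0, 1 - best)
  }, numeric(1))
}

#' Select the representative frame of a movie
#'
#' Returns the index of the frame maximizing a composite score:
#' sharpness (median tile focus score, normalized by the best frame's)
#' minus the motion score minus the debris fraction. This automates the
#' manual, blinded frame choice of the original protocol; ties are broken
#' by the lowest index, and frames with no usable signal (zero mean) are
#' fully penalized.
#'
#' @param movie an [hrme_movie()].
#' @param thresholds a [qc_thresholds()] (tile size and debris bound are
#'   used).
#' @return integer frame index (1-based).
#' @export
select_frame <- function(movie, thresholds = qc_thresholds()) {
  n <- length(movie)
  if (n < 1L) stop("empty movie")
  motion <- rep_len(movie_motion_scores(movie), n)
  sharp <- vapply(movie$frames, function(f) {
    s <- tile_focus_scores(f, thresholds$tile_px)
    if (!length(s)) -Inf else stats::median(s)
  }, numeric(1))
  deb <- vapply(movie$frames, debris_fraction, numeric(1),
                debris_min_px = thresholds$debris_min_px)
  smax <- max(sharp[is.finite(sharp)], 0)
  sharp_norm <- ifelse(is.finite(sharp),
                       if (smax > 0) sharp / smax else 0, -Inf)
  score <- sharp_norm - motion - deb
  which.max(score)  # which.max returns the first (lowest-index) maximum
}

#' Run frame selection and quality control for one movie
#'
#' @param movie an [hrme_movie()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `selected_frame` (index), `report` (a `qc_report`
#'   for the selected frame, motion score included), and `frame` (the
#'   selected [hrme_frame()]).
#' @export
qc_movie <- function(movie, thresholds = qc_thresholds()) {
  i <- select_frame(movie, thresholds)
  motion <- rep_len(movie_motion_scores(movie), length(movie))[i]
  rep <- qc_evaluate(movie$frames[[i]], thresholds, motion = motion)
  list(selected_frame = i, report = rep, frame = movie$frames[[i]])
}
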