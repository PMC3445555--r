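#' Construct a single microendoscopy frame
#'
#' A frame is a 2-D grayscale intensity image on a physical pixel grid,
#' together with the circular field-of-view mask of the fiber bundle.
#' Intensities are stored as doubles in `[0, 1]` (the camera's dynamic
#' range mapped to the unit interval, as EBImage does).
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param fov logical matrix the same shape as `pixels`, `TRUE` inside the
#'   field of view; defaults to the largest centred disc.
#' @return an object of class `hrme_frame` with elements `pixels`,
#'   `pixel_size_um`, `fov`.
#' @export
hrme_frame <- function(pixels, pixel_size_um = 1, fov = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("frame intensities must be finite")
  if (any(pixels < 0))
    stop("frame intensities must be non-negative")
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  if (is.null(fov)) {
    fov <- disc_mask(nrow(pixels), ncol(pixels),
                     min(dim(pixels)) / 2)
  }
  if (!identical(dim(fov), dim(pixels)))
    stop("'fov' must have the same shape as 'pixels'")
  structure(list(pixels = pixels,
                 pixel_size_um = pixel_size_um,
                 fov = fov != 0),
            class = "hrme_frame")
}

#' @export
print.hrme_frame <- function(x, ...) {
  cat(sprintf("<hrme_frame> %d x %d px, %.3g um/px, FOV %d px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$fov)))
  invisible(x)
}

#' Construct a movie (ordered frame sequence) for one imaged site
#'
#' @param frames list of [hrme_frame()] objects of identical shape.
#' @param site_id site identifier string.
#' @param frame_rate frames per second, optional.
#' @return an object of class `hrme_movie`.
#' @export
hrme_movie <- function(frames, site_id = NA_character_, frame_rate = NULL) {
  if (length(frames) < 1L) stop("a movie needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "hrme_frame")))
    stop("all elements of 'frames' must be hrme_frame objects")
  d <- dim(frames[[1L]]$pixels)
  ok <- vapply(frames, function(f) identical(dim(f$pixels), d), logical(1))
  if (!all(ok)) stop("all frames in a movie must have the same shape")
  structure(list(frames = frames, site_id = site_id,
                 frame_rate = frame_rate),
            class = "hrme_movie")
}

#' @export
length.hrme_movie <- function(x) length(x$frames)

#' Write a frame to disk as a 16-bit TIFF (or PNG)
#'
#' @param frame an [hrme_frame()].
#' @param path output path; the extension (`.tif`/`.tiff` or `.png`)
#'   selects the format.
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  # EBImage images are indexed (x, y) = (column, row): transpose on the
  # way out so files read back with load_frames round-trip exactly.
  img <- EBImage::Image(t(frame$pixels))
  EBImage::writeImage(img, path, bits.per.sample = bits)
  invisible(path)
}

#' Load raster frames from disk into a movie
#'
#' Reads TIFF or PNG frames (one file per frame), checks that all frames
#' share one shape, and infers the field of view as the largest centred
#' disc unless a mask is supplied. Multi-channel files are reduced to
#' their first channel.
#'
#' @param paths character vector of readable image paths, in frame order.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param fov optional logical FOV mask applied to every frame.
#' @param site_id site identifier.
#' @return an [hrme_movie()].
#' @export
load_frames <- function(paths, pixel_size_um = 1, fov = NULL,
                        site_id = NA_character_) {
  if (length(paths) < 1L) stop("no frame paths supplied")
  frames <- vector("list", length(paths))
  d0 <- NULL
  for (i in seq_along(paths)) {
    p <- paths[i]
    img <- tryCatch(EBImage::readImage(p),
                    error = function(e)
                      stop(sprintf("cannot read frame '%s': %s",
                                   p, conditionMessage(e)), call. = FALSE))
    m <- EBImage::imageData(img)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m <- t(m)  # back to [row, col] = [y, x]
    if (is.null(d0)) d0 <- dim(m)
    if (!identical(dim(m), d0))
      stop(sprintf("frame '%s' has shape %dx%d, expected %dx%d",
                   p, nrow(m), ncol(m), d0[1], d0[2]), call. = FALSE)
    frames[[i]] <- hrme_frame(m, pixel_size_um = pixel_size_um, fov = fov)
  }
  hrme_movie(frames, site_id = site_id)
}
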