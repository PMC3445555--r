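# 8-connected component labeling of a logical mask. Components are
# relabeled 1..k in scan order (column-major order of each component's
# first pixel), which makes labeling deterministic.
label_mask <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  n <- nrow(mask); m <- ncol(mask)
  edges <- NULL
  # half of the 8-neighbourhood suffices for an undirected graph
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  rr <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    j <- (c2[ok] - 1L) * n + r2[ok]
    hit <- pos[j] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[idx[ok]][hit], pos[j][hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel so labels follow scan order of each component's first pixel
  first <- tapply(seq_along(idx), memb, min)
  ord <- order(idx[first])
  relab <- integer(length(first))
  relab[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[idx] <- relab[memb]
  lab
}

#' Suggest a binarization threshold (Otsu) within the ROI
#'
#' Computes the threshold maximizing between-class variance of the ROI
#' intensity histogram (256 bins spanning the observed ROI range). This
#' initializes the adjustable threshold of the published protocol, where
#' a blinded reviewer tuned the value until nuclei were segmented
#' appropriately; per-site overrides reproduce that manual step.
#' Because bins span the observed range, the suggested threshold is
#' equivariant under affine intensity rescaling.
#'
#' @param frame an [hrme_frame()] (preprocessed).
#' @param roi optional `roi_mask`; defaults to the frame's attached ROI
#'   or full FOV.
#' @param bins number of histogram bins.
#' @return numeric threshold, strictly between the two classes' modes.
#' @export
suggest_threshold <- function(frame, roi = NULL, bins = 256L) {
  v <- roi_values(frame, roi)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("cannot suggest a threshold: ROI intensities are constant")
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges), bins), bins)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2[-length(sb2)])
  # boundary between bin k and k+1
  (mids[k] + mids[k + 1L]) / 2
}

roi_values <- function(frame, roi = NULL) {
  mask <- if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    roi$mask & frame$fov
  } else frame_roi(frame)
  if (!any(mask)) stop("empty ROI")
  frame$pixels[mask]
}

#' Binarize a frame at a threshold within the ROI
#'
#' A pixel is set iff its intensity is strictly greater than the
#' threshold and it lies inside the ROI.
#'
#' @param frame an [hrme_frame()].
#' @param threshold intensity threshold.
#' @param roi optional `roi_mask` (defaults to attached ROI / full FOV).
#' @return logical matrix.
#' @export
binarize <- function(frame, threshold, roi = NULL) {
  mask <- if (!is.null(roi)) roi$mask & frame$fov else frame_roi(frame)
  frame$pixels > threshold & mask
}

#' Label connected objects in a binary mask
#'
#' 8-connected components, labeled deterministically in scan order of
#' each component's first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @return list with `labeled_mask` (integer matrix) and `objects`
#'   (data frame: `label`, `area_px`, `centroid_x`, `centroid_y`; pixel
#'   coordinates are 1-based, x = column, y = row).
#' @export
label_objects <- function(mask) {
  lab <- label_mask(mask != 0)
  k <- max(lab)
  if (k == 0L) {
    objects <- data.frame(label = integer(0), area_px = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    objects <- data.frame(
      label = seq_len(k),
      area_px = as.integer(tabulate(l, k)),
      centroid_x = as.numeric(tapply(cc, l, mean)),
      centroid_y = as.numeric(tapply(rr, l, mean)))
  }
  list(labeled_mask = lab, objects = objects)
}

#' Remove too-small and too-large objects from a labeled mask
#'
#' Objects with fewer than `min_px` pixels are assumed to be noise and
#' objects with more than `max_px` pixels are assumed to be debris; both
#' are removed. The bounds are strict, following the published wording:
#' an object of exactly `min_px` (50) or exactly `max_px` (1500) pixels
#' is retained. Surviving objects are relabeled contiguously; the
#' operation is idempotent.
#'
#' @param labeled output of [label_objects()], or a labeled integer
#'   matrix.
#' @param min_px,max_px inclusive size window in pixels (defaults 50 and
#'   1500).
#' @param threshold_used optional threshold to record in the result.
#' @return an object of class `segmentation_result`: list with
#'   `binary_mask`, `labeled_mask`, `threshold_used`, `objects`.
#' @export
filter_objects <- function(labeled, min_px = 50L, max_px = 1500L,
                           threshold_used = NA_real_) {
  if (min_px > max_px) stop("min_px must not exceed max_px")
  if (is.matrix(labeled)) labeled <- relist_labeled(labeled)
  keep <- labeled$objects$area_px >= min_px &
    labeled$objects$area_px <= max_px
  kept <- labeled$objects$label[keep]
  lab <- labeled$labeled_mask
  lab[!(lab %in% kept)] <- 0L
  relab <- integer(max(labeled$objects$label, 0L))
  relab[kept] <- seq_along(kept)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  objects <- labeled$objects[keep, , drop = FALSE]
  objects$label <- seq_len(nrow(objects))
  rownames(objects) <- NULL
  structure(list(binary_mask = lab > 0L,
                 labeled_mask = lab,
                 threshold_used = threshold_used,
                 objects = objects),
            class = "segmentation_result")
}

relist_labeled <- function(lab) {
  k <- max(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  list(labeled_mask = lab,
       objects = data.frame(
         label = seq_len(k),
         area_px = as.integer(tabulate(l, k)),
         centroid_x = as.numeric(tapply(cc, l, mean)),
         centroid_y = as.numeric(tapply(rr, l, mean))))
}

#' Segment nuclei in a preprocessed frame
#'
#' Binarizes the frame at the supplied (or Otsu-suggested) threshold
#' within the ROI, labels 8-connected objects, and applies the
#' 50-1500 px object-size filter.
#'
#' @param frame a preprocessed [hrme_frame()].
#' @param roi optional `roi_mask`.
#' @param threshold binarization threshold; `NULL` (default) uses
#'   [suggest_threshold()]. A per-site override reproduces the manual
#'   threshold adjustment of the original protocol.
#' @param min_px,max_px object-size window, see [filter_objects()].
#' @return a `segmentation_result` (see [filter_objects()]).
#' @export
segment_frame <- function(frame, roi = NULL, threshold = NULL,
                          min_px = 50L, max_px = 1500L) {
  if (is.null(threshold)) threshold <- suggest_threshold(frame, roi)
  mask <- binarize(frame, threshold, roi)
  filter_objects(label_objects(mask), min_px, max_px,
                 threshold_used = threshold)
}
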