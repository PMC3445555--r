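#' Classify a site from its N/C ratio at a fixed cutoff
#'
#' A site is called neoplastic when its N/C ratio is strictly greater
#' than the cutoff (default 0.163, the published operating point); a
#' ratio exactly at the cutoff is non-neoplastic.
#'
#' @param nc numeric vector of N/C ratios (>= 0).
#' @param cutoff positive N/C cutoff.
#' @return logical vector, `TRUE` for neoplastic.
#' @export
classify_site <- function(nc, cutoff = 0.163) {
  if (any(nc < 0, na.rm = TRUE)) stop("N/C ratios must be non-negative")
  if (cutoff <= 0) stop("cutoff must be positive")
  nc > cutoff
}

#' Confusion counts of the N/C classifier against histopathology
#'
#' Tabulates calls at the cutoff against the histopathologic reference,
#' with neoplastic (high grade dysplasia, CIN 2+) as the positive class.
#'
#' @param results data frame with columns `nc_ratio` and `neoplastic`
#'   (logical reference label), and optionally `site_id`.
#' @param cutoff N/C cutoff, see [classify_site()].
#' @return list of class `confusion_counts`: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(results, cutoff = 0.163) {
  stopifnot(all(c("nc_ratio", "neoplastic") %in% names(results)))
  miss <- is.na(results$neoplastic) | is.na(results$nc_ratio)
  if (any(miss)) {
    ids <- if ("site_id" %in% names(results))
      results$site_id[miss] else which(miss)
    stop("missing N/C or label for site(s): ",
         paste(ids, collapse = ", "))
  }
  call <- classify_site(results$nc_ratio, cutoff)
  ref <- results$neoplastic
  structure(list(tp = sum(call & ref), fn = sum(!call & ref),
                 tn = sum(!call & !ref), fp = sum(call & !ref)),
            class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = 100 * tp / (tp + fn)`;
#' `specificity = 100 * tn / (tn + fp)`. Both are returned at full
#' precision and rounded (half away from zero) to the nearest integer
#' percent, the convention used when reporting headline figures.
#'
#' @param counts a `confusion_counts` (see [confusion()]) or a list with
#'   `tp`, `fn`, `tn`, `fp`.
#' @return list: `sensitivity`, `specificity` (percent, full precision),
#'   `sensitivity_pct`, `specificity_pct` (integer percent).
#' @export
sens_spec <- function(counts) {
  with(counts, {
    if (tp + fn == 0) stop("no positive (neoplastic) sites")
    if (tn + fp == 0) stop("no negative (non-neoplastic) sites")
    se <- 100 * tp / (tp + fn)
    sp <- 100 * tn / (tn + fp)
    list(sensitivity = se, specificity = sp,
         sensitivity_pct = round_half_up(se),
         specificity_pct = round_half_up(sp))
  })
}

#' Receiver operating characteristic curve for the N/C classifier
#'
#' Evaluates the strict-greater classifier at every midpoint between
#' distinct sorted scores, plus sentinel cutoffs below the minimum
#' (sensitivity 1, specificity 0) and above the maximum (sensitivity 0,
#' specificity 1). The area under the curve is computed by the
#' trapezoidal rule over (1 - specificity, sensitivity), which equals
#' the Mann-Whitney U statistic divided by `n1 * n2` (ties counted 1/2).
#'
#' @param scores numeric vector of per-site N/C ratios.
#' @param labels logical vector, `TRUE` for neoplastic sites.
#' @return object of class `roc_curve`: list with `points` (data frame:
#'   `cutoff`, `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`),
#'   `auc`, and `q_point` (closest-to-perfect operating point).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels))
    stop("ROC requires both neoplastic and non-neoplastic sites")
  s <- sort(unique(scores))
  cutoffs <- c(min(s) - 1,
               if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
               max(s) + 1)
  pts <- do.call(rbind, lapply(cutoffs, function(t) {
    call <- scores > t
    data.frame(cutoff = t,
               tp = sum(call & labels), fn = sum(!call & labels),
               tn = sum(!call & !labels), fp = sum(call & !labels))
  }))
  pts$sensitivity <- pts$tp / (pts$tp + pts$fn)
  pts$specificity <- pts$tn / (pts$tn + pts$fp)
  # trapezoid over (1 - specificity, sensitivity); cutoffs ascend, so
  # FPR descends from 1 to 0
  x <- 1 - pts$specificity
  y <- pts$sensitivity
  auc <- sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
  curve <- structure(list(points = pts, auc = auc), class = "roc_curve")
  curve$q_point <- q_point(curve)
  curve
}

#' Q-point (chosen operating point) of an ROC curve
#'
#' The default Q-point is the operating point minimizing the Euclidean
#' distance to the perfect classifier at (false-positive rate 0,
#' sensitivity 1); ties are broken by higher sensitivity, then by lower
#' cutoff. `method = "youden"` instead maximizes Youden's J
#' (sensitivity + specificity - 1), with the same tie-breaks.
#'
#' @param curve an `roc_curve` (see [roc_curve()]).
#' @param method `"closest"` (default) or `"youden"`.
#' @return one-row data frame: the selected operating point.
#' @export
q_point <- function(curve, method = c("closest", "youden")) {
  method <- match.arg(method)
  pts <- curve$points
  key <- if (method == "closest")
    -sqrt((1 - pts$specificity)^2 + (1 - pts$sensitivity)^2)
  else pts$sensitivity + pts$specificity - 1
  ord <- order(-key, -pts$sensitivity, pts$cutoff)
  pts[ord[1L], , drop = FALSE]
}

#' @export
print.roc_curve <- function(x, ...) {
  q <- x$q_point
  cat(sprintf(
    "<roc_curve> %d operating points, AUC = %.3f\n  Q-point: cutoff %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
    nrow(x$points), x$auc, q$cutoff, 100 * q$sensitivity,
    100 * q$specificity))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fn=%d tn=%d fp=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}
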