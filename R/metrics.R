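#' Nuclear-to-cytoplasmic area ratio for one site
#'
#' The N/C ratio is the total segmented nuclear area divided by the total
#' cytoplasmic area within the ROI, where cytoplasmic area is the ROI
#' area minus the nuclear area:
#' `nc = nuclear_px / (roi_px - nuclear_px)`.
#'
#' @param segmentation a `segmentation_result` (see [segment_frame()]).
#' @param roi an `roi_mask`, or a logical matrix.
#' @param site_id optional site identifier.
#' @param qc_passed logical QC flag recorded with the result.
#' @return one-row data frame (a site result): `site_id`, `nc_ratio`,
#'   `nuclear_area_px`, `roi_area_px`, `n_objects`, `threshold_used`,
#'   `qc_passed`.
#' @export
nc_ratio <- function(segmentation, roi, site_id = NA_character_,
                     qc_passed = NA) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi != 0
  roi_px <- sum(mask)
  if (roi_px == 0) stop("empty ROI")
  nuc <- segmentation$binary_mask & mask
  nuclear_px <- sum(nuc)
  if (nuclear_px >= roi_px)
    stop("N/C ratio undefined: nuclear area equals the ROI area")
  data.frame(site_id = site_id,
             nc_ratio = nuclear_px / (roi_px - nuclear_px),
             nuclear_area_px = nuclear_px,
             roi_area_px = roi_px,
             n_objects = nrow(segmentation$objects),
             threshold_used = segmentation$threshold_used,
             qc_passed = qc_passed,
             stringsAsFactors = FALSE)
}

#' Cohort-level group statistics of the N/C ratio
#'
#' Per-category mean and standard error of the per-site N/C ratios, plus
#' two-sample Student's t-tests (classical pooled-variance, two-sided)
#' for every pair of categories. Sites failing QC must be excluded
#' before calling (pass only analyzable sites).
#'
#' @param results data frame with columns `nc_ratio` and `category`.
#' @param welch if `TRUE`, use Welch's unequal-variance t-test instead of
#'   the pooled-variance test.
#' @param bonferroni if `TRUE`, multiply pairwise p values by the number
#'   of comparisons (capped at 1); raw p values are the default, as in
#'   the original analysis.
#' @return list of class `group_stats` with `summary` (category, n_sites,
#'   mean_nc, sd_nc, sem_nc) and `tests` (group1, group2, t, df,
#'   p_value).
#' @export
group_stats <- function(results, welch = FALSE, bonferroni = FALSE) {
  stopifnot(all(c("nc_ratio", "category") %in% names(results)))
  results <- results[!is.na(results$category), , drop = FALSE]
  cats <- intersect(.categories, unique(results$category))
  if (!length(cats)) stop("no categorized sites")
  summ <- do.call(rbind, lapply(cats, function(cat) {
    x <- results$nc_ratio[results$category == cat]
    data.frame(category = cat, n_sites = length(x),
               mean_nc = mean(x),
               sd_nc = if (length(x) > 1) stats::sd(x) else NA_real_,
               sem_nc = if (length(x) > 1)
                 stats::sd(x) / sqrt(length(x)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(cats) > 1) utils::combn(cats, 2) else
    matrix(character(0), 2, 0)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- results$nc_ratio[results$category == g1]
    y <- results$nc_ratio[results$category == g2]
    for (nm in list(list(g1, x), list(g2, y)))
      if (length(nm[[2]]) < 2)
        stop(sprintf("category '%s' has fewer than 2 sites; t-test undefined",
                     nm[[1]]))
    tt <- stats::t.test(x, y, var.equal = !welch)
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  if (!is.null(tests) && bonferroni)
    tests$p_value <- pmin(1, tests$p_value * nrow(tests))
  structure(list(summary = summ, tests = tests), class = "group_stats")
}
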