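#' Pipeline configuration
#'
#' A single serializable object holding every tunable of the pipeline:
#' bundle geometry, cohort simulation settings, noise model, QC
#' thresholds, preprocessing parameters, object-size window, and the
#' N/C classification cutoff. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed master seed; per-site render seeds are derived from it.
#' @param nc_cutoff N/C classification cutoff (default 0.163).
#' @param min_px,max_px object-size window in pixels.
#' @param tiles,clip_limit CLAHE parameters.
#' @param kernel_radius_px median filter radius; `NULL` = derived from
#'   pixel size.
#' @param bundle list of [fiber_bundle_spec()] arguments.
#' @param cohort list of [cohort_sim_config()] arguments (seed excluded;
#'   the master seed is used).
#' @param noise list of [noise_model()] arguments.
#' @param qc list of [qc_thresholds()] arguments.
#' @return an object of class `hrme_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, nc_cutoff = 0.163,
                            min_px = 50L, max_px = 1500L,
                            tiles = c(8L, 8L), clip_limit = 0.01,
                            kernel_radius_px = NULL,
                            bundle = list(), cohort = list(),
                            noise = list(), qc = list()) {
  norm <- function(x) lapply(x, function(v)
    if (is.list(v)) unlist(v) else v)  # YAML maps -> named vectors
  cfg <- list(seed = as.integer(seed), nc_cutoff = nc_cutoff,
              min_px = as.integer(min_px), max_px = as.integer(max_px),
              tiles = as.integer(unlist(tiles)), clip_limit = clip_limit,
              kernel_radius_px = kernel_radius_px,
              bundle = norm(bundle), cohort = norm(cohort),
              noise = norm(noise), qc = norm(qc))
  # validate eagerly by instantiating each component
  invisible(do.call(fiber_bundle_spec, cfg$bundle))
  invisible(do.call(cohort_sim_config, c(cfg$cohort, list(seed = cfg$seed))))
  invisible(do.call(noise_model, cfg$noise))
  invisible(do.call(qc_thresholds, cfg$qc))
  if (cfg$nc_cutoff <= 0) stop("nc_cutoff must be positive")
  structure(cfg, class = "hrme_pipeline_config")
}

cfg_bundle <- function(cfg) do.call(fiber_bundle_spec, cfg$bundle)
cfg_cohort <- function(cfg)
  do.call(cohort_sim_config, c(cfg$cohort, list(seed = cfg$seed)))
cfg_noise <- function(cfg) do.call(noise_model, cfg$noise)
cfg_qc <- function(cfg) do.call(qc_thresholds, cfg$qc)

#' @rdname pipeline_config
#' @param config an `hrme_pipeline_config`.
#' @param path file path for the YAML configuration.
#' @export
write_pipeline_config <- function(config, path) {
  # yaml drops names of atomic vectors; serialize them as maps
  serialize <- function(x) {
    if (is.list(x)) lapply(x, serialize)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(serialize(unclass(config)), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Simulate a cohort to disk
#'
#' Samples a cohort ledger, renders one frame per site (16-bit TIFF) and
#' writes `ledger.csv`, the frames, and the resolved `config.yaml` under
#' `out_dir`. Sites flagged to fail QC are rendered with heavy Gaussian
#' blur over the whole field of view so the downstream focus rule
#' rejects them.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose emit per-site progress to stderr.
#' @return the ledger data frame (with `movie_path` filled), invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, verbose = FALSE) {
  spec <- cfg_bundle(config)
  noise <- cfg_noise(config)
  ledger <- sample_cohort(cfg_cohort(config))
  dir.create(file.path(out_dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  ledger$movie_path <- file.path("frames",
                                 paste0(ledger$site_id, ".tif"))
  for (i in seq_len(nrow(ledger))) {
    if (verbose)
      message(sprintf("simulate %s (%s)", ledger$site_id[i],
                      ledger$histopath_diagnosis[i]))
    if (ledger$qc_fail_intent[i]) {
      # out-of-focus acquisition: probe not in contact with epithelium
      r <- render_frame(0.10, spec, noise = noise,
                        seed = ledger$seed[i])
      img <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(r$frame$pixels), sigma = 12))
      img <- pmin(pmax(img, 0), 1)
      img[!r$frame$fov] <- 0
      fr <- hrme_frame(img, spec$pixel_size_um, r$frame$fov)
    } else {
      r <- render_frame(ledger$true_nc[i], spec, noise = noise,
                        seed = ledger$seed[i])
      # record the exactly realised ground truth, not the request
      ledger$true_nc[i] <- r$truth$true_nc_ratio
      fr <- r$frame
    }
    write_frame(fr, file.path(out_dir, ledger$movie_path[i]))
  }
  utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                   row.names = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(ledger)
}

#' Analyze a simulated or acquired cohort
#'
#' For every site in `ledger.csv`: load the frames, select the
#' representative frame, run quality control, and — for passing sites —
#' preprocess (ROI, CLAHE, median filter), segment, and compute the N/C
#' ratio. Writes `qc_report.csv` (all sites) and `results.csv`
#' (QC-passing sites only).
#'
#' @param out_dir directory produced by [pipeline_simulate()] (or laid
#'   out the same way).
#' @param config an [pipeline_config()]; defaults to the one stored in
#'   `out_dir`.
#' @param verbose emit per-site progress to stderr.
#' @return list with `results` and `qc_report` data frames, invisibly.
#' @export
pipeline_analyze <- function(out_dir, config = NULL, verbose = FALSE) {
  if (is.null(config))
    config <- read_pipeline_config(file.path(out_dir, "config.yaml"))
  spec <- cfg_bundle(config)
  thr <- cfg_qc(config)
  ledger <- utils::read.csv(file.path(out_dir, "ledger.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(ledger) == 0) stop("empty ledger")
  qc_rows <- list()
  res_rows <- list()
  for (i in seq_len(nrow(ledger))) {
    sid <- ledger$site_id[i]
    if (verbose) message(sprintf("analyze %s", sid))
    paths <- file.path(out_dir, strsplit(ledger$movie_path[i], ";")[[1]])
    movie <- load_frames(paths, pixel_size_um = spec$pixel_size_um,
                         site_id = sid)
    qc <- qc_movie(movie, thr)
    qc_rows[[i]] <- data.frame(
      site_id = sid, selected_frame = qc$selected_frame,
      passed = qc$report$passed,
      out_of_focus_fraction = qc$report$out_of_focus_fraction,
      motion_score = qc$report$motion_score,
      debris_fraction = qc$report$debris_fraction,
      reasons = paste(qc$report$reasons, collapse = ";"),
      stringsAsFactors = FALSE)
    if (!qc$report$passed) next
    fr <- preprocess_frame(qc$frame, tiles = config$tiles,
                           clip_limit = config$clip_limit,
                           kernel_radius_px = config$kernel_radius_px)
    override <- if ("threshold_override" %in% names(ledger))
      ledger$threshold_override[i] else NA_real_
    seg <- segment_frame(fr,
                         threshold = if (is.finite(override)) override,
                         min_px = config$min_px, max_px = config$max_px)
    row <- nc_ratio(seg, structure(list(mask = frame_roi(fr)),
                                   class = "roi_mask"),
                    site_id = sid, qc_passed = TRUE)
    row$histopath_diagnosis <- ledger$histopath_diagnosis[i]
    row$category <- ledger$category[i]
    row$neoplastic <- ledger$neoplastic[i]
    row$true_nc <- ledger$true_nc[i]
    res_rows[[length(res_rows) + 1L]] <- row
  }
  qc_report <- do.call(rbind, qc_rows)
  results <- if (length(res_rows)) do.call(rbind, res_rows) else NULL
  if (is.null(results))
    stop("no site passed quality control; nothing to analyze")
  utils::write.csv(qc_report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  invisible(list(results = results, qc_report = qc_report))
}

#' Evaluate cohort results: group statistics, confusion and ROC
#'
#' Reads `results.csv`, computes per-category means/SEMs and pairwise
#' Student's t-tests, the confusion counts and sensitivity/specificity
#' at the fixed N/C cutoff, and the full ROC curve with Q-point. Writes
#' `group_stats.csv`, `group_tests.csv`, `roc.csv` and `summary.json`.
#'
#' @param out_dir directory holding `results.csv`.
#' @param config an [pipeline_config()]; defaults to the stored one.
#' @return list with `group_stats`, `confusion`, `sens_spec`, `roc`,
#'   invisibly.
#' @export
pipeline_evaluate <- function(out_dir, config = NULL) {
  if (is.null(config))
    config <- read_pipeline_config(file.path(out_dir, "config.yaml"))
  results <- utils::read.csv(file.path(out_dir, "results.csv"),
                             stringsAsFactors = FALSE)
  gs <- group_stats(results)
  cm <- confusion(results, cutoff = config$nc_cutoff)
  ss <- sens_spec(cm)
  roc <- tryCatch(roc_curve(results$nc_ratio, results$neoplastic),
                  error = function(e)
                    stop("ROC unavailable: ", conditionMessage(e),
                         " (a cohort must contain both neoplastic and",
                         " non-neoplastic sites)", call. = FALSE))
  utils::write.csv(gs$summary, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(gs$tests, file.path(out_dir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  q <- roc$q_point
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         n_sites = nrow(results),
         nc_cutoff = config$nc_cutoff,
         confusion = unclass(cm),
         sensitivity = ss$sensitivity, specificity = ss$specificity,
         sensitivity_pct = ss$sensitivity_pct,
         specificity_pct = ss$specificity_pct,
         auc = roc$auc,
         q_point = list(cutoff = q$cutoff,
                        sensitivity = q$sensitivity,
                        specificity = q$specificity)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(group_stats = gs, confusion = cm, sens_spec = ss,
                 roc = roc))
}
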