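#' Histopathology diagnoses and diagnostic categories
#'
#' The six histopathologic diagnoses used for cervical sites and their
#' grouping into three diagnostic categories. High grade dysplasia
#' (CIN 2 and CIN 3) defines the neoplastic (positive) class; all other
#' diagnoses, including HPV effect and CIN 1 (low grade dysplasia), are
#' non-neoplastic.
#'
#' @format NULL
#' @name diagnosis_table
NULL

.diagnoses <- c("Normal", "Inflammation", "HPV effect",
                "CIN 1", "CIN 2", "CIN 3")
.categories <- c("Normal/Benign", "Low Grade", "High Grade")
.diag_to_cat <- c("Normal" = "Normal/Benign",
                  "Inflammation" = "Normal/Benign",
                  "HPV effect" = "Low Grade",
                  "CIN 1" = "Low Grade",
                  "CIN 2" = "High Grade",
                  "CIN 3" = "High Grade")

#' Map histopathology diagnoses to category and neoplastic status
#'
#' @param histopath character vector of diagnoses (`"Normal"`,
#'   `"Inflammation"`, `"HPV effect"`, `"CIN 1"`, `"CIN 2"`, `"CIN 3"`).
#' @return data frame with columns `histopath`, `category` and logical
#'   `neoplastic` (`TRUE` for High Grade, i.e. CIN 2+).
#' @export
map_diagnosis <- function(histopath) {
  bad <- setdiff(unique(histopath[!is.na(histopath)]), .diagnoses)
  if (length(bad))
    stop("unknown histopathology diagnosis: ",
         paste(bad, collapse = ", "))
  cat <- unname(.diag_to_cat[histopath])
  data.frame(histopath = histopath,
             category = cat,
             neoplastic = !is.na(cat) & cat == "High Grade",
             stringsAsFactors = FALSE)
}

#' Configuration for simulating an imaging cohort
#'
#' Defines the per-diagnosis site counts, the per-category distribution of
#' true N/C ratios, and the fraction of sites rendered with frames that
#' fail quality control. Defaults reproduce the study cohort: 44
#' analyzable sites (5 Normal, 7 Inflammation, 11 HPV effect, 7 CIN 1,
#' 2 CIN 2, 12 CIN 3). True N/C ratios are drawn from Beta distributions
#' parameterised by a category mean and a common concentration
#' (`alpha + beta`); larger concentration means tighter site-to-site
#' spread. Category means are anchored at the published exemplar values
#' (about 0.08 for a low-grade site and 0.22 for a CIN 3 site).
#'
#' @param counts named integer vector of site counts per diagnosis; names
#'   must be among the six recognised diagnoses.
#' @param nc_means named numeric vector of true-N/C means per category
#'   (`Normal/Benign`, `Low Grade`, `High Grade`), each in (0, 1).
#' @param nc_concentration Beta concentration (sum of shape parameters)
#'   shared by all categories; `Inf` gives zero dispersion (every site at
#'   its category mean).
#' @param artifact_rate fraction of the *total* imaged sites rendered with
#'   QC-failing frames. Artifact sites are appended to the diagnosed
#'   cohort, so with `n` diagnosable sites the generator adds
#'   `round(artifact_rate / (1 - artifact_rate) * n)` failing sites.
#' @param seed integer seed; fully determines the sampled cohort.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(counts = c("Normal" = 5, "Inflammation" = 7,
                                         "HPV effect" = 11, "CIN 1" = 7,
                                         "CIN 2" = 2, "CIN 3" = 12),
                              nc_means = c("Normal/Benign" = 0.06,
                                           "Low Grade" = 0.08,
                                           "High Grade" = 0.22),
                              nc_concentration = 60,
                              artifact_rate = 0,
                              seed = 1L) {
  counts <- unlist(counts)
  nc_means <- unlist(nc_means)
  if (is.null(names(counts)) || !all(names(counts) %in% .diagnoses))
    stop("'counts' must be named by diagnosis: ",
         paste(.diagnoses, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  if (sum(counts) == 0)
    stop("empty cohort: all site counts are zero")
  if (!all(.categories %in% names(nc_means)))
    stop("'nc_means' must be named by category: ",
         paste(.categories, collapse = ", "))
  if (any(nc_means <= 0 | nc_means >= 1))
    stop("'nc_means' must lie in (0, 1)")
  if (!is.infinite(nc_concentration))
    stopifnot_scalar(nc_concentration, "nc_concentration")
  if (artifact_rate < 0 || artifact_rate >= 1)
    stop("'artifact_rate' must be in [0, 1)")
  structure(list(counts = counts, nc_means = nc_means,
                 nc_concentration = nc_concentration,
                 artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Sample a cohort ledger with ground-truth N/C ratios
#'
#' Draws one record per imaged site: the histopathologic diagnosis (fixed
#' by the configured counts), its diagnostic category and neoplastic
#' status, and a true N/C ratio drawn from the category's Beta
#' distribution. If `artifact_rate > 0`, additional sites flagged
#' `qc_fail_intent` are appended; these model movies that are too blurred
#' or obstructed to analyse, so they carry no histopathology record.
#' Patients are assigned two sites each, mirroring typical acquisition
#' of up to two abnormal plus one normal site per subject.
#'
#' @param config a [cohort_sim_config()].
#' @return data frame (the cohort ledger) with columns `site_id`,
#'   `patient_id`, `histopath_diagnosis`, `category`, `neoplastic`,
#'   `true_nc`, `qc_fail_intent`, `seed` (per-site render seed).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  counts <- config$counts[config$counts > 0]
  diag <- rep(names(counts), counts)
  n_good <- length(diag)
  n_art <- round(config$artifact_rate / (1 - config$artifact_rate) * n_good)
  n <- n_good + n_art
  m <- map_diagnosis(diag)
  true_nc <- with_seed(config$seed, {
    nc <- numeric(n_good)
    for (cat in .categories) {
      idx <- which(m$category == cat)
      if (!length(idx)) next
      mu <- unname(config$nc_means[[cat]])
      if (is.infinite(config$nc_concentration)) {
        nc[idx] <- mu
      } else {
        a <- mu * config$nc_concentration
        b <- (1 - mu) * config$nc_concentration
        nc[idx] <- stats::rbeta(length(idx), a, b)
      }
    }
    nc
  })
  ledger <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%03d", ceiling(seq_len(n) / 2)),
    histopath_diagnosis = c(m$histopath, rep(NA_character_, n_art)),
    category = c(m$category, rep(NA_character_, n_art)),
    neoplastic = c(m$neoplastic, rep(NA, n_art)),
    true_nc = c(true_nc, rep(NA_real_, n_art)),
    qc_fail_intent = c(rep(FALSE, n_good), rep(TRUE, n_art)),
    seed = (config$seed %% 100000L) * 10000L + seq_len(n),
    stringsAsFactors = FALSE)
  ledger
}
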