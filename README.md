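# hrme

Quantitative analysis of high-resolution fluorescence microendoscopy
(HRME) images for the detection of cervical neoplasia.

An HRME images proflavine-stained epithelium through a coherent fiber
bundle in contact with tissue: nuclei fluoresce brightly against a
dimmer cytoplasm inside a circular 720 µm field of view. Because
neoplastic epithelium has larger, more crowded nuclei, the fraction of
the image occupied by nuclei discriminates high-grade dysplasia
(CIN 2+) from non-neoplastic tissue. The package implements the full
measurement chain for clinicians and imaging researchers working with
fiber-bundle microendoscopes — and, because such clinical images are
rarely public, a synthetic-frame generator with exact ground truth so
the chain is testable end to end.

The core statistic is the nuclear-to-cytoplasmic area ratio within a
region of interest,

    N/C = A_nuc / (A_ROI − A_nuc),

and the classifier calls a site neoplastic when N/C > 0.163 (strict).

Pipeline stages, each an exported function:

| Stage | Functions |
|---|---|
| synthetic frames/cohorts | `render_frame`, `render_movie`, `sample_cohort`, `make_fiber_pattern` |
| frame selection & QC | `select_frame`, `qc_evaluate`, `qc_movie`, `load_frames` |
| preprocessing | `apply_roi`, `equalize_contrast` (CLAHE), `remove_fiber_pattern` (median) |
| segmentation | `suggest_threshold` (Otsu in ROI), `binarize`, `label_objects`, `filter_objects` (50–1500 px, strict) |
| quantification | `nc_ratio`, `group_stats` |
| diagnostics | `classify_site`, `confusion`, `sens_spec`, `roc_curve`, `q_point` |
| orchestration | `pipeline_simulate`, `pipeline_analyze`, `pipeline_evaluate` |

A thin command-line wrapper with `simulate` / `analyze` / `evaluate`
subcommands is installed at `inst/scripts/hrme.R`.

## Worked example

Render a CIN 3-like site (true N/C 0.22), run the processing chain, and
classify:

```r
library(hrme)

r <- render_frame(0.22, seed = 42)        # 720 px frame, known truth
r$truth$true_nc_ratio
#> [1] 0.2199951

fr  <- preprocess_frame(r$frame)          # ROI -> CLAHE -> median
seg <- segment_frame(fr)                  # Otsu init + 50-1500 px filter
res <- nc_ratio(seg, roi_full(r$frame), site_id = "demo")
res[, c("site_id", "nc_ratio", "nuclear_area_px", "roi_area_px", "n_objects")]
#>   site_id nc_ratio nuclear_area_px roi_area_px n_objects
#> 1    demo 0.209903           70642      407188       450

classify_site(res$nc_ratio)               # cutoff 0.163
#> [1] TRUE
```

The estimate (0.210) recovers the rendered truth (0.220) within the
pipeline's ±0.02 validation band, and the site is correctly called
neoplastic.

Cohort-level evaluation from a per-site table of N/C ratios and
histopathology labels:

```r
cm <- confusion(cohort_results)           # columns nc_ratio, neoplastic
cm
#> <confusion_counts> tp=12 fn=2 tn=26 fp=4
sens_spec(cm)[c("sensitivity_pct", "specificity_pct")]
#> $sensitivity_pct 86    $specificity_pct 87
```

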