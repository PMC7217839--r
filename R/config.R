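#' Pipeline thresholds and conventions
#'
#' Returns the full set of tunable thresholds used by the QC, filtering,
#' classification and annotation stages. Defaults reproduce the published
#' ADHD trio analysis whose summary tables ship with the package:
#'
#' * CNV-level filters: calls are removed when supported by fewer than
#'   `min_probes` probes, shorter than `min_length_bp`, sparser than
#'   `max_bp_per_probe` (mean bp per probe) or below `min_confidence`.
#' * Merging: adjacent same-type calls merge when the gap between them is
#'   smaller than `merge_gap_fraction` of their combined length.
#' * Retention: only calls longer than `retention_min_bp` enter the de novo
#'   analysis.
#' * Sample-level QC: samples fail on LRR-SD above `lrr_sd_max`, BAF drift
#'   above `baf_drift_max` or waviness above `wf_max`; probands additionally
#'   fail an excessive-load / poor-variance screen, either at the fixed
#'   cutoffs in `fixed_outlier_cutoffs` or at mean + `outlier_sd_multiplier`
#'   standard deviations of the proband distribution.
#' * Trio classification: a proband call is likely de novo when the
#'   same-type parental call union covers less than
#'   `parental_coverage_threshold` of it in both parents.
#' * Annotation: a risk locus is hit when a call covers at least
#'   `locus_overlap_fraction` of the locus.
#' * `reference_control_denovo_rate_pct` is the published control-trio
#'   de novo rate (percent) used for the rate-ratio comparison.
#'
#' @param ... named overrides for any listed field
#' @return a named list of thresholds (class `pipeline_config`)
#' @export
pipeline_config <- function(...) {
  config <- list(
    min_probes = 10,
    min_length_bp = 50000,
    max_bp_per_probe = 20000,
    min_confidence = 10,
    merge_gap_fraction = 0.5,
    merge_combined = "sum",        # or "span": gap compared to merged span
    retention_min_bp = 200000,
    lrr_sd_max = 0.3,
    baf_drift_max = 0.01,
    wf_max = 0.05,
    outlier_sd_multiplier = 4,
    fixed_outlier_cutoffs = list(n_segments = 50.8, total_kb = 16593, baf_sd = 0.063),
    parental_coverage_threshold = 0.5,
    locus_overlap_fraction = 0.5,
    reciprocal_locus_overlap = FALSE,
    strict_confidence = FALSE,     # TRUE: unknown confidence is an error
    reference_control_denovo_rate_pct = 1.0
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline_config field(s): ", paste(unknown, collapse = ", ")))
  }
  config[names(overrides)] <- overrides
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  pos <- c("min_probes", "min_length_bp", "max_bp_per_probe", "min_confidence",
           "retention_min_bp", "lrr_sd_max", "baf_drift_max", "wf_max",
           "outlier_sd_multiplier", "reference_control_denovo_rate_pct")
  for (f in pos) {
    if (!is.numeric(config[[f]]) || config[[f]] <= 0) {
      abort(paste0("pipeline_config$", f, " must be a positive number"))
    }
  }
  for (f in c("merge_gap_fraction", "parental_coverage_threshold", "locus_overlap_fraction")) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      abort(paste0("pipeline_config$", f, " must lie in (0, 1]"))
    }
  }
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror [pipeline_config()]
#' field names; unspecified fields keep their defaults.
#'
#' @param path YAML file
#' @return a `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configuration requires the 'yaml' package")
  }
  values <- yaml::read_yaml(path)
  do.call(pipeline_config, values)
}
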