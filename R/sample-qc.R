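#' Per-sample signal QC metrics
#'
#' The four signal metrics screened at the sample level, computed from a
#' probe-level signal table (`chrom`, `position`, `lrr`, `baf`). All
#' standard deviations are population (divide-by-n) SDs.
#'
#' * `compute_lrr_sd()` — SD of all LRR values; noisy arrays exceed 0.3.
#' * `compute_baf_drift()` — fraction of probes whose BAF falls strictly
#'   inside (0.20, 0.25) or (0.75, 0.80), i.e. displaced off the canonical
#'   genotype bands towards the AAB/ABB positions; drifted arrays exceed
#'   0.01.
#' * `compute_waviness_factor()` — SD of per-window median LRR over
#'   non-overlapping 1 Mb windows (windows with fewer than 10 probes are
#'   skipped), capturing long-range genomic-wave artifacts; wavy arrays
#'   exceed 0.05. The SD is trimmed (default: 5% of windows from each
#'   tail) so that a handful of windows shifted by a real focal CNV does
#'   not masquerade as waviness — the statistic targets genome-wide
#'   waves, not copy-number signal.
#' * `compute_baf_sd()` — SD of BAF restricted to the heterozygous band
#'   \[0.25, 0.75\]; poor probe variance exceeds 0.063.
#'
#' @param signal probe signal tibble for one sample with columns `chrom`,
#'   `position`, `lrr`, `baf`
#' @return a single numeric value
#' @export
compute_lrr_sd <- function(signal) {
  lrr <- signal$lrr[!is.na(signal$lrr)]
  if (length(lrr) < 2) abort("LRR-SD needs at least 2 probes")
  sd_pop(lrr)
}

#' @rdname compute_lrr_sd
#' @export
compute_baf_drift <- function(signal) {
  baf <- signal$baf[!is.na(signal$baf)]
  if (length(baf) < 1) abort("BAF drift needs at least 1 probe")
  drifted <- (baf > 0.20 & baf < 0.25) | (baf > 0.75 & baf < 0.80)
  mean(drifted)
}

#' @rdname compute_lrr_sd
#' @param window_bp window width for the waviness factor (default 1 Mb)
#' @param min_window_probes minimum probes for a window to count
#' @param trim total fraction of windows dropped before the SD, split
#'   between the two tails of the window-median distribution
#' @export
compute_waviness_factor <- function(signal, window_bp = 1e6,
                                    min_window_probes = 10, trim = 0.1) {
  ok <- !is.na(signal$lrr)
  sig <- signal[ok, , drop = FALSE]
  if (nrow(sig) == 0) abort("waviness factor needs probes with LRR")
  window <- floor(sig$position / window_bp)
  key <- paste(sig$chrom, window)
  counts <- table(key)
  eligible <- names(counts)[counts >= min_window_probes]
  if (length(eligible) == 0) {
    abort("no window holds enough probes for the waviness factor")
  }
  keep <- key %in% eligible
  medians <- sort(as.numeric(tapply(sig$lrr[keep], key[keep], median)))
  drop <- floor(length(medians) * trim / 2)
  if (drop > 0 && length(medians) > 2 * drop) {
    medians <- medians[(drop + 1):(length(medians) - drop)]
  }
  sd_pop(medians)
}

#' @rdname compute_lrr_sd
#' @export
compute_baf_sd <- function(signal) {
  baf <- signal$baf[!is.na(signal$baf)]
  het <- baf[baf >= 0.25 & baf <= 0.75]
  if (length(het) < 2) abort("BAF-SD needs at least 2 heterozygous-band probes")
  sd_pop(het)
}

#' Aggregate all QC metrics for one sample
#'
#' Combines the four signal metrics with the call-load metrics:
#' `n_segments` is the number of CNV calls for the sample (counted after
#' CNV-level filtering but before the 200 kb retention step) and
#' `total_kb` their summed length in kilobases.
#'
#' @param signal probe signal tibble for one sample
#' @param calls the sample's post-filter call table (may be empty)
#' @param sample_id sample identifier recorded in the output (defaults to
#'   the id found in `signal`)
#' @return one-row tibble of metrics
#' @export
compute_sample_metrics <- function(signal, calls, sample_id = NULL) {
  sample_id <- sample_id %||% signal$sample_id[1]
  if (nrow(calls) > 0 && !all(calls$sample_id == sample_id)) {
    abort("calls passed to compute_sample_metrics belong to a different sample")
  }
  tibble::tibble(
    sample_id = sample_id,
    lrr_sd = compute_lrr_sd(signal),
    baf_drift = compute_baf_drift(signal),
    wf = compute_waviness_factor(signal),
    baf_sd = compute_baf_sd(signal),
    n_segments = nrow(calls),
    total_kb = sum(cnv_length(calls)) / 1000
  )
}

#' Apply the sample-exclusion rules
#'
#' Any sample is excluded when `lrr_sd > 0.3`, `baf_drift > 0.01` or
#' `wf > 0.05`. Probands are additionally screened for outlying call load
#' or probe variance: in `"fixed"` mode against the published cutoffs
#' (`n_segments > 50.8`, `total_kb > 16593`, `baf_sd > 0.063`); in
#' `"recompute"` mode against mean + 4 SD of the proband metric
#' distribution. Parents are never excluded by the load screen, so a whole
#' trio is not lost to reduced data quality in one parent.
#'
#' @param metrics tibble of per-sample metrics (see
#'   [compute_sample_metrics()]); `NA` metric values skip that rule
#' @param roles named character vector mapping `sample_id` to `"proband"`,
#'   `"mother"` or `"father"`
#' @param config a [pipeline_config()]
#' @param outlier_mode `"fixed"` (default) or `"recompute"`
#' @return tibble of QC decisions: `sample_id`, `kept`, `reasons`
#'   (semicolon-joined failed-rule identifiers, empty when kept)
#' @export
apply_sample_filters <- function(metrics, roles, config = pipeline_config(),
                                 outlier_mode = c("fixed", "recompute")) {
  outlier_mode <- match.arg(outlier_mode)
  role <- unname(roles[metrics$sample_id])
  if (any(is.na(role)) || !all(role %in% c("proband", "mother", "father", "parent"))) {
    abort("every sample needs a known role (proband/mother/father)")
  }
  is_proband <- role == "proband"

  cutoffs <- config$fixed_outlier_cutoffs
  if (outlier_mode == "recompute") {
    k <- config$outlier_sd_multiplier
    recompute <- function(x) {
      x <- x[is_proband & !is.na(x)]
      if (length(x) < 2) return(Inf)
      mean(x) + k * sd(x)
    }
    cutoffs <- list(
      n_segments = recompute(metrics$n_segments),
      total_kb = recompute(metrics$total_kb),
      baf_sd = recompute(metrics$baf_sd)
    )
  }

  exceeds <- function(x, cut) !is.na(x) & x > cut
  reasons <- purrr::pmap_chr(
    list(metrics$lrr_sd, metrics$baf_drift, metrics$wf,
         metrics$n_segments, metrics$total_kb, metrics$baf_sd, is_proband),
    function(lrr_sd, baf_drift, wf, n_segments, total_kb, baf_sd, proband) {
      failed <- c(
        if (exceeds(lrr_sd, config$lrr_sd_max)) "lrr_sd",
        if (exceeds(baf_drift, config$baf_drift_max)) "baf_drift",
        if (exceeds(wf, config$wf_max)) "wf",
        if (proband && exceeds(n_segments, cutoffs$n_segments)) "n_segments",
        if (proband && exceeds(total_kb, cutoffs$total_kb)) "total_kb",
        if (proband && exceeds(baf_sd, cutoffs$baf_sd)) "baf_sd"
      )
      paste(failed, collapse = ";")
    }
  )
  tibble::tibble(
    sample_id = metrics$sample_id,
    kept = reasons == "",
    reasons = reasons
  )
}

#' Keep only trios whose three members all passed QC
#'
#' @param trios a trio table
#' @param decisions QC decisions from [apply_sample_filters()]; a member
#'   without a decision counts as not kept (with a warning)
#' @return the surviving subset of `trios`
#' @export
complete_trios <- function(trios, decisions) {
  if (nrow(trios) == 0) return(trios)
  members <- c(trios$proband_id, trios$mother_id, trios$father_id)
  uncovered <- setdiff(members, decisions$sample_id)
  if (length(uncovered) > 0) {
    warn(paste0(length(uncovered),
                " trio member(s) lack a QC decision and are treated as excluded"))
  }
  kept <- decisions$kept[match(members, decisions$sample_id)]
  kept[is.na(kept)] <- FALSE
  kept <- matrix(kept, ncol = 3)
  trios[rowSums(kept) == 3, , drop = FALSE]
}
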