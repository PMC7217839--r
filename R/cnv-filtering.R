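#' Merge adjacent CNV calls of one sample
#'
#' HMM callers often fragment one real event into several nearby calls.
#' Consecutive calls of the same dosage type on the same chromosome are
#' merged when the gap between them is smaller than half (the configured
#' `merge_gap_fraction`) of their combined length — by default the sum of
#' the two call lengths; `merge_combined = "span"` compares against the
#' merged span instead. Overlapping same-type calls (gap <= 0) always
#' merge. The merged call spans the union, carries the summed probe count
#' and the smaller confidence of the pair, and merging is applied
#' left-to-right until a fixed point, so the result is idempotent.
#' Overlapping calls of conflicting type are both kept, with a warning.
#'
#' @param calls call table for a single sample
#' @param config a [pipeline_config()]
#' @return the merged call table, in (chrom, start) order
#' @export
merge_adjacent_calls <- function(calls, config = pipeline_config()) {
  validate_cnv_calls(calls)
  if (nrow(calls) <= 1) return(calls)
  if (length(unique(calls$sample_id)) > 1) {
    abort("merge_adjacent_calls expects calls from a single sample")
  }
  warn_conflicting_overlaps(calls)
  merged <- calls |>
    dplyr::group_by(.data$chrom, .data$cnv_type) |>
    dplyr::group_modify(~ merge_run(.x, config)) |>
    dplyr::ungroup() |>
    dplyr::relocate("sample_id")
  arrange_calls(merged)
}

merge_run <- function(df, config) {
  repeat {
    df <- df[order(df$start, df$end), , drop = FALSE]
    if (nrow(df) <= 1) return(df)
    out <- df[1, , drop = FALSE]
    changed <- FALSE
    for (i in 2:nrow(df)) {
      k <- nrow(out)
      cur <- out[k, ]
      nxt <- df[i, ]
      gap <- nxt$start - cur$end
      combined <- if (identical(config$merge_combined, "span")) {
        max(cur$end, nxt$end) - cur$start
      } else {
        cnv_length(cur) + cnv_length(nxt)
      }
      if (gap < config$merge_gap_fraction * combined) {
        out$end[k] <- max(cur$end, nxt$end)
        out$n_probes[k] <- cur$n_probes + nxt$n_probes
        out$confidence[k] <- if (any(is.na(c(cur$confidence, nxt$confidence)))) {
          NA_real_
        } else {
          min(cur$confidence, nxt$confidence)
        }
        out$copy_number[k] <- if (isTRUE(cur$copy_number == nxt$copy_number)) {
          cur$copy_number
        } else {
          NA_integer_
        }
        out$source[k] <- "merged"
        changed <- TRUE
      } else {
        out <- dplyr::bind_rows(out, nxt)
      }
    }
    if (!changed) return(out)
    df <- out
  }
}

warn_conflicting_overlaps <- function(calls) {
  by_chrom <- split(calls, calls$chrom)
  for (df in by_chrom) {
    del <- df[df$cnv_type == "DEL", ]
    dup <- df[df$cnv_type == "DUP", ]
    if (nrow(del) == 0 || nrow(dup) == 0) next
    hits <- IRanges::findOverlaps(
      as_halfopen_iranges(del$start, del$end),
      as_halfopen_iranges(dup$start, dup$end)
    )
    if (length(hits) > 0) {
      warn("overlapping DEL and DUP calls in one sample; both kept unmerged")
    }
  }
}

#' Apply the CNV-level quality filters
#'
#' A merged call fails when it is supported by fewer than `min_probes`
#' probes (`"min_probes"`), shorter than `min_length_bp` (`"min_size"`),
#' sparser than `max_bp_per_probe` mean probe spacing (`"density"`), or
#' has a caller confidence below `min_confidence` (`"confidence"`). All
#' failing rules are listed. A call with unknown confidence skips the
#' confidence rule with a warning unless `config$strict_confidence` is
#' set, in which case it is an error.
#'
#' @param calls merged call table
#' @param config a [pipeline_config()]
#' @return tibble of outcomes: the call columns plus `retained` and
#'   `reasons` (semicolon-joined; empty when retained)
#' @export
filter_calls <- function(calls, config = pipeline_config()) {
  validate_cnv_calls(calls)
  if (any(is.na(calls$confidence))) {
    if (isTRUE(config$strict_confidence)) {
      abort("call(s) with unknown confidence under strict_confidence mode")
    }
    warn("call(s) with unknown confidence: confidence rule skipped for them")
  }
  len <- cnv_length(calls)
  spacing <- len / calls$n_probes
  reasons <- purrr::pmap_chr(
    list(calls$n_probes, len, spacing, calls$confidence),
    function(n_probes, len, spacing, conf) {
      failed <- c(
        if (!is.na(n_probes) && n_probes < config$min_probes) "min_probes",
        if (len < config$min_length_bp) "min_size",
        if (!is.na(spacing) && spacing > config$max_bp_per_probe) "density",
        if (!is.na(conf) && conf < config$min_confidence) "confidence"
      )
      paste(failed, collapse = ";")
    }
  )
  out <- calls
  out$retained <- reasons == ""
  out$reasons <- reasons
  out
}

#' Keep only the retained calls of a filter outcome
#'
#' @param outcomes output of [filter_calls()]
#' @return a call table containing the retained calls only
#' @export
retained_calls <- function(outcomes) {
  out <- outcomes[outcomes$retained, , drop = FALSE]
  out$retained <- NULL
  out$reasons <- NULL
  out
}

#' Final size-retention step
#'
#' After merging and filtering, only calls strictly longer than
#' `retention_min_bp` (200 kb by default) enter the de novo analysis; a
#' call of exactly the threshold length is dropped.
#'
#' @param calls filtered call table
#' @param config a [pipeline_config()]
#' @return the retained subset
#' @export
apply_size_retention <- function(calls, config = pipeline_config()) {
  calls[cnv_length(calls) > config$retention_min_bp, , drop = FALSE]
}
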