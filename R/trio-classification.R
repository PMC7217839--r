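#' Fraction of a call covered by other calls
#'
#' Computes the fraction of `target`'s bases covered by the union of the
#' intervals in `others`, counting only calls on the same chromosome and
#' of the same dosage type (a parental duplication never explains a
#' proband deletion). Lengths follow the end − start convention.
#'
#' @param target one-row call table
#' @param others call table (any sample)
#' @return a value in \[0, 1\]
#' @export
coverage_fraction <- function(target, others) {
  stopifnot(nrow(target) == 1)
  others <- others[others$chrom == target$chrom &
                     others$cnv_type == target$cnv_type, , drop = FALSE]
  if (nrow(others) == 0) return(0)
  target_ir <- as_halfopen_iranges(target$start, target$end)
  union_ir <- IRanges::reduce(as_halfopen_iranges(others$start, others$end))
  covered <- sum(IRanges::width(IRanges::intersect(union_ir, target_ir)))
  covered / cnv_length(target)
}

#' Classify one proband call against the parental call sets
#'
#' A proband call is `likely_de_novo` when the same-type parental call
#' union covers less than the configured threshold (default 50%) of it in
#' *both* parents — operationalizing "present in the proband and absent
#' in both biological parents" robustly against caller boundary jitter —
#' and `inherited` otherwise. Parental call sets should be at the
#' post-filter (50 kb) level, not the 200 kb retention level, so that
#' small surviving parental evidence still vetoes a de novo label.
#'
#' @param call one-row proband call table
#' @param mother_calls,father_calls parental call tables
#' @param config a [pipeline_config()]
#' @return the call row with added `status`, `mother_coverage`,
#'   `father_coverage`
#' @export
classify_proband_call <- function(call, mother_calls, father_calls,
                                  config = pipeline_config()) {
  stopifnot(nrow(call) == 1)
  if (is.na(call$cnv_type)) abort("cannot classify a call of unknown type")
  threshold <- config$parental_coverage_threshold
  call$mother_coverage <- coverage_fraction(call, mother_calls)
  call$father_coverage <- coverage_fraction(call, father_calls)
  call$status <- if (max(call$mother_coverage, call$father_coverage) < threshold) {
    "likely_de_novo"
  } else {
    "inherited"
  }
  call
}

#' Classify one parental call as transmitted or not
#'
#' A parental call is `transmitted` when the same-type proband call union
#' covers at least the configured threshold of it (the boundary is
#' inclusive), else `non_transmitted`.
#'
#' @param call one-row parental call table
#' @param proband_calls proband call table
#' @param config a [pipeline_config()]
#' @return the call row with added `status` and `proband_coverage`
#' @export
classify_parental_call <- function(call, proband_calls,
                                   config = pipeline_config()) {
  stopifnot(nrow(call) == 1)
  if (is.na(call$cnv_type)) abort("cannot classify a call of unknown type")
  call$proband_coverage <- coverage_fraction(call, proband_calls)
  call$status <- if (call$proband_coverage >= config$parental_coverage_threshold) {
    "transmitted"
  } else {
    "non_transmitted"
  }
  call
}

#' Likely de novo candidates across a cohort
#'
#' Classifies every proband call of every trio against the trio's parental
#' call sets and returns the likely de novo ones, with both coverage
#' fractions as machine-checkable evidence, sorted by (chrom, start).
#' Proband calls are expected post size-retention; parental calls
#' post-filter.
#'
#' @param calls call table covering probands and parents of the cohort
#' @param trios trio table; every member id must be non-missing
#' @param config a [pipeline_config()]
#' @return tibble of classified likely-de-novo calls (possibly empty),
#'   with a `trio_id` column
#' @export
denovo_candidates <- function(calls, trios, config = pipeline_config()) {
  if (nrow(trios) == 0) abort("no trios supplied")
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    trio <- trios[i, ]
    proband <- calls[calls$sample_id == trio$proband_id, , drop = FALSE]
    if (nrow(proband) == 0) return(NULL)
    mother <- calls[calls$sample_id == trio$mother_id, , drop = FALSE]
    father <- calls[calls$sample_id == trio$father_id, , drop = FALSE]
    classified <- dplyr::bind_rows(lapply(seq_len(nrow(proband)), function(j) {
      classify_proband_call(proband[j, ], mother, father, config)
    }))
    classified$trio_id <- trio$trio_id
    classified[classified$status == "likely_de_novo", , drop = FALSE]
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    empty <- cnv_calls(character(), character(), numeric(), numeric(), character())
    empty$mother_coverage <- numeric()
    empty$father_coverage <- numeric()
    empty$status <- character()
    empty$trio_id <- character()
    return(empty)
  }
  out[order(chrom_rank(out$chrom), out$start, out$end), , drop = FALSE]
}

#' Export a trio signal window for manual review
#'
#' The published analysis confirmed candidate de novo calls by visual
#' inspection of the LRR/BAF traces in all three trio members. This
#' utility extracts the per-probe review table for a call plus flanks —
#' one row per probe position with the proband's and both parents' LRR
#' and BAF — suitable for plotting or archiving alongside the candidate
#' list.
#'
#' @param signals named list with elements `proband`, `mother`, `father`,
#'   each a probe signal tibble
#' @param call one-row call table
#' @param flank_bp flank width on each side of the call
#' @return tibble with columns `position`, `proband_lrr`, `proband_baf`,
#'   `mother_lrr`, `mother_baf`, `father_lrr`, `father_baf`
#' @export
export_trace_window <- function(signals, call, flank_bp = 0) {
  stopifnot(nrow(call) == 1)
  missing <- setdiff(c("proband", "mother", "father"), names(signals))
  if (length(missing) > 0) {
    abort(paste0("signals missing for trio member(s): ", paste(missing, collapse = ", ")))
  }
  lo <- call$start - flank_bp
  hi <- call$end + flank_bp
  member_window <- function(sig, member) {
    win <- sig[normalize_chrom(sig$chrom) == call$chrom &
                 sig$position >= lo & sig$position <= hi, , drop = FALSE]
    out <- tibble::tibble(position = win$position, lrr = win$lrr, baf = win$baf)
    names(out)[2:3] <- paste0(member, c("_lrr", "_baf"))
    out
  }
  base <- member_window(signals$proband, "proband")
  if (nrow(base) == 0) abort("no probes fall inside the requested window")
  out <- base |>
    dplyr::full_join(member_window(signals$mother, "mother"), by = "position") |>
    dplyr::full_join(member_window(signals$father, "father"), by = "position") |>
    dplyr::arrange(.data$position)
  out
}
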