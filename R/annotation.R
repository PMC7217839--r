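#' Fraction of a risk locus covered by a call
#'
#' The overlap rule is asymmetric: the intersection length divided by the
#' *locus* length (end − start convention). Calls on another chromosome
#' cover nothing.
#'
#' @param call one-row call table
#' @param locus one-row locus table
#' @return a value in \[0, 1\]
#' @export
locus_coverage <- function(call, locus) {
  stopifnot(nrow(call) == 1, nrow(locus) == 1)
  if (call$chrom != locus$chrom) return(0)
  overlap <- min(call$end, locus$end) - max(call$start, locus$start)
  max(0, overlap) / (locus$end - locus$start)
}

#' Annotate calls against a curated risk-locus list
#'
#' A call hits a locus when it covers at least `locus_overlap_fraction`
#' (default 50%) of the locus, regardless of dosage type; the
#' `type_concordant` flag records whether the call's type is among the
#' types previously implicated at the locus. With
#' `config$reciprocal_locus_overlap` the call must additionally be
#' covered to the same fraction by the locus.
#'
#' @param calls call table
#' @param loci locus table (non-empty)
#' @param config a [pipeline_config()]
#' @return tibble of hits: call columns plus `locus_name`,
#'   `fraction_of_locus_covered`, `type_concordant`
#' @export
annotate_known_loci <- function(calls, loci, config = pipeline_config()) {
  if (nrow(loci) == 0) abort("locus list is empty")
  hits <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    per_locus <- lapply(seq_len(nrow(loci)), function(j) {
      locus <- loci[j, ]
      frac <- locus_coverage(call, locus)
      if (frac < config$locus_overlap_fraction) return(NULL)
      if (isTRUE(config$reciprocal_locus_overlap)) {
        call_frac <- max(0, min(call$end, locus$end) - max(call$start, locus$start)) /
          cnv_length(call)
        if (call_frac < config$locus_overlap_fraction) return(NULL)
      }
      out <- call
      out$locus_name <- locus$name
      out$fraction_of_locus_covered <- frac
      out$type_concordant <- call$cnv_type %in% strsplit(locus$implicated_types, ",")[[1]]
      out
    })
    dplyr::bind_rows(per_locus)
  })
  dplyr::bind_rows(hits)
}

#' Annotate calls with overlapped genes
#'
#' Reports one hit per gene whose span overlaps a call by at least 1 bp
#' (`any_overlap`); `coding_overlap` is additionally true when any of the
#' gene's coding intervals intersects the call. Overlap is measured under
#' the end − start (half-open) convention, so touching intervals that
#' share only a boundary coordinate do not overlap.
#'
#' @param calls call table
#' @param models gene-model table (see [gene_models()])
#' @return tibble of gene hits: call columns plus `symbol`, `any_overlap`,
#'   `coding_overlap`
#' @export
annotate_genes <- function(calls, models) {
  empty <- tibble::tibble(symbol = character(), any_overlap = logical(),
                          coding_overlap = logical())
  if (nrow(calls) == 0 || nrow(models) == 0) {
    return(empty)
  }
  hits <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    cand <- models[models$chrom == call$chrom &
                     models$gene_start < call$end &
                     models$gene_end > call$start, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    coding_hit <- vapply(cand$coding, function(cd) {
      nrow(cd) > 0 && any(cd$start < call$end & cd$end > call$start)
    }, logical(1))
    out <- call[rep(1, nrow(cand)), , drop = FALSE]
    out$symbol <- cand$symbol
    out$any_overlap <- TRUE
    out$coding_overlap <- coding_hit
    out
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) empty else out
}

#' Screen calls against a curated gene-of-interest list
#'
#' Restricts gene annotation to a curated symbol list and to hits that
#' affect the coding sequence (the published gene rule). Curated symbols
#' absent from the supplied gene models cannot be screened; they are
#' returned in the `unresolved` attribute and reported via a warning.
#'
#' @param calls call table
#' @param curated_genes character vector of symbols of interest
#' @param models gene-model table resolving the symbols
#' @return tibble of coding gene hits restricted to curated symbols, with
#'   attribute `unresolved`
#' @export
gene_list_overlap <- function(calls, curated_genes, models) {
  curated_genes <- unique(curated_genes)
  unresolved <- setdiff(curated_genes, models$symbol)
  if (length(unresolved) > 0) {
    warn(paste0(length(unresolved), " curated symbol(s) not in the gene models: ",
                paste(head(unresolved, 5), collapse = ", ")))
  }
  hits <- annotate_genes(calls, models[models$symbol %in% curated_genes, , drop = FALSE])
  if (nrow(hits) > 0) hits <- hits[hits$coding_overlap, , drop = FALSE]
  attr(hits, "unresolved") <- unresolved
  hits
}

#' Flag calls as novel or previously reported
#'
#' A call is `known` when it covers at least the configured fraction
#' (default 50%) of any record in a user-supplied catalogue of previously
#' reported CNVs — the same asymmetric rule as the risk-locus
#' annotation — and `novel` otherwise. Duplicate catalogue records (same
#' chrom, start, end) are collapsed first. No catalogue ships with the
#' package; an empty catalogue flags everything novel, with a warning.
#'
#' @param calls call table
#' @param known_cnvs catalogue tibble with `chrom`, `start`, `end`
#' @param config a [pipeline_config()]
#' @return the calls with an added logical `known` column
#' @export
novelty_report <- function(calls, known_cnvs, config = pipeline_config()) {
  out <- calls
  if (is.null(known_cnvs) || nrow(known_cnvs) == 0) {
    warn("empty catalogue of known CNVs: every call is flagged novel")
    out$known <- rep(FALSE, nrow(calls))
    return(out)
  }
  known_cnvs <- dplyr::distinct(
    tibble::tibble(
      chrom = normalize_chrom(known_cnvs$chrom),
      start = known_cnvs$start, end = known_cnvs$end
    )
  )
  out$known <- vapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    recs <- known_cnvs[known_cnvs$chrom == call$chrom, , drop = FALSE]
    if (nrow(recs) == 0) return(FALSE)
    frac <- pmax(0, pmin(call$end, recs$end) - pmax(call$start, recs$start)) /
      (recs$end - recs$start)
    any(frac >= config$locus_overlap_fraction)
  }, logical(1))
  out
}
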