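#' Construct a validated table of CNV calls
#'
#' The central container of the pipeline: one row per copy-number call.
#' Coordinates are stored as printed by the caller (1-based start) and a
#' call's length is defined as `end - start`; exported BED is shifted to
#' 0-based half-open. Dosage type is `"DEL"` (copy number below 2) or
#' `"DUP"` (above 2); copy-neutral records are rejected upstream.
#'
#' @param sample_id sample identifiers
#' @param chrom chromosome labels, with or without a "chr" prefix
#'   (stored without)
#' @param start,end base positions as printed by the caller; `end > start`
#' @param cnv_type `"DEL"` or `"DUP"`
#' @param copy_number integer copy number 0-4, or `NA` when the caller did
#'   not report one
#' @param n_probes number of array probes supporting the call
#' @param confidence caller confidence score (`NA` when absent)
#' @param source provenance tag: `"called"`, `"merged"`, `"fixture"` or
#'   `"simulated"`
#' @return a tibble with one row per call
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cnv_type,
                      copy_number = NA_integer_, n_probes = NA_integer_,
                      confidence = NA_real_, source = "called") {
  calls <- tibble::tibble(
    sample_id = as.character(sample_id),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = as.character(cnv_type),
    copy_number = as.integer(copy_number),
    n_probes = as.integer(n_probes),
    confidence = as.numeric(confidence),
    source = as.character(source)
  )
  validate_cnv_calls(calls)
  calls
}

validate_cnv_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  required <- c("sample_id", "chrom", "start", "end", "cnv_type")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    abort(paste0("call table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(calls$end <= calls$start)) {
    abort("every call must satisfy end > start")
  }
  bad_type <- !calls$cnv_type %in% c("DEL", "DUP")
  if (any(bad_type)) {
    abort(paste0("cnv_type must be DEL or DUP; offending value(s): ",
                 paste(unique(calls$cnv_type[bad_type]), collapse = ", ")))
  }
  if ("copy_number" %in% names(calls)) {
    cn <- calls$copy_number
    known <- !is.na(cn)
    if (any(known & cn == 2L)) abort("copy_number 2 is copy-neutral, not a CNV")
    mism <- known & ((cn < 2L) != (calls$cnv_type == "DEL"))
    if (any(mism)) abort("copy_number and cnv_type disagree (cn < 2 iff DEL)")
  }
  invisible(calls)
}

#' Length of a call or interval, end minus start
#'
#' @param calls a call table, or a numeric `start` vector when `end` is given
#' @param end optional numeric vector of ends
#' @return numeric lengths in bp
#' @export
cnv_length <- function(calls, end = NULL) {
  if (is.null(end)) calls$end - calls$start else end - calls
}

#' Construct a validated trio table
#'
#' One row per parent-offspring trio. `has_id` (comorbid intellectual
#' disability) is derived as full-scale IQ below 70 and is missing exactly
#' when IQ is missing.
#'
#' @param trio_id trio labels
#' @param proband_id,mother_id,father_id sample identifiers; must be three
#'   distinct ids within a trio and non-missing
#' @param proband_sex `"F"`, `"M"` or `NA`
#' @param proband_iq full-scale IQ, `NA` when not measured
#' @return a tibble with one row per trio, including the derived `has_id`
#' @export
trio_table <- function(trio_id, proband_id, mother_id, father_id,
                       proband_sex = NA_character_, proband_iq = NA_real_) {
  trios <- tibble::tibble(
    trio_id = as.character(trio_id),
    proband_id = as.character(proband_id),
    mother_id = as.character(mother_id),
    father_id = as.character(father_id),
    proband_sex = as.character(proband_sex),
    proband_iq = as.numeric(proband_iq)
  )
  ids <- c(trios$proband_id, trios$mother_id, trios$father_id)
  if (any(is.na(ids) | ids == "")) {
    abort("incomplete trio: proband, mother and father ids are all required")
  }
  same <- trios$proband_id == trios$mother_id |
    trios$proband_id == trios$father_id |
    trios$mother_id == trios$father_id
  if (any(same)) abort("trio members must be three distinct samples")
  if (anyDuplicated(trios$proband_id)) {
    abort("duplicated proband_id in pedigree")
  }
  trios$has_id <- trios$proband_iq < 70
  trios
}

#' Construct a table of curated risk loci
#'
#' @param name locus label (typically a cytoband, e.g. "16p13.11")
#' @param chrom,start,end locus coordinates (printed convention)
#' @param implicated_types character, comma-separated subset of DEL/DUP
#'   reported at the locus
#' @param disorders character, comma-separated disorder tags (e.g.
#'   "ADHD,ASD,DD/ID,SCZ,TD"); must be non-empty
#' @return a tibble of loci
#' @export
locus_table <- function(name, chrom, start, end, implicated_types, disorders) {
  loci <- tibble::tibble(
    name = as.character(name),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    implicated_types = as.character(implicated_types),
    disorders = as.character(disorders)
  )
  if (any(loci$end <= loci$start)) abort("locus end must exceed start")
  if (any(is.na(loci$disorders) | loci$disorders == "")) {
    abort("every locus needs at least one disorder tag")
  }
  loci
}

#' Construct a table of gene models
#'
#' One row per gene; coding exons are held in the `coding` list-column as
#' data frames with `start`/`end`. Coding intervals are normalized (sorted,
#' overlaps collapsed) and must lie within the gene span.
#'
#' @param symbol gene symbols
#' @param chrom chromosome labels
#' @param gene_start,gene_end gene span
#' @param coding list of data frames with columns start/end (may be empty)
#' @return a tibble of gene models
#' @export
gene_models <- function(symbol, chrom, gene_start, gene_end, coding = NULL) {
  n <- length(symbol)
  if (is.null(coding)) coding <- rep(list(data.frame(start = numeric(), end = numeric())), n)
  models <- tibble::tibble(
    symbol = as.character(symbol),
    chrom = normalize_chrom(chrom),
    gene_start = as.numeric(gene_start),
    gene_end = as.numeric(gene_end),
    coding = lapply(coding, normalize_intervals)
  )
  if (any(models$gene_end <= models$gene_start)) abort("gene_end must exceed gene_start")
  ok <- mapply(function(cd, s, e) {
    nrow(cd) == 0 || (min(cd$start) >= s && max(cd$end) <= e)
  }, models$coding, models$gene_start, models$gene_end)
  if (!all(ok)) abort("coding intervals must lie within the gene span")
  models
}

# Sort intervals and collapse overlaps/abutments under the half-open
# convention; returns a data.frame(start, end).
normalize_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(data.frame(start = numeric(), end = numeric()))
  stopifnot(all(iv$end > iv$start))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]
  out_e <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      k <- length(out_s)
      if (iv$start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], iv$end[i])
      } else {
        out_s <- c(out_s, iv$start[i])
        out_e <- c(out_e, iv$end[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}
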