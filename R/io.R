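#' Read CNV calls in PennCNV rawcnv format
#'
#' Parses the whitespace-delimited dialect emitted by the PennCNV HMM
#' caller: a region token `chrN:start-end`, `numsnp=`, `length=` (commas
#' tolerated), a `stateS,cn=C` token, the sample identifier, and optional
#' `startsnp=`/`endsnp=`/`conf=` tokens. Dosage type is derived from the
#' copy number (`cn < 2` is a deletion, `cn > 2` a duplication); a
#' copy-neutral `cn=2` record is an error. Missing `conf=` is recorded as
#' unknown confidence.
#'
#' @param path rawcnv text file; one call per line, blank lines ignored
#' @return a call table (see [cnv_calls()]) with `source = "called"`
#' @export
read_penncnv_calls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    return(cnv_calls(character(), character(), numeric(), numeric(), character()))
  }
  rows <- lapply(seq_along(lines), function(i) parse_rawcnv_line(lines[[i]], i))
  dplyr::bind_rows(rows)
}

parse_rawcnv_line <- function(line, line_no) {
  fail <- function(msg) {
    abort(paste0("rawcnv parse error at line ", line_no, ": ", msg))
  }
  tokens <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tokens) < 4) fail("expected region, numsnp, length and state,cn tokens")
  region <- stringr::str_match(tokens[1], "^(?:chr)?([0-9XYMTxymt]+):([0-9,]+)-([0-9,]+)$")
  if (is.na(region[1, 1])) fail(paste0("malformed region token '", tokens[1], "'"))
  chrom <- region[1, 2]
  start <- as.numeric(gsub(",", "", region[1, 3]))
  end <- as.numeric(gsub(",", "", region[1, 4]))
  if (is.na(start) || is.na(end) || end <= start) fail("region must satisfy end > start")

  kv <- tokens[-1]
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  numsnp <- suppressWarnings(as.integer(gsub(",", "", get_kv("numsnp"))))
  if (is.na(numsnp)) fail("missing or malformed numsnp=")
  state_tok <- grep("^state[0-9]+,cn=[0-9]+$", kv, value = TRUE)
  if (length(state_tok) == 0) fail("missing stateS,cn=C token")
  cn <- as.integer(sub("^state[0-9]+,cn=", "", state_tok[1]))
  if (cn == 2L) fail("cn=2 is copy-neutral, not a CNV record")
  conf <- suppressWarnings(as.numeric(get_kv("conf")))

  # the sample token is the first non-key=value token after the
  # region/numsnp/length/state fields
  plain <- kv[!grepl("=", kv)]
  if (length(plain) == 0) fail("missing sample identifier token")
  sample_id <- plain[1]

  cnv_calls(
    sample_id = sample_id, chrom = chrom, start = start, end = end,
    cnv_type = if (cn < 2L) "DEL" else "DUP", copy_number = cn,
    n_probes = numsnp, confidence = conf, source = "called"
  )
}

#' Read a trio pedigree table
#'
#' Tab-separated with header columns `trio_id`, `proband_id`, `mother_id`,
#' `father_id`, `sex`, `iq` (`iq` may be `NA`). Incomplete trios (any
#' missing member id) and duplicated probands are errors: only complete
#' trios enter the analysis.
#'
#' @param path TSV file
#' @return a trio table (see [trio_table()])
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  required <- c("trio_id", "proband_id", "mother_id", "father_id", "sex", "iq")
  missing <- setdiff(required, names(ped))
  if (length(missing) > 0) {
    abort(paste0("pedigree lacks column(s): ", paste(missing, collapse = ", ")))
  }
  trio_table(
    trio_id = ped$trio_id, proband_id = ped$proband_id,
    mother_id = ped$mother_id, father_id = ped$father_id,
    proband_sex = ped$sex, proband_iq = suppressWarnings(as.numeric(ped$iq))
  )
}

#' Write calls as BED3+ and read them back
#'
#' BED lines are 0-based half-open (`bed_start = start - 1`,
#' `bed_end = end`), carry `chr`-prefixed chromosome labels, and extra
#' columns `cnv_type`, `sample_id`, `confidence`. Rows are emitted in
#' deterministic (chrom, start, end, type) order. `read_bed_calls()`
#' inverts the convention so a write/read round trip is lossless for
#' intervals, types and sample ids.
#'
#' @param calls a call table
#' @param path output (or input) file
#' @return `write_bed()` returns `path` invisibly; `read_bed_calls()`
#'   returns a call table
#' @export
write_bed <- function(calls, path) {
  validate_cnv_calls(calls)
  if (nrow(calls) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  calls <- arrange_calls(calls)
  bed <- data.frame(
    chrom = paste0("chr", calls$chrom),
    start = format(calls$start - 1, scientific = FALSE, trim = TRUE),
    end = format(calls$end, scientific = FALSE, trim = TRUE),
    cnv_type = calls$cnv_type,
    sample_id = calls$sample_id,
    confidence = ifelse(is.na(calls$confidence), ".", as.character(calls$confidence))
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed_calls <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "cnv_type", "sample_id", "confidence"),
    col_types = "cddccc", progress = FALSE
  )
  if (nrow(bed) == 0) {
    return(cnv_calls(character(), character(), numeric(), numeric(), character()))
  }
  cnv_calls(
    sample_id = bed$sample_id, chrom = bed$chrom,
    start = bed$start + 1, end = bed$end, cnv_type = bed$cnv_type,
    confidence = suppressWarnings(as.numeric(ifelse(bed$confidence == ".", NA, bed$confidence))),
    source = "called"
  )
}

#' Read per-sample probe-level signal tables
#'
#' TSV with columns `sample_id`, `chrom`, `position`, `lrr`, `baf`
#' (gzipped files are handled transparently). Probes are sorted by
#' position within chromosome; BAF must lie in \[0, 1\].
#'
#' @param path TSV or TSV.gz file
#' @return a tibble of probe signals
#' @export
read_probe_signals <- function(path) {
  sig <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "chrom", "position", "lrr", "baf")
  missing <- setdiff(required, names(sig))
  if (length(missing) > 0) {
    abort(paste0("signal table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  sig$chrom <- normalize_chrom(sig$chrom)
  if (any(sig$baf < 0 | sig$baf > 1, na.rm = TRUE)) abort("BAF values must lie in [0, 1]")
  dplyr::arrange(sig, .data$sample_id, chrom_rank(.data$chrom), .data$position)
}

#' Read a curated locus list
#'
#' BED-like TSV with header columns `name`, `chrom`, `start`, `end`,
#' `implicated_types`, `disorders`; duplicate regions (same chrom, start,
#' end) are collapsed with their type and disorder tags unioned.
#'
#' @param path TSV file
#' @return a locus table (see [locus_table()])
#' @export
read_locus_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  loci <- locus_table(raw$name, raw$chrom, raw$start, raw$end,
                      raw$implicated_types, raw$disorders)
  dedupe_loci(loci)
}

dedupe_loci <- function(loci) {
  union_tags <- function(x) paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ",")
  loci |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      name = .data$name[1],
      implicated_types = union_tags(.data$implicated_types),
      disorders = union_tags(.data$disorders),
      .groups = "drop"
    ) |>
    dplyr::select("name", "chrom", "start", "end", "implicated_types", "disorders") |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$start)
}

#' Read gene models from an exon-interval TSV
#'
#' One row per gene with columns `symbol`, `chrom`, `gene_start`,
#' `gene_end` and comma-joined `coding_starts`/`coding_ends` (empty for
#' non-coding genes).
#'
#' @param path TSV file
#' @return a gene-model table (see [gene_models()])
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  coding <- mapply(function(s, e) {
    if (is.na(s) || s == "") return(data.frame(start = numeric(), end = numeric()))
    data.frame(
      start = as.numeric(strsplit(s, ",")[[1]]),
      end = as.numeric(strsplit(e, ",")[[1]])
    )
  }, raw$coding_starts, raw$coding_ends, SIMPLIFY = FALSE)
  gene_models(raw$symbol, raw$chrom, as.numeric(raw$gene_start),
              as.numeric(raw$gene_end), coding)
}
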