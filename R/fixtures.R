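fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "denovotrio")
  if (path == "") abort(paste0("packaged fixture not found: ", file))
  path
}

#' Packaged de novo CNV summary fixture
#'
#' The 14 de novo CNVs reported by the published ADHD trio study that this
#' package reproduces (hg19 coordinates, dosage type, caller score, probe
#' support, printed size), carried by 13 probands — one proband carries
#' both chromosome-4 events. Copy numbers are unknown (the source table
#' prints type only). The per-call gene lists as printed accompany the
#' calls.
#'
#' @return a list with elements `calls` (a call table with extra columns
#'   `call_id`, `locus`, `size_printed`, `n_genes_printed`) and `genes`
#'   (tibble of `call_id`, `symbol`, one row per printed gene)
#' @export
load_table1_fixture <- function() {
  raw <- readr::read_tsv(fixture_path("table1_calls.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  calls <- cnv_calls(
    sample_id = raw$sample_id, chrom = raw$chrom, start = raw$start,
    end = raw$end, cnv_type = raw$cnv_type, confidence = raw$confidence,
    n_probes = raw$n_probes, source = "fixture"
  )
  calls$call_id <- raw$call_id
  calls$locus <- raw$locus
  calls$size_printed <- raw$size_printed
  calls$n_genes_printed <- raw$n_genes_printed
  genes <- readr::read_tsv(fixture_path("table1_genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  list(calls = calls, genes = genes)
}

#' Packaged neurodevelopmental risk-locus fixture
#'
#' The four genomic loci hit by the fixture de novo CNVs that had
#' previously been robustly implicated in ADHD or another
#' neurodevelopmental disorder (ASD, DD/ID, schizophrenia, Tourette
#' disorder), with the dosage types and disorder tags reported for each.
#'
#' @return a locus table (see [locus_table()])
#' @export
load_table2_loci <- function() {
  read_locus_table(fixture_path("table2_loci.tsv"))
}

#' Synthetic gene models matching the printed gene lists
#'
#' Real hg19 gene coordinates are not shipped. Instead, each printed gene
#' symbol of the summary fixture becomes a synthetic model occupying an
#' equal slice of its CNV's span, with a coding interval in the middle
#' half of the slice. Annotating the fixture calls against these models
#' therefore reproduces the printed per-call gene counts exactly — under
#' either the gene-span or the coding-overlap rule — while real gene
#' models can be supplied by the user for new data.
#'
#' @param fixture output of [load_table1_fixture()] (loaded afresh when
#'   omitted)
#' @return a gene-model table (see [gene_models()])
#' @export
table1_gene_models <- function(fixture = load_table1_fixture()) {
  calls <- fixture$calls
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    symbols <- fixture$genes$symbol[fixture$genes$call_id == call$call_id]
    k <- length(symbols)
    edges <- round(seq(call$start, call$end, length.out = k + 1))
    starts <- edges[-(k + 1)]
    ends <- edges[-1]
    coding <- lapply(seq_len(k), function(j) {
      width <- ends[j] - starts[j]
      data.frame(
        start = starts[j] + floor(width / 4),
        end = ends[j] - floor(width / 4)
      )
    })
    gene_models(symbols, call$chrom, starts, ends, coding)
  })
  dplyr::bind_rows(rows)
}

#' Reconstructed study cohort pedigree
#'
#' A 305-trio pedigree matching the published cohort's marginal counts:
#' the 13 fixture probands are the de novo carriers (3 with comorbid
#' intellectual disability, IQ < 70; one with missing IQ; two female);
#' the 292 remaining probands include 26 with ID, 245 without, and 21
#' with missing IQ, and 34 further female probands (36 in all, 11.8%).
#' Individual IQ values are synthetic placeholders (65 / 85 / 95) chosen
#' only to reproduce the ID / non-ID / missing partition; the published
#' group means are not encoded.
#'
#' @return a trio table (see [trio_table()]) for 305 complete trios
#' @export
study_cohort_trios <- function() {
  n <- 305
  trio_id <- sprintf("T%03d", seq_len(n))
  carrier <- seq_len(13)
  iq <- rep(95, n)
  iq[carrier] <- 85                 # carriers without ID
  iq[1:3] <- 65                     # carriers with ID
  iq[4] <- NA                       # carrier with missing IQ
  iq[14:39] <- 65                   # 26 non-carrier probands with ID
  iq[285:305] <- NA                 # 21 non-carrier probands missing IQ
  sex <- rep("M", n)
  sex[c(1, 5)] <- "F"               # two female carriers
  sex[14:47] <- "F"                 # 34 further female probands
  trio_table(
    trio_id = trio_id,
    proband_id = trio_id,
    mother_id = paste0(trio_id, "_m"),
    father_id = paste0(trio_id, "_f"),
    proband_sex = sex,
    proband_iq = iq
  )
}
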