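#' Run the full trio de novo CNV pipeline
#'
#' Orchestrates the stages in their published order: per-sample merging of
#' adjacent calls, CNV-level filters, sample-level QC (skipped with a
#' notice in calls-only mode, i.e. when no probe signals are supplied),
#' restriction to complete surviving trios, the 200 kb retention step for
#' proband calls, trio classification, optional locus/gene annotation,
#' and cohort rate statistics.
#'
#' @param calls call table for all cohort samples (raw caller output)
#' @param trios trio table for the cohort
#' @param config a [pipeline_config()]
#' @param signals optional named list of probe signal tibbles (by sample
#'   id); when absent, every sample passes QC
#' @param loci optional locus table for risk-locus annotation
#' @param models optional gene-model table for gene annotation
#' @return list of stage outputs: `decisions`, `trios_kept`, `filtered`
#'   (post-filter calls), `analysis_calls`, `candidates`, `locus_hits`,
#'   `gene_hits`, `rates` (overall + per-type + per-size-bin),
#'   `manifest` (per-stage record counts)
#' @export
run_full_pipeline <- function(calls, trios, config = pipeline_config(),
                              signals = NULL, loci = NULL, models = NULL) {
  if (nrow(trios) == 0) abort("no trios supplied")
  validate_cnv_calls(calls)

  merged <- if (nrow(calls) == 0) calls else {
    calls |>
      dplyr::group_split(.data$sample_id) |>
      lapply(merge_adjacent_calls, config = config) |>
      dplyr::bind_rows()
  }
  outcomes <- filter_calls(merged, config)
  filtered <- retained_calls(outcomes)

  roles <- c(
    stats::setNames(rep("proband", nrow(trios)), trios$proband_id),
    stats::setNames(rep("mother", nrow(trios)), trios$mother_id),
    stats::setNames(rep("father", nrow(trios)), trios$father_id)
  )
  if (is.null(signals)) {
    inform("calls-only mode: no probe signals supplied, signal QC skipped")
    decisions <- tibble::tibble(
      sample_id = names(roles), kept = TRUE, reasons = ""
    )
  } else {
    metrics <- dplyr::bind_rows(lapply(names(signals), function(id) {
      compute_sample_metrics(signals[[id]],
                             filtered[filtered$sample_id == id, , drop = FALSE],
                             sample_id = id)
    }))
    decisions <- apply_sample_filters(metrics, roles, config)
  }
  trios_kept <- complete_trios(trios, decisions)
  if (nrow(trios_kept) == 0) abort("no trios survive sample QC")

  is_proband <- filtered$sample_id %in% trios_kept$proband_id
  analysis_calls <- dplyr::bind_rows(
    apply_size_retention(filtered[is_proband, , drop = FALSE], config),
    filtered[!is_proband, , drop = FALSE]
  )
  candidates <- denovo_candidates(analysis_calls, trios_kept, config)

  locus_hits <- if (!is.null(loci)) annotate_known_loci(candidates, loci, config) else NULL
  gene_hits <- if (!is.null(models)) annotate_genes(candidates, models) else NULL

  n_trios <- nrow(trios_kept)
  rates <- dplyr::bind_rows(
    mutation_rate(candidates, n_trios),
    stratified_rates(candidates, trios_kept, n_trios, "cnv_type"),
    stratified_rates(candidates, trios_kept, n_trios, "size_bin")
  )

  manifest <- list(
    n_samples_in = length(roles),
    n_samples_kept = sum(decisions$kept),
    n_trios_in = nrow(trios),
    n_trios_kept = n_trios,
    n_calls_in = nrow(calls),
    n_calls_merged = nrow(merged),
    n_calls_filtered = nrow(filtered),
    n_calls_analysis = nrow(analysis_calls),
    n_denovo = nrow(candidates)
  )
  list(
    decisions = decisions, trios_kept = trios_kept, outcomes = outcomes,
    filtered = filtered, analysis_calls = analysis_calls,
    candidates = candidates, locus_hits = locus_hits, gene_hits = gene_hits,
    rates = rates, manifest = manifest
  )
}

#' Recompute every headline statistic from the packaged fixtures
#'
#' Runs the downstream pipeline on the packaged de novo call fixture over
#' the reconstructed 305-trio cohort (calls-only, empty parental call
#' sets — the fixture calls were all confirmed absent in both parents)
#' and recomputes each published headline quantity: overall and
#' per-individual rates, deletion/duplication rates, size-bin counts,
#' total genes hit, risk-locus hits, the ID-stratified carrier rate and
#' share, and the control-rate ratio. Every `computed` value is the
#' product of the pipeline functions at run time; `expected` carries the
#' published value for comparison.
#'
#' @param config a [pipeline_config()]
#' @return tibble with columns `quantity`, `computed`, `expected`, `pass`
#' @export
reproduce_study <- function(config = pipeline_config()) {
  fixture <- load_table1_fixture()
  trios <- study_cohort_trios()
  loci <- load_table2_loci()
  models <- table1_gene_models(fixture)

  calls <- fixture$calls
  candidates <- denovo_candidates(calls, trios, config)
  n_trios <- nrow(trios)

  overall <- mutation_rate(candidates, n_trios)
  by_type <- stratified_rates(candidates, trios, n_trios, "cnv_type")
  by_size <- stratified_rates(candidates, trios, n_trios, "size_bin")
  by_id <- stratified_rates(candidates, trios, n_trios, "id_status")
  carriers <- carrier_table(candidates, trios)
  id_share <- attr(carriers, "id_share")
  locus_hits <- annotate_known_loci(candidates, loci, config)
  gene_hits <- annotate_genes(candidates, models)
  c22 <- calls[calls$locus == "22q11.21", ]

  quantities <- tibble::tribble(
    ~quantity, ~computed, ~expected,
    "n_denovo_events", nrow(candidates), 14,
    "n_denovo_carriers", overall$n_carriers, 13,
    "overall_mutation_rate_pct", overall$event_rate_pct, 4.6,
    "per_individual_rate_pct", overall$carrier_rate_pct, 4.3,
    "del_mutation_rate_pct", by_type$event_rate_pct[by_type$stratum == "DEL"], 3.3,
    "dup_mutation_rate_pct", by_type$event_rate_pct[by_type$stratum == "DUP"], 1.3,
    "n_events_over_500kb", by_size$n_events[by_size$stratum == ">500kb"], 9,
    "n_events_200_500kb", by_size$n_events[by_size$stratum == "200-500kb"], 5,
    "total_genes_hit", nrow(gene_hits), 262,
    "n_known_locus_hits", nrow(locus_hits), 4,
    "no_id_carrier_rate_pct", by_id$carrier_rate_pct[by_id$stratum == "no_ID"], 3.5,
    "carrier_id_share_pct", id_share$share_pct, 25.0,
    "rate_ratio_vs_controls", rate_ratio(overall, config$reference_control_denovo_rate_pct), 4.6,
    "dup_22q11_length_bp", cnv_length(c22), 2567645
  )
  quantities$pass <- quantities$computed == quantities$expected
  quantities
}
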