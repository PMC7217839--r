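#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed-form beta-quantile bounds for a binomial proportion; exact
#' coverage at the small counts typical of de novo CNV studies.
#'
#' @param x number of successes
#' @param n number of trials
#' @param conf_level confidence level (default 0.95)
#' @return named numeric vector `c(low, high)` on the proportion scale
#' @export
clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - conf_level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

rate_report <- function(stratum, n_events, n_carriers, n_trios) {
  ci <- clopper_pearson_ci(n_carriers, n_trios)
  tibble::tibble(
    stratum = stratum,
    n_events = as.integer(n_events),
    n_carriers = as.integer(n_carriers),
    n_trios = as.integer(n_trios),
    event_rate_pct = round_half_up(100 * n_events / n_trios, 1),
    carrier_rate_pct = round_half_up(100 * n_carriers / n_trios, 1),
    ci_low = ci[["low"]],
    ci_high = ci[["high"]]
  )
}

#' Cohort de novo mutation and carrier rates
#'
#' The mutation (event) rate counts every likely de novo call per trio;
#' the carrier (per-individual) rate counts probands with at least one.
#' Percentages are rounded half-up to one decimal at emission; the 95%
#' Clopper-Pearson interval is reported on the carrier proportion.
#'
#' @param classified_calls classified call table (see
#'   [denovo_candidates()]); only rows with status `likely_de_novo` count
#' @param n_trios number of complete post-QC trios (the denominator)
#' @return a one-row rate report tibble
#' @export
mutation_rate <- function(classified_calls, n_trios) {
  if (!is.numeric(n_trios) || n_trios <= 0) abort("n_trios must be positive")
  dn <- classified_calls[classified_calls$status == "likely_de_novo", , drop = FALSE]
  rate_report(
    stratum = "overall",
    n_events = nrow(dn),
    n_carriers = dplyr::n_distinct(dn$sample_id),
    n_trios = n_trios
  )
}

#' Stratified de novo rates
#'
#' Supported strata:
#' * `"cnv_type"` — deletion and duplication event rates over all trios
#'   (the two event counts partition the overall count);
#' * `"size_bin"` — events of 200-500 kb versus > 500 kb (length =
#'   end − start; the bin boundary is inclusive on the left bin);
#' * `"id_status"` — carrier rates among probands with and without
#'   comorbid intellectual disability, with denominators restricted to
#'   probands whose IQ is known.
#'
#' @param classified_calls classified call table
#' @param trios trio table for the cohort (used by `id_status`)
#' @param n_trios number of complete post-QC trios
#' @param strata one of `"cnv_type"`, `"size_bin"`, `"id_status"`
#' @return a rate report tibble, one row per stratum
#' @export
stratified_rates <- function(classified_calls, trios, n_trios,
                             strata = c("cnv_type", "size_bin", "id_status")) {
  strata <- match.arg(strata)
  dn <- classified_calls[classified_calls$status == "likely_de_novo", , drop = FALSE]

  if (strata == "cnv_type") {
    reports <- lapply(c("DEL", "DUP"), function(type) {
      sub <- dn[dn$cnv_type == type, , drop = FALSE]
      rate_report(type, nrow(sub), dplyr::n_distinct(sub$sample_id), n_trios)
    })
    return(dplyr::bind_rows(reports))
  }

  if (strata == "size_bin") {
    len <- cnv_length(dn)
    bins <- list("200-500kb" = len <= 5e5, ">500kb" = len > 5e5)
    reports <- lapply(names(bins), function(bin) {
      sub <- dn[bins[[bin]], , drop = FALSE]
      rate_report(bin, nrow(sub), dplyr::n_distinct(sub$sample_id), n_trios)
    })
    return(dplyr::bind_rows(reports))
  }

  # id_status: carrier rates over known-IQ probands
  carriers <- unique(dn$sample_id)
  known <- trios[!is.na(trios$has_id), , drop = FALSE]
  reports <- lapply(c("ID", "no_ID"), function(stratum) {
    grp <- known[known$has_id == (stratum == "ID"), , drop = FALSE]
    in_grp <- dn$sample_id %in% grp$proband_id
    rate_report(
      stratum,
      n_events = sum(in_grp),
      n_carriers = sum(grp$proband_id %in% carriers),
      n_trios = nrow(grp)
    )
  })
  dplyr::bind_rows(reports)
}

#' Ratio of an observed event rate to a reference rate
#'
#' Compares the cohort de novo event rate to a published reference rate
#' (e.g. the 1.0% control-trio rate for CNVs > 200 kb).
#'
#' @param report a one-row rate report
#' @param reference_rate_pct reference rate in percent; must be positive
#' @return the ratio (dimensionless)
#' @export
rate_ratio <- function(report, reference_rate_pct) {
  if (!is.numeric(reference_rate_pct) || reference_rate_pct <= 0) {
    abort("reference rate must be positive")
  }
  report$event_rate_pct / reference_rate_pct
}

#' Per-carrier summary table
#'
#' One row per de novo carrier with the number of events, their sizes and
#' types, and the proband's IQ / ID status. The ID share among carriers
#' is computed over the non-missing-IQ subset; its numerator, denominator
#' and percentage are attached as the `id_share` attribute (the
#' percentage is `NA` when no carrier has a known IQ).
#'
#' @param classified_calls classified call table
#' @param trios trio table; every carrier must have a pedigree record
#' @return per-carrier tibble with attribute `id_share`
#' @export
carrier_table <- function(classified_calls, trios) {
  dn <- classified_calls[classified_calls$status == "likely_de_novo", , drop = FALSE]
  missing <- setdiff(unique(dn$sample_id), trios$proband_id)
  if (length(missing) > 0) {
    abort(paste0("carrier(s) without a trio record: ", paste(missing, collapse = ", ")))
  }
  out <- dn |>
    dplyr::group_by(proband_id = .data$sample_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      sizes_bp = paste(.data$end - .data$start, collapse = ";"),
      types = paste(.data$cnv_type, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      trios[, c("proband_id", "proband_iq", "has_id")],
      by = "proband_id"
    )
  n_known <- sum(!is.na(out$has_id))
  n_id <- sum(out$has_id, na.rm = TRUE)
  attr(out, "id_share") <- list(
    n_id = n_id,
    n_known_iq = n_known,
    share_pct = if (n_known > 0) round_half_up(100 * n_id / n_known, 1) else NA_real_
  )
  out
}
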