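# Small builders and independent brute-force oracles used across tests.

mk_calls <- function(start, end, chrom = "1", type = "DEL", sample = "S1",
                     n_probes = 100L, confidence = 50, cn = NA_integer_) {
  n <- max(length(start), length(end))
  cnv_calls(
    sample_id = rep_len(sample, n), chrom = rep_len(chrom, n),
    start = start, end = end, cnv_type = rep_len(type, n),
    copy_number = rep_len(cn, n), n_probes = rep_len(n_probes, n),
    confidence = rep_len(confidence, n)
  )
}

# Brute-force per-base coverage oracle: marks every base of the target
# (half-open [start, end)) covered by any other interval. Independent of
# the IRanges-based implementation.
brute_coverage <- function(target, others) {
  others <- others[others$chrom == target$chrom &
                     others$cnv_type == target$cnv_type, , drop = FALSE]
  bases <- rep(FALSE, target$end - target$start)
  if (nrow(others) > 0) {
    for (i in seq_len(nrow(others))) {
      lo <- max(target$start, others$start[i])
      hi <- min(target$end, others$end[i])
      if (hi > lo) bases[(lo - target$start + 1):(hi - target$start)] <- TRUE
    }
  }
  mean(bases)
}

# Brute-force all-pairs gene overlap oracle (half-open intervals).
brute_gene_hits <- function(call, models) {
  hit <- models$chrom == call$chrom &
    models$gene_start < call$end & models$gene_end > call$start
  models$symbol[hit]
}

mk_signal <- function(lrr, baf = rep(0.5, length(lrr)), chrom = "1",
                      spacing = 1000, sample = "S1", start = spacing) {
  tibble::tibble(
    sample_id = sample, chrom = chrom,
    position = seq(start, by = spacing, length.out = length(lrr)),
    lrr = lrr, baf = baf
  )
}

nominal_metrics <- function(sample_id, n_segments = 5, total_kb = 1000,
                            lrr_sd = 0.1, baf_drift = 0, wf = 0.01, baf_sd = 0.03) {
  tibble::tibble(
    sample_id = sample_id, lrr_sd = lrr_sd, baf_drift = baf_drift,
    wf = wf, baf_sd = baf_sd, n_segments = n_segments, total_kb = total_kb
  )
}
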