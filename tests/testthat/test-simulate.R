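# A small genome (six largest chromosomes at 1/10 scale) keeps
# signal-level runs fast; event sizes stay proportionate so per-sample
# QC behaves as it would genome-wide.
small_genome <- function(...) {
  cl <- round(c("1" = 249250621, "2" = 243199373, "3" = 198022430,
                "4" = 191154276, "5" = 180915260, "6" = 171115067) / 10)
  simulation_config(chrom_lengths = cl, size_max_bp = 1e6, ...)
}

test_that("simulation is deterministic per (seed, trio index) and across repeats", {
  cfg <- small_genome(seed = 4, n_trios = 3)
  a <- simulate_trio(cfg, 2)
  b <- simulate_trio(cfg, 2)
  expect_identical(a, b)
  expect_false(identical(simulate_trio(cfg, 1)$truth, simulate_trio(cfg, 3)$truth))
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$pedigree, co2$pedigree)
})

test_that("zero rates plant nothing and a unit cohort lists three members", {
  cfg <- small_genome(seed = 1, n_trios = 1,
                      denovo_rate_per_offspring = 0, parental_cnv_rate = 0)
  trio <- simulate_trio(cfg, 1)
  expect_equal(nrow(trio$truth), 0)
  expect_length(trio$signals, 3)
  expect_named(trio$signals, c("proband", "mother", "father"))
  co <- simulate_cohort(cfg, signals = TRUE)
  expect_length(co$signals, 3)
  expect_equal(co$manifest$n_denovo_truth, 0)
})

test_that("noise-free emission hits the configured copy-number means exactly", {
  cfg <- small_genome(seed = 6, n_trios = 1, lrr_noise_sd = 0, baf_noise_sd = 0,
                      wave_amplitude = 0, denovo_rate_per_offspring = 1,
                      parental_cnv_rate = 0)
  trio <- simulate_trio(cfg, 1)
  dn <- trio$truth[trio$truth$origin == "de_novo", ]
  expect_equal(nrow(dn), 1)
  sig <- trio$signals$proband
  inside <- sig$chrom == dn$chrom & sig$position >= dn$start & sig$position <= dn$end
  expected_mean <- if (dn$cnv_type == "DEL") -0.66 else 0.4
  expect_equal(mean(sig$lrr[inside]), expected_mean)
  expect_equal(sd(sig$lrr[inside]), 0)
  expect_equal(mean(sig$lrr[!inside]), 0)
  expect_true(all(sig$baf >= 0 & sig$baf <= 1))
})

test_that("truth bookkeeping ties transmitted events to the contributing parent", {
  cfg <- small_genome(seed = 12, n_trios = 30, parental_cnv_rate = 1.5,
                      denovo_rate_per_offspring = 0)
  co <- simulate_cohort(cfg)
  truth <- co$truth
  expect_true(all(truth$origin[truth$member == "mother"] == "maternal"))
  expect_true(all(truth$origin[truth$member == "father"] == "paternal"))
  proband <- truth[truth$member == "proband", ]
  expect_true(all(proband$origin %in% c("maternal", "paternal")))
  # every transmitted proband event matches an identical parental event
  for (i in seq_len(nrow(proband))) {
    ev <- proband[i, ]
    parent_member <- if (ev$origin == "maternal") "mother" else "father"
    match <- truth[truth$trio_id == ev$trio_id & truth$member == parent_member &
                     truth$chrom == ev$chrom & truth$start == ev$start &
                     truth$end == ev$end & truth$cnv_type == ev$cnv_type, ]
    expect_equal(nrow(match), 1)
  }
  # de novo truth only ever appears in probands
  expect_true(all(truth$member[truth$origin == "de_novo"] == "proband"))
})

test_that("planted carrier count behaves binomially over the cohort", {
  cfg <- small_genome(seed = 99, n_trios = 305)
  co <- simulate_cohort(cfg)
  carriers <- dplyr::n_distinct(co$truth$sample_id[co$truth$origin == "de_novo"])
  bounds <- qbinom(c(0.005, 0.995), 305, 0.046)
  expect_gte(carriers, bounds[1])
  expect_lte(carriers, bounds[2])
})

test_that("cohort writing emits pedigree, truth and signal files once", {
  out <- file.path(withr::local_tempdir(), "cohort")
  cfg <- small_genome(seed = 2, n_trios = 1)
  co <- simulate_cohort(cfg, signals = TRUE, out_dir = out)
  files <- list.files(out)
  expect_setequal(files, c("pedigree.tsv", "truth.tsv",
                           paste0("signal_", names(co$signals), ".tsv")))
  expect_length(grep("^signal_", files), 3)
  expect_error(simulate_cohort(cfg, out_dir = out), "already exists")
  ped <- read_pedigree(file.path(out, "pedigree.tsv"))
  expect_equal(nrow(ped), 1)
})

test_that("the naive segmenter recovers noise-free events exactly and ignores flat signal", {
  cfg <- small_genome(seed = 8, n_trios = 1, lrr_noise_sd = 0, baf_noise_sd = 0,
                      wave_amplitude = 0, denovo_rate_per_offspring = 1,
                      parental_cnv_rate = 1)
  trio <- simulate_trio(cfg, 1)
  for (member in c("proband", "mother", "father")) {
    events <- trio$truth[trio$truth$member == member, ]
    calls <- naive_segment(trio$signals[[member]], cfg)
    expect_equal(nrow(calls), nrow(events))
    if (nrow(events) > 0) {
      events <- events[order(chrom_rank(events$chrom), events$start), ]
      expect_equal(calls$start, events$start)
      expect_equal(calls$end, events$end)
      expect_equal(calls$cnv_type, events$cnv_type)
      expect_true(all(calls$confidence >= 10))
    }
  }
  flat <- mk_signal(rep(0, 5000), spacing = 3000)
  expect_equal(nrow(naive_segment(flat, cfg)), 0)
})

test_that("segmentation under noise recovers boundaries within jitter tolerance", {
  # replicated seeded study: events >= 200 kb, noise sd 0.15
  cfg <- simulation_config(
    seed = 14, n_trios = 40, lrr_noise_sd = 0.15, size_max_bp = 1e6,
    denovo_rate_per_offspring = 1, parental_cnv_rate = 0,
    chrom_lengths = round(c("1" = 249250621, "2" = 243199373) / 10)
  )
  hits <- 0L
  total <- 0L
  tol <- 10 * cfg$probe_spacing_bp
  for (i in seq_len(cfg$n_trios)) {
    trio <- simulate_trio(cfg, i)
    dn <- trio$truth[trio$truth$origin == "de_novo", ]
    calls <- naive_segment(trio$signals$proband, cfg)
    calls <- merge_adjacent_calls(calls)
    total <- total + 1L
    match <- calls[calls$chrom == dn$chrom & calls$cnv_type == dn$cnv_type, ]
    if (nrow(match) >= 1 &&
        min(abs(match$start - dn$start)) <= tol &&
        min(abs(match$end - dn$end)) <= tol) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("caller-like calls from truth respect jitter bounds and survive filters", {
  cfg <- small_genome(seed = 21, n_trios = 50)
  co <- simulate_cohort(cfg)
  calls <- calls_from_truth(co$truth, cfg)
  expect_equal(nrow(calls), nrow(co$truth))
  max_shift <- cfg$boundary_jitter_probes * cfg$probe_spacing_bp
  expect_true(all(abs(calls$start - co$truth$start) <= max_shift))
  expect_true(all(abs(calls$end - co$truth$end) <= max_shift))
  outcome <- filter_calls(calls)
  expect_true(all(outcome$retained))
})
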