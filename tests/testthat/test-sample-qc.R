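test_that("LRR-SD is the population SD and flags noisy arrays", {
  expect_equal(compute_lrr_sd(mk_signal(rep(0, 1000))), 0)
  # closed form: population SD of alternating {-0.1, 0.1} is exactly 0.1
  expect_equal(compute_lrr_sd(mk_signal(rep(c(-0.1, 0.1), 500))), 0.1)
  expect_error(compute_lrr_sd(mk_signal(0)), "at least 2")
  # estimator consistency: sigma = 0.35 must exceed the 0.3 cutoff at n = 10000
  set.seed(42)
  noisy <- mk_signal(rnorm(10000, 0, 0.35))
  expect_gt(compute_lrr_sd(noisy), 0.3)
})

test_that("BAF drift counts probes displaced off the canonical bands", {
  canonical <- mk_signal(rep(0, 300), baf = rep(c(0, 0.5, 1), 100))
  expect_equal(compute_baf_drift(canonical), 0)
  two_of_hundred <- mk_signal(rep(0, 100), baf = c(rep(0.22, 2), rep(0.5, 98)))
  expect_equal(compute_baf_drift(two_of_hundred), 0.02)
  expect_equal(compute_baf_drift(mk_signal(rep(0, 50), baf = rep(0.78, 50))), 1)
  # interval ends are exclusive: 0.25 and 0.75 themselves do not drift
  expect_equal(compute_baf_drift(mk_signal(rep(0, 4), baf = c(0.20, 0.25, 0.75, 0.80))), 0)
})

test_that("waviness factor detects long-range waves but not flat or noisy-flat signal", {
  spacing <- 3000
  n <- 4000                                   # 12 Mb of probes
  pos <- seq(spacing, by = spacing, length.out = n)
  flat <- mk_signal(rep(0, n), spacing = spacing)
  expect_equal(compute_waviness_factor(flat), 0)

  wave_lrr <- 0.2 * sin(2 * pi * pos / 8e6)
  wave <- mk_signal(wave_lrr, spacing = spacing)
  wf_clean <- compute_waviness_factor(wave)
  expect_gt(wf_clean, 0.05)

  # robustness: zero-mean per-probe noise moves window medians very little
  set.seed(7)
  noisy <- mk_signal(wave_lrr + rnorm(n, 0, 0.15), spacing = spacing)
  expect_lt(abs(compute_waviness_factor(noisy) - wf_clean), 0.01)

  expect_error(compute_waviness_factor(mk_signal(rep(0, 5))), "no window")
})

test_that("BAF-SD is computed on the heterozygous band only", {
  expect_equal(compute_baf_sd(mk_signal(rep(0, 100), baf = rep(0.5, 100))), 0)
  # closed form: balanced {0.45, 0.55} has population SD 0.05
  het <- mk_signal(rep(0, 100), baf = rep(c(0.45, 0.55), 50))
  expect_equal(compute_baf_sd(het), 0.05)
  # homozygous probes are excluded
  mixed <- mk_signal(rep(0, 200), baf = c(rep(c(0.45, 0.55), 50), rep(0, 100)))
  expect_equal(compute_baf_sd(mixed), 0.05)
  expect_error(compute_baf_sd(mk_signal(rep(0, 3), baf = c(0, 1, 0))), "heterozygous")
  # seeded simulation: band noise sigma = 0.07 exceeds the 0.063 cutoff
  set.seed(11)
  noisy <- mk_signal(rep(0, 20000), baf = pmin(1, pmax(0, 0.5 + rnorm(20000, 0, 0.07))))
  expect_gt(compute_baf_sd(noisy), 0.063)
})

test_that("sample metrics aggregate signal and call-load values", {
  sig <- mk_signal(rep(c(-0.05, 0.05), 3000), baf = rep(c(0, 0.5, 1), 2000))
  none <- mk_calls(numeric(), numeric())
  m0 <- compute_sample_metrics(sig, none, sample_id = "S1")
  expect_equal(m0$n_segments, 0)
  expect_equal(m0$total_kb, 0)

  one <- mk_calls(15493046, 16251647, chrom = "16", type = "DUP")
  m1 <- compute_sample_metrics(sig, one, sample_id = "S1")
  expect_equal(m1$total_kb, 758.601)

  # the whole fixture treated as one sample's load
  fixture_calls <- load_table1_fixture()$calls
  fixture_calls$sample_id <- "S1"
  mf <- compute_sample_metrics(sig, fixture_calls, sample_id = "S1")
  expect_equal(mf$n_segments, 14)
  expect_equal(mf$total_kb, 16251.249)

  expect_error(compute_sample_metrics(sig, one, sample_id = "other"), "different sample")
})

test_that("sample filters exclude on signal rules for all, load rules for probands only", {
  roles <- c(p1 = "proband", p2 = "proband", m1 = "mother", f1 = "father")
  metrics <- dplyr::bind_rows(
    nominal_metrics("p1", n_segments = 60),
    nominal_metrics("p2", lrr_sd = 0.31, baf_drift = 0.02),
    nominal_metrics("m1", n_segments = 60, total_kb = 20000, baf_sd = 0.1),
    nominal_metrics("f1", wf = 0.06)
  )
  dec <- apply_sample_filters(metrics, roles)
  expect_equal(dec$kept, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(dec$reasons[1], "n_segments")
  expect_setequal(strsplit(dec$reasons[2], ";")[[1]], c("lrr_sd", "baf_drift"))
  expect_equal(dec$reasons[3], "")      # load rules never touch a parent
  expect_equal(dec$reasons[4], "wf")
  expect_true(all(dec$kept == (dec$reasons == "")))
  expect_error(apply_sample_filters(metrics, c(p1 = "proband")), "known role")
})

test_that("recompute outlier mode screens at mean + 4 SD of the proband distribution", {
  set.seed(3)
  seg <- c(rnorm(30, 20, 5), 60)
  ids <- sprintf("p%02d", seq_along(seg))
  metrics <- nominal_metrics(ids, n_segments = seg)
  roles <- stats::setNames(rep("proband", length(ids)), ids)
  cutoff <- mean(seg) + 4 * sd(seg)          # independent closed form
  dec <- apply_sample_filters(metrics, roles, outlier_mode = "recompute")
  expect_equal(dec$kept, !(seg > cutoff))
  expect_false(dec$kept[length(seg)])
})

test_that("sample filtering is monotone in every threshold", {
  set.seed(19)
  n <- 40
  metrics <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    lrr_sd = runif(n, 0, 0.5), baf_drift = runif(n, 0, 0.03),
    wf = runif(n, 0, 0.1), baf_sd = runif(n, 0, 0.1),
    n_segments = sample(0:80, n, replace = TRUE),
    total_kb = runif(n, 0, 25000)
  )
  roles <- stats::setNames(rep(c("proband", "mother"), n / 2), metrics$sample_id)
  base <- apply_sample_filters(metrics, roles)
  for (field in c("lrr_sd_max", "baf_drift_max", "wf_max")) {
    tighter <- pipeline_config()
    tighter[[field]] <- tighter[[field]] / 2
    dec <- apply_sample_filters(metrics, roles, tighter)
    expect_true(all(dec$kept <= base$kept), info = field)
  }
  tighter <- pipeline_config(fixed_outlier_cutoffs = list(
    n_segments = 10, total_kb = 1000, baf_sd = 0.01))
  dec <- apply_sample_filters(metrics, roles, tighter)
  expect_true(all(dec$kept <= base$kept))
})

test_that("only trios with all three members kept survive", {
  trios <- trio_table(c("t1", "t2"), c("p1", "p2"), c("m1", "m2"),
                      c("f1", "f2"), c("M", "F"), c(80, 90))
  dec <- tibble::tibble(
    sample_id = c("p1", "m1", "f1", "p2", "m2", "f2"),
    kept = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    reasons = c("", "", "", "", "lrr_sd", "")
  )
  kept <- complete_trios(trios, dec)
  expect_equal(kept$trio_id, "t1")
  all_kept <- dec
  all_kept$kept <- TRUE
  expect_equal(nrow(complete_trios(trios, all_kept)), 2)
  expect_warning(none <- complete_trios(trios, dec[0, ]), "lack a QC decision")
  expect_equal(nrow(none), 0)
})
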