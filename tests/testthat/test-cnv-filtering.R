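test_that("adjacent same-type calls merge exactly when the gap rule says so", {
  # gap 10,000 < 0.5 * (100,000 + 90,000): merge
  pair <- mk_calls(c(1000000, 1110000), c(1100000, 1200000), n_probes = c(50L, 40L),
                   confidence = c(30, 20))
  merged <- merge_adjacent_calls(pair)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1000000)
  expect_equal(merged$end, 1200000)
  expect_equal(merged$n_probes, 90L)
  expect_equal(merged$confidence, 20)    # min of the pair
  expect_equal(merged$source, "merged")

  # gap 100,000 >= 0.5 * (100,000 + 90,000): keep apart
  apart <- mk_calls(c(1000000, 1200000), c(1100000, 1290000))
  expect_equal(nrow(merge_adjacent_calls(apart)), 2)

  # single call untouched; different chromosomes and types never merge
  single <- mk_calls(1000000, 1100000)
  expect_equal(merge_adjacent_calls(single), single)
  cross <- dplyr::bind_rows(
    mk_calls(1000000, 1100000, chrom = "1"),
    mk_calls(1110000, 1200000, chrom = "2")
  )
  expect_equal(nrow(merge_adjacent_calls(cross)), 2)
  mixed <- dplyr::bind_rows(
    mk_calls(1000000, 1100000, type = "DEL"),
    mk_calls(1110000, 1200000, type = "DUP")
  )
  expect_equal(nrow(merge_adjacent_calls(mixed)), 2)
})

test_that("overlapping same-type calls always merge; conflicting overlap warns", {
  overlapping <- mk_calls(c(1000000, 1050000), c(1100000, 1150000))
  expect_equal(nrow(merge_adjacent_calls(overlapping)), 1)
  conflict <- dplyr::bind_rows(
    mk_calls(1000000, 1100000, type = "DEL"),
    mk_calls(1050000, 1150000, type = "DUP")
  )
  expect_warning(out <- merge_adjacent_calls(conflict), "both kept")
  expect_equal(nrow(out), 2)
})

test_that("merging cascades to a fixed point and is idempotent, conserving probes", {
  # B-C merge first, and the merged call then absorbs A
  chain <- mk_calls(c(0, 200000, 220000) + 1, c(100000, 210000, 400000) + 1,
                    n_probes = c(30L, 5L, 60L))
  merged <- merge_adjacent_calls(chain)
  expect_equal(nrow(merged), 1)
  expect_equal(sum(merged$n_probes), sum(chain$n_probes))

  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    starts <- sort(sample.int(5e6, n))
    lens <- sample.int(3e5, n)
    calls <- mk_calls(starts, starts + lens,
                      type = sample(c("DEL", "DUP"), n, replace = TRUE),
                      n_probes = sample.int(500L, n))
    merged <- suppressWarnings(merge_adjacent_calls(calls))
    again <- suppressWarnings(merge_adjacent_calls(merged))
    expect_equal(again, merged)
    expect_equal(sum(merged$n_probes), sum(calls$n_probes))
    # no surviving same-type pair still violates the merge criterion
    by_grp <- split(merged, paste(merged$chrom, merged$cnv_type))
    for (grp in by_grp) {
      if (nrow(grp) < 2) next
      grp <- grp[order(grp$start), ]
      gap <- grp$start[-1] - grp$end[-nrow(grp)]
      combined <- cnv_length(grp)[-1] + cnv_length(grp)[-nrow(grp)]
      expect_true(all(gap >= 0.5 * combined))
    }
  }
})

test_that("CNV-level filters fail calls for every violated rule", {
  config <- pipeline_config()
  calls <- dplyr::bind_rows(
    mk_calls(15493046, 16251647, chrom = "16", type = "DUP",
             n_probes = 426L, confidence = 85.57),        # fixture row: retained
    mk_calls(1000000, 1100000, n_probes = 9L),            # too few probes
    mk_calls(1000000, 1040000, n_probes = 20L),           # too short
    mk_calls(1000000, 1300000, n_probes = 10L),           # 30 kb/probe: sparse
    mk_calls(1000000, 1300000, n_probes = 100L, confidence = 9.99),
    mk_calls(1000000, 1030000, n_probes = 1L, confidence = 2)   # fails everything
  )
  out <- filter_calls(calls, config)
  expect_equal(out$retained,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reasons[2], "min_probes")
  expect_equal(out$reasons[3], "min_size")
  expect_equal(out$reasons[4], "density")
  expect_equal(out$reasons[5], "confidence")
  expect_setequal(strsplit(out$reasons[6], ";")[[1]],
                  c("min_probes", "min_size", "density", "confidence"))
  expect_true(all(out$retained == (out$reasons == "")))
  expect_equal(nrow(retained_calls(out)), 1)
})

test_that("unknown confidence skips the rule with a warning, errors in strict mode", {
  call <- mk_calls(1000000, 1300000, n_probes = 100L, confidence = NA)
  expect_warning(out <- filter_calls(call), "confidence rule skipped")
  expect_true(out$retained)
  expect_error(filter_calls(call, pipeline_config(strict_confidence = TRUE)),
               "strict_confidence")
})

test_that("all fixture calls pass the CNV-level filters and the 200 kb retention", {
  fixture <- load_table1_fixture()
  out <- filter_calls(fixture$calls)
  expect_true(all(out$retained))
  expect_lte(max(cnv_length(fixture$calls) / fixture$calls$n_probes), 20000)
  kept <- apply_size_retention(fixture$calls)
  expect_equal(nrow(kept), 14)
  expect_equal(min(cnv_length(kept)), 233244)
})

test_that("size retention is strictly greater-than and independent of filter order", {
  calls <- mk_calls(c(0, 0, 0) + 1, c(200000, 200001, 233244) + 1, n_probes = 100L)
  kept <- apply_size_retention(calls)
  expect_equal(cnv_length(kept), c(200001, 233244) + 1 - 1)
  # exactly 200,000 is dropped
  exact <- mk_calls(100000, 300000)
  expect_equal(nrow(apply_size_retention(exact)), 0)

  # per-call rules commute: retention(filter(x)) == filter(retention(x))
  set.seed(55)
  pool <- mk_calls(
    start = sample.int(1e6, 30),
    end = sample.int(1e6, 30) + 1e6,
    n_probes = sample(5:200, 30, replace = TRUE),
    confidence = sample(c(NA, 5, 50), 30, replace = TRUE)
  )
  a <- apply_size_retention(retained_calls(suppressWarnings(filter_calls(pool))))
  b <- retained_calls(suppressWarnings(filter_calls(apply_size_retention(pool))))
  expect_equal(dplyr::arrange(a, start), dplyr::arrange(b, start))
})

test_that("filtering is monotone in each threshold", {
  set.seed(77)
  starts <- sample.int(1e6, 40)
  pool <- mk_calls(
    start = starts,
    end = starts + sample.int(5e5, 40),
    n_probes = sample(5:60, 40, replace = TRUE),
    confidence = runif(40, 0, 40)
  )
  base <- filter_calls(pool)
  for (field in list(c("min_probes", 2), c("min_length_bp", 2),
                     c("min_confidence", 2))) {
    cfg <- pipeline_config()
    cfg[[field[1]]] <- cfg[[field[1]]] * as.numeric(field[2])
    out <- filter_calls(pool, cfg)
    expect_true(all(out$retained <= base$retained), info = field[1])
  }
  cfg <- pipeline_config(max_bp_per_probe = 10000)
  expect_true(all(filter_calls(pool, cfg)$retained <= base$retained))
})
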