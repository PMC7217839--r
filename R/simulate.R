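# hg19 autosome lengths (bp); the default simulated genome is these
# scaled to one tenth so a full cohort simulates in seconds.
HG19_AUTOSOME_BP <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566
)

#' Configuration of the synthetic trio generator
#'
#' The generator plants inherited and de novo CNVs in parent-offspring
#' trios and (optionally) emits probe-level LRR/BAF signals, so every
#' pipeline stage can be validated against known truth. Defaults emulate
#' the study conditions the packaged fixtures come from: a de novo rate
#' of 0.046 per offspring (one Bernoulli event, so the carrier count is
#' Binomial(n_trios, rate)), a 10/14 deletion fraction, and event sizes
#' log-uniform between 200 kb and 4 Mb. LRR emission means per copy
#' number follow conventional SNP-array values (CN0 −3.5, CN1 −0.66,
#' CN2 0, CN3 0.4, CN4 0.68). Event boundaries snap to the probe grid so
#' a noise-free segmentation recovers them exactly.
#'
#' @param seed master seed; per-trio streams are derived from it
#' @param n_trios number of trios
#' @param ... overrides for any field: `chrom_lengths` (named bp map;
#'   default autosomes at 1/10 hg19 scale), `probe_spacing_bp` (3000),
#'   `denovo_rate_per_offspring` (0.046), `parental_cnv_rate` (Poisson
#'   mean large-CNV count per parent per genome, 0.8),
#'   `transmission_prob` (0.5), `del_fraction` (10/14), `size_min_bp` /
#'   `size_max_bp` (200 kb / 4 Mb, log-uniform), `lrr_means`,
#'   `lrr_noise_sd` (0.15), `baf_noise_sd` (0.03), `wave_amplitude`
#'   (0.01), `wave_period_bp` (8 Mb), `boundary_jitter_probes` (2), and
#'   the naive-segmenter settings `segment_min_probes` (10),
#'   `segment_del_lrr` (−0.3), `segment_dup_lrr` (0.25),
#'   `segment_smooth_probes` (5)
#' @return a named list (class `simulation_config`)
#' @export
simulation_config <- function(seed = 1, n_trios = 10, ...) {
  config <- list(
    seed = seed,
    n_trios = n_trios,
    chrom_lengths = round(HG19_AUTOSOME_BP / 10),
    probe_spacing_bp = 3000,
    denovo_rate_per_offspring = 0.046,
    parental_cnv_rate = 0.8,
    transmission_prob = 0.5,
    del_fraction = 10 / 14,
    size_min_bp = 2e5,
    size_max_bp = 4e6,
    lrr_means = c("0" = -3.5, "1" = -0.66, "2" = 0, "3" = 0.4, "4" = 0.68),
    lrr_noise_sd = 0.15,
    baf_noise_sd = 0.03,
    wave_amplitude = 0.01,
    wave_period_bp = 8e6,
    boundary_jitter_probes = 2,
    segment_min_probes = 10,
    segment_del_lrr = -0.3,
    segment_dup_lrr = 0.25,
    segment_smooth_probes = 5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    abort(paste0("unknown simulation_config field(s): ", paste(unknown, collapse = ", ")))
  }
  config[names(overrides)] <- overrides
  for (f in c("denovo_rate_per_offspring", "transmission_prob", "del_fraction")) {
    if (config[[f]] < 0 || config[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  if (config$probe_spacing_bp <= 0) abort("probe_spacing_bp must be positive")
  if (config$size_min_bp >= config$size_max_bp) abort("size_min_bp must be below size_max_bp")
  if (config$size_max_bp > min(config$chrom_lengths)) {
    abort("size_max_bp exceeds the shortest chromosome")
  }
  structure(config, class = "simulation_config")
}

probe_positions <- function(config, chrom) {
  L <- config$chrom_lengths[[chrom]]
  sp <- config$probe_spacing_bp
  seq(sp, by = sp, length.out = floor(L / sp))
}

# Draw one CNV event snapped to the probe grid, avoiding overlap with
# the intervals already planted in the same genome. Events longer than a
# chromosome cannot arise (size_max_bp is validated against the shortest
# chromosome); overlap collisions are resampled.
draw_event <- function(config, existing) {
  chroms <- names(config$chrom_lengths)
  weights <- as.numeric(config$chrom_lengths)
  sp <- config$probe_spacing_bp
  for (try in 1:100) {
    chrom <- sample(chroms, 1, prob = weights)
    size <- exp(runif(1, log(config$size_min_bp), log(config$size_max_bp)))
    m <- round(size / sp) + 1           # probes covered
    n_chr <- floor(config$chrom_lengths[[chrom]] / sp)
    if (m >= n_chr) next
    i0 <- sample.int(n_chr - m + 1, 1)
    start <- i0 * sp
    end <- (i0 + m - 1) * sp
    clash <- existing$chrom == chrom & existing$start < end & existing$end > start
    if (!any(clash)) {
      type <- if (runif(1) < config$del_fraction) "DEL" else "DUP"
      return(tibble::tibble(chrom = chrom, start = start, end = end,
                            cnv_type = type))
    }
  }
  abort("could not place a simulated CNV without overlap after 100 tries")
}

empty_events <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 cnv_type = character())
}

#' Simulate one parent-offspring trio
#'
#' Deterministic given `(config$seed, trio_index)`. Parental CNVs are
#' drawn per parent (Poisson count), each transmitted to the offspring
#' with the configured probability; a de novo event is planted in the
#' offspring per the de novo rate. With `signals = TRUE` probe-level
#' LRR/BAF tables are emitted for all three members: LRR is
#' Normal(mean\[CN\], `lrr_noise_sd`) plus a sinusoidal genomic wave, and
#' BAF is drawn from the CN-appropriate genotype bands (CN1: 0/1; CN2:
#' 0, 1/2, 1; CN3: 0, 1/3, 2/3, 1) plus noise, clipped to \[0, 1\].
#'
#' @param config a [simulation_config()]
#' @param trio_index positive integer identifying the trio stream
#' @param signals emit probe-level signals?
#' @return list with `trio_id`, `members` (named sample ids), `truth`
#'   (planted-event table with per-member rows and origins) and `signals`
#'   (named list of probe tables, or `NULL`)
#' @export
simulate_trio <- function(config, trio_index, signals = TRUE) {
  trio_id <- sprintf("S%04d", trio_index)
  members <- c(proband = paste0(trio_id, "_p"),
               mother = paste0(trio_id, "_m"),
               father = paste0(trio_id, "_f"))
  with_rng(derive_seed(config$seed, trio_index), {
    truth <- list()
    proband_events <- empty_events()
    for (parent in c("mother", "father")) {
      n_ev <- rpois(1, config$parental_cnv_rate)
      own <- empty_events()
      if (n_ev > 0) {
        for (k in seq_len(n_ev)) own <- dplyr::bind_rows(own, draw_event(config, own))
      }
      origin <- if (parent == "mother") "maternal" else "paternal"
      if (nrow(own) > 0) {
        truth[[length(truth) + 1]] <- tibble::tibble(
          trio_id = trio_id, member = parent, sample_id = members[[parent]],
          chrom = own$chrom, start = own$start, end = own$end,
          cnv_type = own$cnv_type, origin = origin
        )
        transmitted <- own[rbinom(nrow(own), 1, config$transmission_prob) == 1, , drop = FALSE]
        if (nrow(transmitted) > 0) {
          keep <- !vapply(seq_len(nrow(transmitted)), function(j) {
            any(proband_events$chrom == transmitted$chrom[j] &
                  proband_events$start < transmitted$end[j] &
                  proband_events$end > transmitted$start[j])
          }, logical(1))
          transmitted <- transmitted[keep, , drop = FALSE]
        }
        if (nrow(transmitted) > 0) {
          proband_events <- dplyr::bind_rows(proband_events, transmitted)
          truth[[length(truth) + 1]] <- tibble::tibble(
            trio_id = trio_id, member = "proband", sample_id = members[["proband"]],
            chrom = transmitted$chrom, start = transmitted$start,
            end = transmitted$end, cnv_type = transmitted$cnv_type, origin = origin
          )
        }
      }
    }
    if (rbinom(1, 1, config$denovo_rate_per_offspring) == 1) {
      dn <- draw_event(config, proband_events)
      proband_events <- dplyr::bind_rows(proband_events, dn)
      truth[[length(truth) + 1]] <- tibble::tibble(
        trio_id = trio_id, member = "proband", sample_id = members[["proband"]],
        chrom = dn$chrom, start = dn$start, end = dn$end,
        cnv_type = dn$cnv_type, origin = "de_novo"
      )
    }
    truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else tibble::tibble(
      trio_id = character(), member = character(), sample_id = character(),
      chrom = character(), start = numeric(), end = numeric(),
      cnv_type = character(), origin = character()
    )
    sig <- NULL
    if (signals) {
      sig <- lapply(names(members), function(member) {
        emit_signal(config, members[[member]],
                    truth[truth$member == member, , drop = FALSE])
      })
      names(sig) <- names(members)
    }
    list(trio_id = trio_id, members = members, truth = truth, signals = sig)
  })
}

emit_signal <- function(config, sample_id, events) {
  per_chrom <- lapply(names(config$chrom_lengths), function(chrom) {
    pos <- probe_positions(config, chrom)
    cn <- rep(2L, length(pos))
    ev <- events[events$chrom == chrom, , drop = FALSE]
    if (nrow(ev) > 0) {
      for (j in seq_len(nrow(ev))) {
        inside <- pos >= ev$start[j] & pos <= ev$end[j]
        cn[inside] <- if (ev$cnv_type[j] == "DEL") 1L else 3L
      }
    }
    mu <- config$lrr_means[as.character(cn)]
    wave <- config$wave_amplitude * sin(2 * pi * pos / config$wave_period_bp)
    lrr <- mu + wave + rnorm(length(pos), 0, config$lrr_noise_sd)
    baf <- baf_bands(cn) + rnorm(length(pos), 0, config$baf_noise_sd)
    tibble::tibble(
      sample_id = sample_id, chrom = chrom, position = pos,
      lrr = as.numeric(lrr), baf = pmin(1, pmax(0, baf))
    )
  })
  dplyr::bind_rows(per_chrom)
}

# Genotype-band BAF centres per copy number (allele ratios drawn with
# conventional genotype frequencies; haplotype sharing is not modelled).
baf_bands <- function(cn) {
  out <- numeric(length(cn))
  for (state in unique(cn)) {
    idx <- which(cn == state)
    bands <- switch(as.character(state),
      "1" = list(v = c(0, 1), p = c(0.5, 0.5)),
      "3" = list(v = c(0, 1 / 3, 2 / 3, 1), p = c(0.3, 0.2, 0.2, 0.3)),
      list(v = c(0, 0.5, 1), p = c(0.3, 0.4, 0.3))
    )
    out[idx] <- sample(bands$v, length(idx), replace = TRUE, prob = bands$p)
  }
  out
}

#' Simulate a trio cohort
#'
#' Runs [simulate_trio()] over `n_trios` deterministic per-trio streams
#' and assembles the cohort pedigree (11.8% female probands, IQ drawn
#' around the cohort mean with ~7% missing) and the planted-truth table.
#' With an `out_dir`, pedigree, truth and (if generated) per-sample
#' signal TSVs are written; the directory must not already exist.
#'
#' @param config a [simulation_config()]
#' @param signals emit probe-level signals for every member? (memory-
#'   intensive at full cohort scale; call-level studies can leave this
#'   off and derive caller-like calls with [calls_from_truth()])
#' @param out_dir optional output directory
#' @return list with `pedigree`, `truth`, `signals` (named by sample id,
#'   or `NULL`) and `manifest` (record counts)
#' @export
simulate_cohort <- function(config, signals = FALSE, out_dir = NULL) {
  if (config$n_trios < 1) abort("n_trios must be at least 1")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir)) abort(paste0("output directory already exists: ", out_dir))
    dir.create(out_dir, recursive = TRUE)
  }
  trios <- lapply(seq_len(config$n_trios), function(i) {
    simulate_trio(config, i, signals = signals)
  })
  truth <- dplyr::bind_rows(lapply(trios, `[[`, "truth"))
  pedigree <- with_rng(derive_seed(config$seed, 0L), {
    ids <- vapply(trios, `[[`, character(1), "trio_id")
    members <- t(vapply(trios, `[[`, character(3), "members"))
    iq <- rnorm(length(ids), 85, 13.5)
    iq[runif(length(ids)) < 0.07] <- NA
    trio_table(
      trio_id = ids, proband_id = members[, 1],
      mother_id = members[, 2], father_id = members[, 3],
      proband_sex = ifelse(runif(length(ids)) < 0.118, "F", "M"),
      proband_iq = iq
    )
  })
  sig <- NULL
  if (signals) {
    sig <- unlist(lapply(trios, `[[`, "signals"), recursive = FALSE)
    names(sig) <- unlist(lapply(trios, function(t) unname(t$members)))
  }
  manifest <- list(
    n_trios = config$n_trios,
    n_samples = 3L * config$n_trios,
    n_truth_records = nrow(truth),
    n_denovo_truth = sum(truth$origin == "de_novo"),
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    readr::write_tsv(
      tibble::tibble(
        trio_id = pedigree$trio_id, proband_id = pedigree$proband_id,
        mother_id = pedigree$mother_id, father_id = pedigree$father_id,
        sex = pedigree$proband_sex, iq = pedigree$proband_iq
      ),
      file.path(out_dir, "pedigree.tsv"), progress = FALSE
    )
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
    if (!is.null(sig)) {
      for (id in names(sig)) {
        readr::write_tsv(sig[[id]], file.path(out_dir, paste0("signal_", id, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  list(pedigree = pedigree, truth = truth, signals = sig, manifest = manifest)
}

#' Derive caller-like call sets from planted truth
#'
#' Converts every planted event into a call with boundary jitter of up
#' to `boundary_jitter_probes` probes on each side, a probe count from
#' the grid and a synthetic confidence (|LRR shift| x probe count) —
#' emulating the output of an external caller without simulating
#' signals. Deterministic given the simulation seed.
#'
#' @param truth planted-truth table from [simulate_cohort()]
#' @param config the [simulation_config()] that produced it
#' @return a call table with `source = "simulated"`
#' @export
calls_from_truth <- function(truth, config) {
  if (nrow(truth) == 0) {
    return(cnv_calls(character(), character(), numeric(), numeric(), character()))
  }
  sp <- config$probe_spacing_bp
  J <- config$boundary_jitter_probes
  with_rng(derive_seed(config$seed, 10^6), {
    j1 <- if (J > 0) sample(-J:J, nrow(truth), replace = TRUE) else rep(0L, nrow(truth))
    j2 <- if (J > 0) sample(-J:J, nrow(truth), replace = TRUE) else rep(0L, nrow(truth))
    start <- pmax(sp, truth$start + j1 * sp)
    end <- truth$end + j2 * sp
    end <- pmax(end, start + sp)
    n_probes <- as.integer((end - start) / sp) + 1L
    cn <- ifelse(truth$cnv_type == "DEL", 1L, 3L)
    shift <- abs(config$lrr_means[as.character(cn)])
    cnv_calls(
      sample_id = truth$sample_id, chrom = truth$chrom,
      start = start, end = end, cnv_type = truth$cnv_type,
      copy_number = cn, n_probes = n_probes,
      confidence = round(shift * n_probes, 2), source = "simulated"
    )
  })
}

#' Naive threshold segmentation (test double for the external caller)
#'
#' A deliberately simple segmenter standing in for the external HMM
#' caller, which is consumed as input in real use and out of scope here.
#' LRR is median-smoothed (window `segment_smooth_probes`), then runs of
#' at least `segment_min_probes` consecutive probes below
#' `segment_del_lrr` become DEL calls and runs above `segment_dup_lrr`
#' DUP calls, with boundaries at the run's probe positions and `n_probes`
#' the run length. The confidence score is the Gaussian log-likelihood
#' ratio of the run's mean shift, `n * mean(lrr)^2 / (2 * sigma^2)` with
#' `sigma` estimated robustly from the sample's probe-to-probe LRR
#' differences — the quantity an HMM caller's per-call score
#' approximates. It is not a PennCNV reimplementation.
#'
#' @param signal probe signal tibble for one sample
#' @param config a [simulation_config()] carrying the segmenter settings
#' @return a call table (possibly empty)
#' @export
naive_segment <- function(signal, config = simulation_config()) {
  # robust per-sample noise level; floored so a noise-free signal still
  # yields finite scores
  sigma <- max(stats::mad(diff(signal$lrr)) / sqrt(2), 0.01)
  out <- lapply(split(signal, signal$chrom), function(chr) {
    chr <- chr[order(chr$position), , drop = FALSE]
    lrr <- chr$lrr
    k <- config$segment_smooth_probes
    if (k > 1 && length(lrr) >= k) lrr <- stats::runmed(lrr, k)
    state <- ifelse(lrr < config$segment_del_lrr, -1L,
                    ifelse(lrr > config$segment_dup_lrr, 1L, 0L))
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values != 0L & runs$lengths >= config$segment_min_probes
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    tibble::tibble(
      sample_id = chr$sample_id[1],
      chrom = chr$chrom[1],
      start = chr$position[starts[idx]],
      end = chr$position[ends[idx]],
      cnv_type = ifelse(runs$values[idx] < 0, "DEL", "DUP"),
      copy_number = NA_integer_,
      n_probes = as.integer(runs$lengths[idx]),
      confidence = vapply(idx, function(r) {
        runs$lengths[r] * mean(chr$lrr[starts[r]:ends[r]])^2 / (2 * sigma^2)
      }, numeric(1)),
      source = "called"
    )
  })
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    return(cnv_calls(character(), character(), numeric(), numeric(), character()))
  }
  arrange_calls(calls)
}

#' Simulate a cohort and run the full pipeline against the planted truth
#'
#' The end-to-end validation loop: simulate a cohort, obtain caller-like
#' calls (`mode = "signal"`: probe signals through [naive_segment()];
#' `mode = "calls"`: [calls_from_truth()] with boundary jitter), then
#' merge, filter, apply sample QC (signal mode), retain proband calls
#' above 200 kb, classify against parents and estimate the de novo
#' carrier rate — and compare everything to the planted truth.
#'
#' A candidate matches a planted de novo event when it is the same
#' proband and type and covers at least half of the planted interval.
#'
#' @param config a [simulation_config()]
#' @param mode `"calls"` (fast, call-level) or `"signal"` (probe-level)
#' @param pipeline pipeline thresholds, a [pipeline_config()]
#' @return list: `report` (rate report), `estimated_carrier_rate_pct`,
#'   `truth_carrier_rate_pct`, `sensitivity`, `n_false_discoveries`,
#'   `n_trios`, `candidates`, `truth`
#' @export
end_to_end_recovery <- function(config, mode = c("calls", "signal"),
                                pipeline = pipeline_config()) {
  mode <- match.arg(mode)
  cohort <- simulate_cohort(config, signals = (mode == "signal"))
  pedigree <- cohort$pedigree

  raw_calls <- if (mode == "signal") {
    dplyr::bind_rows(lapply(cohort$signals, naive_segment, config = config))
  } else {
    calls_from_truth(cohort$truth, config)
  }

  # per-sample merge, then CNV-level filters
  merged <- if (nrow(raw_calls) == 0) raw_calls else {
    raw_calls |>
      dplyr::group_split(.data$sample_id) |>
      lapply(merge_adjacent_calls, config = pipeline) |>
      dplyr::bind_rows()
  }
  filtered <- retained_calls(filter_calls(merged, pipeline))

  roles <- c(
    stats::setNames(rep("proband", nrow(pedigree)), pedigree$proband_id),
    stats::setNames(rep("mother", nrow(pedigree)), pedigree$mother_id),
    stats::setNames(rep("father", nrow(pedigree)), pedigree$father_id)
  )
  if (mode == "signal") {
    metrics <- dplyr::bind_rows(lapply(names(cohort$signals), function(id) {
      compute_sample_metrics(cohort$signals[[id]],
                             filtered[filtered$sample_id == id, , drop = FALSE],
                             sample_id = id)
    }))
    decisions <- apply_sample_filters(metrics, roles, pipeline)
    surviving <- complete_trios(pedigree, decisions)
  } else {
    surviving <- pedigree
  }

  is_proband <- filtered$sample_id %in% surviving$proband_id
  analysis_calls <- dplyr::bind_rows(
    apply_size_retention(filtered[is_proband, , drop = FALSE], pipeline),
    filtered[!is_proband, , drop = FALSE]
  )
  candidates <- denovo_candidates(analysis_calls, surviving, pipeline)
  report <- mutation_rate(candidates, n_trios = nrow(surviving))

  planted <- cohort$truth[cohort$truth$origin == "de_novo" &
                            cohort$truth$sample_id %in% surviving$proband_id, , drop = FALSE]
  matched <- vapply(seq_len(nrow(planted)), function(i) {
    ev <- planted[i, ]
    cand <- candidates[candidates$sample_id == ev$sample_id &
                         candidates$chrom == ev$chrom &
                         candidates$cnv_type == ev$cnv_type, , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    cov <- pmax(0, pmin(cand$end, ev$end) - pmax(cand$start, ev$start)) /
      (ev$end - ev$start)
    any(cov >= 0.5)
  }, logical(1))
  false_disc <- if (nrow(candidates) == 0) 0L else {
    sum(!vapply(seq_len(nrow(candidates)), function(i) {
      cand <- candidates[i, ]
      ev <- planted[planted$sample_id == cand$sample_id &
                      planted$chrom == cand$chrom &
                      planted$cnv_type == cand$cnv_type, , drop = FALSE]
      if (nrow(ev) == 0) return(FALSE)
      cov <- pmax(0, pmin(cand$end, ev$end) - pmax(cand$start, ev$start)) /
        (ev$end - ev$start)
      any(cov >= 0.5)
    }, logical(1)))
  }

  list(
    report = report,
    estimated_carrier_rate_pct = report$carrier_rate_pct,
    truth_carrier_rate_pct = round_half_up(
      100 * dplyr::n_distinct(planted$sample_id) / max(1, nrow(surviving)), 1),
    sensitivity = if (nrow(planted) == 0) NA_real_ else mean(matched),
    n_false_discoveries = false_disc,
    n_trios = nrow(surviving),
    candidates = candidates,
    truth = cohort$truth
  )
}
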