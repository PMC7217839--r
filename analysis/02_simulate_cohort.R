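#!/usr/bin/env Rscript

# Simulates a synthetic 305-trio cohort with planted inherited and de
# novo CNVs under the study-default conditions (de novo rate 0.046 per
# offspring, DEL fraction 10/14), derives caller-like call sets, and
# writes the cohort tables under results/simulated_cohort/.
#
# Usage: Rscript analysis/02_simulate_cohort.R [seed]

suppressMessages(library(denovotrio))
suppressMessages(library(readr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out_dir <- file.path("results", sprintf("simulated_cohort_seed%d", seed))
if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)

config <- simulation_config(seed = seed, n_trios = 305)
cohort <- simulate_cohort(config, out_dir = out_dir)
calls <- calls_from_truth(cohort$truth, config)
write_tsv(calls, file.path(out_dir, "calls.tsv"))

n_dn <- sum(cohort$truth$origin == "de_novo")
n_carriers <- dplyr::n_distinct(cohort$truth$sample_id[cohort$truth$origin == "de_novo"])
cat("Simulated", config$n_trios, "trios (seed", seed, ")\n")
cat("Planted truth records:", nrow(cohort$truth),
    "| de novo events:", n_dn, "| carriers:", n_carriers,
    sprintf("(%.1f%%)\n", 100 * n_carriers / config$n_trios))
cat("Caller-like calls written:", nrow(calls), "\n")
cat("Outputs under", out_dir, "\n")
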