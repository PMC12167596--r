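#!/usr/bin/env Rscript

# Step 1: generate the synthetic field experiment.
#
# The default configuration mirrors the published breeding design: six
# founder accessions, two of them (COL, CV) mutagenized into 20 and 16 EMS
# lines of 2 sublines x 60 plants, 120-plant controls for every founder,
# 12 field blocks, Poisson(25) mutations per line segregating over three
# selfing generations, logistic survival calibrated to the focal control
# rates (~0.51 and ~0.35), and per-founder residual noise.  Writes the
# plant-level table to results/synthetic_experiment.csv.

suppressPackageStartupMessages(library(mutdfe))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 20140901L
dir.create("results", showWarnings = FALSE)

config <- simulation_config(seed = seed)
table <- simulate_experiment(config)

cat("Simulated", nrow(table), "plants\n\n")
print(design_counts(table))

out <- "results/synthetic_experiment.csv"
write_experiment_table(table, out)
cat("\nWrote", out, "\n")
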