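#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Three conditions, 16 cells each, mirroring the imaging scenarios the
# downstream statistics discriminate: foci placed uniformly at random in
# the domain ("g1_uniform", the random-placement reference), foci at the
# domain periphery ("g1s_peripheral") and foci near the center
# ("interior"). Each cell is one ~200 nm-Rg TAD cloud (2500 localizations,
# 647 channel) plus 7 ~30 nm foci (561 channel) and sparse background.
# Writes one localization CSV and one ground-truth CSV per cell, plus an
# index table, under results/data/.

suppressPackageStartupMessages(library(stormtad))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- analysis_config(seed = seed)
presets <- c("g1_uniform", "g1s_peripheral", "interior")

index <- list()
for (pi in seq_along(presets)) {
  for (ci in seq_len(cfg$simulate$n_cells)) {
    s <- (seed %% 10000L) * 100000L + pi * 10000L + ci
    cell <- simulate_cell(presets[pi], seed = s, sim = cfg$simulate)
    path <- file.path(out, sprintf("%s_cell%02d.csv", presets[pi], ci))
    write_localizations(cell$table, path)
    truth <- data.frame(focus = seq_along(cell$truth$foci$radial_fraction),
                        radial_fraction = cell$truth$foci$radial_fraction)
    write.csv(truth, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
    index[[length(index) + 1L]] <- data.frame(
      preset = presets[pi], cell = ci, seed = s, file = path,
      n_localizations = nrow(cell$table))
  }
}
index <- do.call(rbind, index)
write.csv(index, file.path(out, "index.csv"), row.names = FALSE)
message("wrote ", nrow(index), " cells (", sum(index$n_localizations),
        " localizations) under ", out)
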