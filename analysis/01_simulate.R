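#!/usr/bin/env Rscript
# Stage 1 — synthetic screening campaign.
# Generates the chemical library (aromatic interferent scaffolds vs
# aliphatic decoys, 10% planted actives) and simulates the full 13-endpoint
# concentration-response screen: 15-point triplicate titrations for the
# luciferase-inhibition readout, 5-point titrations for the twelve
# autofluorescence readouts, Gaussian activity noise of 5%.

suppressMessages(library(qhtscreen))
seed <- 1L
dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)

lib <- generate_library(600, active_fraction = 0.1, seed = derive_seed(seed, "library"))
scr <- simulate_screen(lib, seed = derive_seed(seed, "screen"))

write.csv(lib, "results/screen/library.csv", row.names = FALSE)
write.csv(scr$truth, "results/screen/truth.csv", row.names = FALSE)
write.csv(scr$titrations, "results/screen/titrations.csv", row.names = FALSE)

cat(sprintf("library: %d chemicals (%d planted actives, %.1f%%)\n",
            nrow(lib), sum(lib$truth_active), 100 * mean(lib$truth_active)))
cat(sprintf("titrations: %d rows over %d endpoints\n",
            nrow(scr$titrations), length(unique(scr$titrations$endpoint_id))))
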