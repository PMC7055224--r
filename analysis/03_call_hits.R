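#!/usr/bin/env Rscript
# Stage 3 — active-chemical identification.
# Applies the four filters (AC50 < 150 uM, curve class 1.x/2.x or
# -1.x/-2.x by direction, efficacy > 30%, burst cutoff for
# autofluorescence), summarizes actives per endpoint and quantifies the
# cross-endpoint overlap structure.

suppressMessages(library(qhtscreen))
fits <- read.csv("results/screen/fits.csv")
lib <- read.csv("results/screen/library.csv")

hits <- call_hits(fits)
summ <- summarize_actives(hits, fits, library_size = nrow(lib))
ov <- overlap_analysis(hits)

write.csv(hits, "results/screen/hitcalls.csv", row.names = FALSE)
write.csv(summ, "results/screen/summary.csv", row.names = FALSE)
jsonlite::write_json(ov, "results/screen/overlaps.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

print(summ, row.names = FALSE)
cat(sprintf("\nautofluorescence union: %d chemicals; active everywhere: %d\n",
            ov$autofluorescence_union, ov$all_conditions_all_channels$n))
cat(sprintf("luciferase x autofluorescence overlap: %d\n",
            ov$luciferase_x_autofluorescence))

truth <- read.csv("results/screen/truth.csv")
m <- merge(hits, truth, by = c("chem_id", "endpoint_id"))
cat(sprintf("recall %.1f%%, false-positive rate %.2f%% against planted truth\n",
            100 * sum(m$active & m$truth_active) / sum(m$truth_active),
            100 * sum(m$active & !m$truth_active) / sum(!m$truth_active)))
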