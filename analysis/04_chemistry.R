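#!/usr/bin/env Rscript
# Stage 4 — structure curation and descriptor engineering.
# Standardizes the library structures (salt stripping, metal disconnection,
# stereo removal, mixture rejection), computes the 2D descriptor block and
# reduces it to an informative non-redundant set (zero-variance, degeneracy
# and |rho| > 0.9 correlation-cluster filters).

suppressMessages(library(qhtscreen))
seed <- 1L
lib <- read.csv("results/screen/library.csv")

cur <- curate_structure(lib$smiles, chem_id = lib$chem_id)
desc <- compute_descriptors(cur)
sel <- select_descriptors(desc$matrix, seed = derive_seed(seed, "select"))

write.csv(cur, "results/screen/curated.csv", row.names = FALSE)
write.csv(data.frame(chem_id = rownames(sel$matrix), sel$matrix, check.names = FALSE),
          "results/screen/descriptors_selected.csv", row.names = FALSE)
write.csv(sel$report, "results/screen/selection_report.csv", row.names = FALSE)

cat(sprintf("curation: %d/%d passed\n", sum(cur$curation_status == "passed"), nrow(cur)))
cat(sprintf("descriptors: %d computed -> %d selected\n",
            ncol(desc$matrix), length(sel$selected)))
print(table(drop_rule = sel$report$rule[sel$report$action == "dropped"]))
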