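#!/usr/bin/env Rscript
# Stage 5 — unsupervised chemical-space analysis.
# Trains a 15x15 self-organizing map on the selected descriptors, colors it
# by per-node active percentage, Ward-clusters the active chemicals with
# per-condition AC50 annotations, and projects the library on a PCA for
# coverage plots.

suppressMessages(library(qhtscreen))
seed <- 1L
read_mat <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1]); rownames(m) <- d[[1]]; m
}
X <- read_mat("results/screen/descriptors_selected.csv")
hits <- read.csv("results/screen/hitcalls.csv")
fits <- read.csv("results/screen/fits.csv")

som <- train_som(X, seed = derive_seed(seed, "som"))
act_union <- unique(hits$chem_id[hits$active])
enr <- som_enrichment(som, act_union)
write.csv(enr$nodes, "results/screen/som_enrichment.csv", row.names = FALSE)
cat(sprintf("SOM: %d/%d nodes occupied; enrichment %.1f +/- %.1f%%, max %.0f%%\n",
            enr$summary$n_occupied, nrow(enr$nodes),
            enr$summary$mean_pct_active, enr$summary$sd_pct_active,
            enr$summary$max_pct_active))
print(head(enr$ranked, 5), row.names = FALSE)

act_ids <- intersect(rownames(X), act_union)
if (length(act_ids) >= 2) {
  blue <- fits[grepl("blue$", fits$endpoint_id) & fits$chem_id %in% act_ids, ]
  ann <- reshape(blue[, c("chem_id", "endpoint_id", "ac50_uM")],
                 idvar = "chem_id", timevar = "endpoint_id", direction = "wide")
  wc <- ward_cluster(X[act_ids, , drop = FALSE], annotations = ann)
  writeLines(wc$newick, "results/screen/actives_dendrogram.nwk")
  write.csv(wc$annotations, "results/screen/actives_potency_annotations.csv",
            row.names = FALSE)
  cat(sprintf("Ward tree over %d actives written (max merge height %.2f)\n",
              length(act_ids), max(wc$hclust$height)))
}

pca <- pca_project(X)
write.csv(data.frame(chem_id = rownames(pca$reference_coords),
                     pca$reference_coords),
          "results/screen/pca_coordinates.csv", row.names = FALSE)
cat(sprintf("PCA: first two components explain %.1f%% of variance\n",
            100 * sum(pca$explained_variance)))
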