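#!/usr/bin/env Rscript
# Stage 6 — interference QSAR ensembles.
# For the luciferase and blue-channel endpoints: label the curated library
# under the endpoint rule, undersample inactives to 70/30 ten times,
# grid-tune each member on ten-fold CV MCC, and report the five metrics as
# mean +/- SD over repetitions, with RF variable importances.

suppressMessages(library(qhtscreen))
seed <- 1L
read_mat <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1]); rownames(m) <- d[[1]]; m
}
X <- read_mat("results/screen/descriptors_selected.csv")
hits <- read.csv("results/screen/hitcalls.csv")

rules <- list(
  luciferase = list(rule = "luciferase"),
  blue = list(rule = "channel_any_condition", channel = "blue")
)
perf_all <- list()
for (nm in names(rules)) {
  rl <- rules[[nm]]
  ds <- assemble_endpoint_dataset(hits, X, rule = rl$rule, channel = rl$channel)
  cat(sprintf("\n== %s: %d chemicals, %d actives ==\n",
              nm, ds$rule$n_total, ds$rule$n_positive))
  if (ds$rule$n_positive < 10) { cat("too few actives; skipped\n"); next }
  ens <- build_ensemble(ds$X, ds$labels,
                        ensemble_spec(learner = "rf",
                                      seed = derive_seed(seed, paste0("qsar_", nm))))
  p <- ens$performance; p$model <- nm
  perf_all[[nm]] <- p
  print(p[p$metric == "MCC", ], row.names = FALSE)
  vi <- variable_importance(ens)
  write.csv(vi$summary, sprintf("results/screen/importance_%s.csv", nm),
            row.names = FALSE)
  cat("top descriptors:", paste(head(vi$summary$descriptor, 5), collapse = ", "), "\n")
}
write.csv(do.call(rbind, perf_all), "results/screen/qsar_performance.csv",
          row.names = FALSE)
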