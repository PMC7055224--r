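#!/usr/bin/env Rscript
# Stage 2 — concentration-response modeling.
# Fits the Hill equation to every chemical x endpoint titration (bounded
# Levenberg-Marquardt, AC50 capped at the top tested concentration) and
# assigns signed qHTS curve classes.

suppressMessages(library(qhtscreen))
titr <- read.csv("results/screen/titrations.csv")

fits <- classify_curves(titr, direction = "auto")
write.csv(fits, "results/screen/fits.csv", row.names = FALSE)

conv <- mean(fits$converged)
cat(sprintf("fitted %d curves; %.1f%% converged\n", nrow(fits), 100 * conv))
print(table(curve_class = fits$curve_class))
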