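#!/usr/bin/env Rscript
# Step 2: entropy-weighted composite supply index.
#
# Range-normalizes the three resource indicators over the pooled panel,
# computes entropy weights, and writes the composite series. With shared
# indicator proportions the three columns carry identical information, so
# the weights split evenly — a useful sanity check of the weighting logic
# (real yearbook indicators disperse differently and weight unevenly).

suppressMessages(library(allohealth))
panel <- read_panel("results/data/vertical_panel.csv")
idx <- supply_index(panel, epsilon = 1e-4)
write.csv(idx$series, "results/composite_index.csv", row.names = FALSE)
cat("Entropy weights (institutions/beds/doctors):",
    sprintf("%.4f", idx$weights), "\n")
cat("Scope:", idx$scope, "; epsilon:", idx$epsilon, "\n")
cat("Composite index range:",
    sprintf("[%.4f, %.4f] over %d city-years\n",
            min(idx$series$m_index), max(idx$series$m_index),
            nrow(idx$series)))
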