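#!/usr/bin/env Rscript
# Step 4: allometric typology and between-period change analysis.

suppressMessages(library(allohealth))
dpan <- read_panel("results/data/driver_panel.csv")

h1 <- horizontal_fits(dpan, period = c(2000, 2010))
h2 <- horizontal_fits(dpan, period = c(2011, 2022))

for (h in list(h1, h2)) {
  p <- h$period
  cls <- classify_exponent(h$fits$exponent_b)
  out <- cbind(h$fits[c("city_id", "exponent_b", "r_squared")],
               cls[c("label", "rank", "long_label")])
  write.csv(out, sprintf("results/classes_%d_%d.csv", p[1], p[2]),
            row.names = FALSE)
  s <- summarize_counts(h)
  write.csv(s$by_class, sprintf("results/class_counts_%d_%d.csv", p[1], p[2]),
            row.names = FALSE)
  cat(sprintf("Period %d-%d: %d positive (%.2f%%), %d negative (%.2f%%)\n",
              p[1], p[2], s$positive$count, s$positive$share,
              s$negative$count, s$negative$share))
}

ch <- change_table(h1, h2)
write.csv(ch, "results/change_table.csv", row.names = FALSE)
cat("Change kinds between periods:\n")
print(table(ch$change_kind))

# map-ready binning of the second-period exponents
jb <- jenks_breaks(h2$fits$exponent_b, 5)
jsonlite::write_json(list(k = jb$k, breaks = jb$breaks),
                     "results/jenks_breaks.json", auto_unbox = TRUE,
                     digits = NA)
cat("Jenks breaks (k = 5):", sprintf("%.3f", jb$breaks), "\n")
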