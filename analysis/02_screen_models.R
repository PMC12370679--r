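#!/usr/bin/env Rscript
# Stage 2 -- candidate growth-function screening.
#
# Fits the nine candidate curves to secondary branch length and diameter
# against SDINC and ranks them by AIC. On data generated from the unimodal
# law the unimodal curve (M7) should take the smallest AIC for both
# responses, mirroring the selection of the basic model.

library(secbranch)

ds <- read_dataset("results/dataset.csv")
d <- dataset_table(ds)

for (resp in c("SBL", "SBD")) {
  tab <- suppressWarnings(screen_candidates(d, response = resp))
  cat("\n==", resp, "candidate ranking ==\n")
  print(tab, row.names = FALSE)
  write.csv(tab, sprintf("results/screen_%s.csv", resp), row.names = FALSE)
  cat("best candidate:", tab$function_id[1], "\n")
}
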