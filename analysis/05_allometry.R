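#!/usr/bin/env Rscript
# Stage 5 -- allometric scaling between primary and secondary branches.
#
# Log-log OLS of the primary-branch size on the secondary-branch size at
# three grouping levels (primary-branch age, secondary-branch age, tree
# age), for both length and diameter, with 95% percentile-bootstrap
# confidence intervals from 3,000 case resamples per group.

library(secbranch)

ds <- read_dataset("results/dataset.csv")
seed <- 2025L

for (g in c("PAGE", "SAGE", "tree_age")) {
  for (m in c("length", "diameter")) {
    prof <- scaling_profile(ds, g, m, B = 3000, seed = seed +
                              1000 * match(g, c("PAGE", "SAGE", "tree_age")))
    fn <- sprintf("results/allometry_%s_%s.csv", g, m)
    write.csv(prof, fn, row.names = FALSE)
    ok <- prof[prof$reliable & !is.na(prof$exponent), ]
    cat(sprintf("%s / %s: %d groups, exponent range %.3f..%.3f -> %s\n",
                g, m, nrow(ok), min(ok$exponent), max(ok$exponent), fn))
  }
}
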