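#!/usr/bin/env Rscript
# Stage 6 -- crown-profile summaries.
#
# Whorl-wise and age-group mean sizes, current-year shoots against
# primary-branch age, and the relative depth at which the mean secondary
# branch size peaks within the primary branch (binned and fitted-curve
# readings).

library(secbranch)

ds <- read_dataset("results/dataset.csv")

for (by in c("PAGE", "SAGE", "depth")) {
  wm <- whorl_means(ds, by)
  write.csv(wm, sprintf("results/profile_by_%s.csv", by), row.names = FALSE)
  cat(sprintf("profile by %s: %d groups, mean SBL %.1f..%.1f cm\n",
              by, nrow(wm), min(wm$mean_SBL), max(wm$mean_SBL)))
}

cys <- current_year_shoots(ds)
write.csv(cys, "results/profile_current_year.csv", row.names = FALSE)
cat(sprintf("current-year shoots: %d branch-age groups, %d shoots\n",
            nrow(cys), sum(cys$n)))

for (m in c("length", "diameter")) {
  binned <- inflection_point(ds, m, "binned")
  fitted <- inflection_point(ds, m, "fitted")
  cat(sprintf("peak relative depth (%s): binned %.2f%s, fitted %.2f\n",
              m, binned$relative_depth,
              if (binned$monotone) " (profile still rising at the base)" else "",
              fitted$relative_depth))
}
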