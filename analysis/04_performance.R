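#!/usr/bin/env Rscript
# Relate mechanical work to 10 000-m performance in a simulated cohort whose
# sample W_ext-performance correlation is constructed to be exactly 0.80,
# and tabulate Pearson r with the least-squares prediction line for each
# work component under b = 1, 0.75 and the cohort-fitted 0.49.

library(mechwork)

dir.create("results", showWarnings = FALSE)
runners <- generate_runner_cohort(n = 14, target_r = 0.80, seed = 1)
write.csv(runners, "results/runner_cohort.csv", row.names = FALSE)

tab <- work_performance_table(runners, b_values = c(1, 0.75, 0.49))
tab[c("r", "p", "slope", "intercept")] <-
  lapply(tab[c("r", "p", "slope", "intercept")], signif, digits = 5)
print(tab, row.names = FALSE)

r_wext <- tab$r[tab$component == "W_ext" & tab$b == 1]
cat(sprintf(
  "\nW_ext carries the built-in association (r = %.2f at b = 1); W_int only\n",
  r_wext))
cat("correlates through its latent link to W_ext, so its r is lower -- the\n")
cat("qualitative ordering seen in work-performance studies of runners.\n")

write.csv(tab, "results/work_performance_table.csv", row.names = FALSE)
cat("Wrote results/runner_cohort.csv and results/work_performance_table.csv\n")
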