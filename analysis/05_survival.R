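#!/usr/bin/env Rscript
# Survival stratification: Kaplan-Meier curves for carriers of the planted
# survival gene's A&U event versus non-carriers, with the log-rank test,
# plus the screen of the top concordant genes from the pipeline run.

library(cnconcord)

cohort <- read_cohort("results/cohort")
zm <- compute_z(cohort$expression, cohort$calls)
tt <- classify_tendency(cohort$calls, call_degs(zm))

g <- cohort$survival_gene
grp <- tendency_groups(tt, cohort$clinical, g, "AU")
lr <- logrank_test(grp$time, grp$event, grp$group)
cat(sprintf("gene %s: %d A&U carriers vs %d non-carriers\n", g,
            sum(grp$group == "carrier"), sum(grp$group == "non-carrier")))
cat(sprintf("log-rank chi-square %.2f (1 df), p = %.3g\n", lr$chisq, lr$p))

for (gname in c("carrier", "non-carrier")) {
  km <- km_estimate(grp$time[grp$group == gname],
                    grp$event[grp$group == gname])
  med <- suppressWarnings(min(km$time[km$surv <= 0.5]))
  cat(sprintf("  %-12s median survival time: %.1f\n", gname, med))
  write.table(km, file.path("results", paste0("km_", gname, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\nsurvival screen of top concordant genes:\n")
print(read.delim("results/run/survival_results.tsv"))
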