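#!/usr/bin/env Rscript
# Generate the study cohort: 2,000 genes x 500 samples with 50 strongly
# amplification-concordant genes, 30 deletion-concordant genes, and the
# 30-oncogene / 10-TSG reference panels used later for threshold
# calibration. Writes the TSV inputs every later step consumes.

library(cnconcord)

cfg <- simulation_config(seed = 20260923L, discord_rate = 0.01)
cohort <- simulate_cohort(cfg)
print(cohort)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort", overwrite = TRUE)
cat("cohort written to results/cohort\n")
cat("planted survival gene:", cohort$survival_gene, "\n")
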