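#!/usr/bin/env Rscript
# Cohort-level dosage response: does expression track copy number?
# Reports the pooled median Z per call level with its linear fit, and the
# Welch comparison of amplified versus deleted Z-scores.

library(cnconcord)

fit <- read.delim("results/run/cohort_fit.tsv")
cat("pooled median Z per copy-number level:\n")
print(fit[, c("level", "median_z", "n_obs")])
cat(sprintf("\nlinear fit: slope %.3f, r %.3f, p %.3g\n",
            fit$slope[1], fit$r[1], fit$p[1]))

avd <- read.delim("results/run/amp_vs_del.tsv")
cat(sprintf("amplified vs deleted Z: t = %.1f, p = %.3g (means %.2f vs %.2f)\n",
            avd$t, avd$p, avd$mean_amplified, avd$mean_deleted))

rep <- summary_report("results/run")
cat(sprintf("genes with positive Spearman rho: %.1f%% of %d defined genes\n",
            100 * rep$frac_rho_positive, rep$n_valid_genes))
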