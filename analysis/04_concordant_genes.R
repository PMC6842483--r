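#!/usr/bin/env Rscript
# Concordant-gene identification: tendency fractions per cohort, the
# calibrated AUG/DDG sets compared against the planted truth, the top
# concordant genes, and their chromosome distribution.

library(cnconcord)

fr <- read.delim("results/run/cohort_summary.tsv")
cat("tendency fractions of the total variant CN count:\n")
print(fr)

gc <- read.delim("results/run/concordant_genes.tsv")
truth <- read.delim("results/cohort/truth.tsv")
tab <- table(truth = truth$planted[match(gc$gene, truth$gene)],
             called = gc$status)
cat("\nplanted truth vs called status:\n")
print(tab)

cat("\ntop 10 AUGs by A&U event count:\n")
print(head(gc[gc$status == "AUG", ][order(-gc$n_AU[gc$status == "AUG"]), ], 10))

cd <- read.delim("results/run/chromosome_distribution.tsv")
cat("\nchromosome distribution of AUG/DDG genes (top 5):\n")
print(head(cd, 5))
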