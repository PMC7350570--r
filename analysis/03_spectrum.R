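#!/usr/bin/env Rscript
# 12-class substitution spectrum and 96-channel trinucleotide spectra.

suppressMessages(library(sarcosig))
out <- "results/analysis"
variants <- read_variant_table(file.path(out, "variants.tsv"))

sp <- build_spectra(variants)
write_spectra(sp, file.path(out, "spectra.tsv"))

r12 <- sort(colSums(as.matrix(sp[, raw12_classes()])), decreasing = TRUE)
n <- sum(r12)
cat("substitution classes (cohort totals):\n")
for (k in names(r12)[1:4])
  cat(sprintf("  %s: %d (%.1f%%)\n", k, r12[[k]], 100 * r12[[k]] / n))
cat(sprintf("G>A + C>T transitions: %.1f%% of %d SNVs\n",
            100 * (r12[["G>A"]] + r12[["C>T"]]) / n, n))
cat(sprintf("SNVs without usable context: %d\n", sum(sp$n_no_context)))
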