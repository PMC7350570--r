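#!/usr/bin/env Rscript
# Consequence classes, top amino-acid changes, and the Kyte-Doolittle
# hydrophobicity-shift statistic over missense variants.

suppressMessages(library(sarcosig))
out <- "results/analysis"
variants <- read_variant_table(file.path(out, "variants.tsv"))

cons <- tabulate_consequences(variants)
write.table(cons$counts, file.path(out, "consequence_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cons$aa_changes, file.path(out, "aa_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cnt <- setNames(cons$counts$count, cons$counts$class)
cat(sprintf("missense %d (%d%%), silent %d (%d%%) of %d variants\n",
            cnt[["missense"]], round(100 * cnt[["missense"]] / cons$n_total),
            cnt[["silent"]], round(100 * cnt[["silent"]] / cons$n_total),
            cons$n_total))
top10 <- top_aa_changes(cons, 10)
cat(sprintf("%d of the top 10 amino-acid changes increase hydrophobicity\n",
            sum(top10$direction == "more_hydrophobic")))

h <- hydrophobicity_report(variants)
s <- h$shift
cat(sprintf("KD shift: mean %+.4f [%+.4f, %+.4f], %d/%d (%.0f%%) increasing, paired t p = %.3g\n",
            s$mean_delta, s$ci95[1], s$ci95[2], s$n_increasing, s$n,
            100 * s$frac_increasing, s$p_paired))
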