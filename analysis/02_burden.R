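#!/usr/bin/env Rscript
# Per-sample mutation counts and TMB/Mb; face/scalp vs rest comparison.

suppressMessages(library(sarcosig))
out <- "results/analysis"
variants <- read_variant_table(file.path(out, "variants.tsv"))
meta <- read_sample_meta(file.path(out, "meta.tsv"))

b <- compute_burden(variants, meta)
write.table(b$per_sample, file.path(out, "burden_per_sample.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(b$group_means, file.path(out, "burden_group_means.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fs <- b$per_sample$site_group == "face_scalp"
for (m in c("welch_t", "mann_whitney")) {
  cmp <- compare_groups(b$per_sample$n_mutations[fs],
                        b$per_sample$n_mutations[!fs], method = m)
  cat(sprintf("face/scalp (mean %.0f, N=%d) vs rest (mean %.0f, N=%d), %s: p = %.3g\n",
              cmp$mean_a, cmp$n_a, cmp$mean_b, cmp$n_b, m, cmp$p_value))
}
cat(sprintf("cohort mean %.0f mutations/sample (range %d-%d)\n",
            b$summary$mean_mutations, b$summary$min_mutations,
            b$summary$max_mutations))
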