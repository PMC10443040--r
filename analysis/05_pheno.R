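# Canavanine-resistance frequencies: titers from the countable drops of
# each serial dilution, Can^R/total ratios per biological replicate, and
# geometric-mean summaries per strain.

source("analysis/00_common.R")

counts <- read_plate_counts(file.path(paths$data, "plate_counts.tsv"))
res <- canr_experiment(counts)
write_tsv_table(res$replicates, file.path(paths$tables, "canr_replicates.tsv"))
write_tsv_table(res$summary, file.path(paths$tables, "canr_rates.tsv"))

for (k in seq_len(nrow(res$summary))) {
  row <- res$summary[k, ]
  message(sprintf("%s: Can^R frequency %.3g (log10 %.2f +/- %.2f, n = %d)",
                  row$strain, row$rate, row$log10_rate,
                  ifelse(is.na(row$log10_sd), 0, row$log10_sd),
                  row$n_replicates))
}
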