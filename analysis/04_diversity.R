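# Read-level editing diversity: distinct merged reads per sample, SNP
# counts against the fragment template, removal of recurrent WT background
# reads, per-kiloread normalization, and the Welch test of every sample
# against the no-guide control.

source("analysis/00_common.R")

unique_tabs <- list()
for (i in seq_len(nrow(sample_sheet))) {
  row <- sample_sheet[i, ]
  for (frag_name in names(scenario$fragments)) {
    frag <- scenario$fragments[[frag_name]]
    al <- tibble::as_tibble(read.delim(
      aligned_path(row$sample, row$replicate, frag_name)))
    ut <- collect_distinct(al, frag, sample = row$sample,
                           replicate = row$replicate,
                           total_reads = scenario$depth)
    ut$role <- row$role
    unique_tabs[[length(unique_tabs) + 1]] <- ut
  }
}

res <- bescan:::diversity_analysis(unique_tabs, scenario$fragments,
                                   scenario$parameters$min_occurrences)
write_tsv_table(res$summaries, file.path(paths$tables, "diversity.tsv"))
write_tsv_table(res$histograms,
                file.path(paths$tables, "diversity_by_snps.tsv"))

s <- res$summaries
by_role <- tapply(s$unique_reads_per_kiloread, s$role, mean)
message(sprintf(
  "mean unique reads per kiloread: edited %.1f vs control %.1f",
  by_role["edited"], by_role["control"]))
sig <- unique(s[s$role == "edited" & !is.na(s$p_value),
                c("sample", "fragment", "p_value", "stars")])
for (k in seq_len(nrow(sig))) {
  message(sprintf("  %s on %s: p = %.3g %s", sig$sample[k], sig$fragment[k],
                  sig$p_value[k], sig$stars[k]))
}
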