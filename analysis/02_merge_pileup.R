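# Merge the paired reads of every sample (0 mismatches in the overlap),
# align the distinct merged sequences to their fragment, and build
# per-position allele-count pileups written as VCF-like variant tables.

source("analysis/00_common.R")

merge_stats <- list()
for (i in seq_len(nrow(sample_sheet))) {
  row <- sample_sheet[i, ]
  for (frag_name in names(scenario$fragments)) {
    frag <- scenario$fragments[[frag_name]]
    reads <- read_fastq_pairs(fastq_path(row$sample, row$replicate,
                                         frag_name, 1),
                              fastq_path(row$sample, row$replicate,
                                         frag_name, 2))
    merged <- merge_pairs(reads,
                          max_mismatch = scenario$parameters$max_mismatch)
    al <- align_sample(merged, frag)
    write_tsv_table(al, aligned_path(row$sample, row$replicate, frag_name))
    pile <- build_pileup(al, frag, sample = row$sample,
                         replicate = row$replicate,
                         max_depth = scenario$parameters$max_depth)
    write_variant_table(pile,
                        pileup_path(row$sample, row$replicate, frag_name))
    merge_stats[[length(merge_stats) + 1]] <- data.frame(
      sample = row$sample, replicate = row$replicate, fragment = frag_name,
      pairs = nrow(reads), merged = sum(merged$status == "merged"),
      distinct = nrow(al))
  }
}
stats <- dplyr::bind_rows(merge_stats)
write_tsv_table(stats, file.path(paths$tables, "merge_stats.tsv"))
message(sprintf(
  "merged %d samples: overall merge rate %.1f%% (pairs with a mate error are rejected at 0 overlap mismatches)",
  nrow(stats), 100 * sum(stats$merged) / sum(stats$pairs)))
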