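# Generate the synthetic study data: paired amplicon FASTQ for every
# sample/replicate/fragment of the sheet, serial-dilution plate counts for
# the phenotype assay, and Sanger clone sequences — all from the scenario's
# single top-level seed.

source("analysis/00_common.R")

seeds <- withr::with_seed(scenario$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     nrow(sample_sheet) + 2L))

truth <- list()
for (i in seq_len(nrow(sample_sheet))) {
  row <- sample_sheet[i, ]
  cfg <- sim_config(scenario$gene, scenario$fragments, scenario$guides,
                    scenario$editor, depth = scenario$depth,
                    seq_error_rate = scenario$seq_error_rate,
                    background_rate = scenario$background_rate,
                    seed = seeds[i])
  sim <- if (row$role == "edited") {
    simulate_reads(cfg, sample = row$sample, replicate = row$replicate)
  } else {
    simulate_wt_reads(cfg, sample = row$sample, replicate = row$replicate)
  }
  truth[[i]] <- sim$truth
  for (frag in names(scenario$fragments)) {
    reads <- sim$reads[sim$reads$fragment == frag, ]
    write_fastq_pairs(reads,
                      fastq_path(row$sample, row$replicate, frag, 1),
                      fastq_path(row$sample, row$replicate, frag, 2))
  }
  message(sprintf("simulated %s %s: %d read pairs x %d fragments",
                  row$sample, row$replicate, scenario$depth,
                  length(scenario$fragments)))
}
truth <- dplyr::bind_rows(truth)
write_tsv_table(truth, file.path(paths$data, "truth.tsv"))
message(sprintf("truth table: %d editable positions, injected probability %s",
                length(unique(truth$pos)),
                paste(unique(truth$injected_prob), collapse = "/")))

# phenotype assay: one plating experiment per strain of the scenario
counts <- dplyr::bind_rows(lapply(seq_along(scenario$pheno$strains),
  function(k) {
    st <- scenario$pheno$strains[[k]]
    simulate_plate_counts(st$true_freq, strain = st$name,
                          seed = (seeds[nrow(sample_sheet) + 1L] + k) %%
                            .Machine$integer.max)
  }))
write_tsv_table(counts, file.path(paths$data, "plate_counts.tsv"))

# Sanger clones of selected resistant mutants
clones <- simulate_sanger_clones(scenario$sanger$n_clones, scenario$editor,
                                 scenario$guides, scenario$gene,
                                 seed = seeds[nrow(sample_sheet) + 2L])
write_clone_fasta(clones$sequences,
                  file.path(paths$data, "sanger_clones_synthetic.fasta"))
write_tsv_table(clones$truth, file.path(paths$data, "clone_truth.tsv"))
message(sprintf("simulated %d clones carrying %d substitutions",
                scenario$sanger$n_clones, nrow(clones$truth)))
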