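# Sanger clone analysis: align each clone to the gene, call substitutions,
# compute per-position clone mutation rates, and profile the calls in
# PAM-relative coordinates of the scenario's focal guide.

source("analysis/00_common.R")

clones <- read_clone_fasta(file.path(paths$data,
                                     "sanger_clones_synthetic.fasta"))
ac <- align_clones(clones, scenario$gene)
n_ok <- sum(ac$clones$status == "ok")
rates <- clone_mutation_rate(ac$substitutions, n_ok)
profile <- pam_window_profile(ac$substitutions,
                              scenario$guides[[scenario$sanger$guide]])
write_tsv_table(ac$substitutions, file.path(paths$tables,
                                            "clone_substitutions.tsv"))
write_tsv_table(rates, file.path(paths$tables, "clone_mutation_rates.tsv"))
write_tsv_table(profile, file.path(paths$tables, "clone_pam_profile.tsv"))

top <- rates[which.max(rates$rate_percent), ]
message(sprintf("%d/%d clones aligned; %d mutated positions", n_ok,
                length(clones), nrow(rates)))
message(sprintf("highest clone mutation rate: %.0f%% at position %d (%d/%d clones)",
                top$rate_percent, top$pos, top$n_mutated, n_ok))
in_window <- mean(abs(profile$offset[!profile$out_of_window]) <= 20)
message(sprintf("%.0f%% of %s-relative calls lie within +/-20 bp of the PAM",
                100 * in_window, scenario$sanger$guide))
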