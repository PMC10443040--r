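# Mutation spectra: trim fragment ends, apply the depth filter, convert
# pileups to per-position/per-class proportions, pool the WT replicates
# into the background, derive the 95% WT band, and subtract the background
# from every non-WT sample.

source("analysis/00_common.R")

prm <- scenario$parameters
spectra <- list(); wt_keys <- character(0)
for (i in seq_len(nrow(sample_sheet))) {
  row <- sample_sheet[i, ]
  for (frag_name in names(scenario$fragments)) {
    frag <- scenario$fragments[[frag_name]]
    pile <- read_variant_table(pileup_path(row$sample, row$replicate,
                                           frag_name))
    kept <- filter_depth(trim_fragment_ends(pile, frag, prm$n_trim),
                         prm$min_depth)
    key <- paste(row$sample, row$replicate, frag_name, sep = "|")
    spectra[[key]] <- mutated_proportion(kept)
    if (row$role == "wt") wt_keys <- c(wt_keys, key)
  }
}

band <- wt_background_band(spectra[wt_keys], coverage = prm$coverage)
write_tsv_table(band, file.path(paths$tables, "wt_band.tsv"))

pooled_wt <- bescan:::pool_wt_spectra(spectra[wt_keys])
subtracted <- lapply(setdiff(names(spectra), wt_keys), function(key) {
  subtract_wt(spectra[[key]], pooled_wt)
})
all_spectra <- dplyr::bind_rows(c(spectra, subtracted))
write_tsv_table(all_spectra, file.path(paths$tables, "spectra.tsv"))

# where does the editing signal sit relative to the guides?
sub_tot <- position_totals(dplyr::bind_rows(subtracted))
edited_tot <- sub_tot[grepl("g", sub_tot$sample) &
                        sub_tot$sample != "WT", ]
top <- edited_tot[order(-edited_tot$p_mut), ][1:10, ]
offsets <- sapply(top$pos, function(p)
  min(abs(sapply(scenario$guides, pam_relative, pos = p))))
message(sprintf(
  "top WT-subtracted positions lie within %d bp of a PAM (max over top 10)",
  max(offsets)))
message(sprintf("95%% WT band spans %.2g (min class) to %.2g (max class)",
                min(band$bound), max(band$bound)))
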