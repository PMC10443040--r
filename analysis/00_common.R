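# Shared setup for the numbered analysis drivers: loads the bundled
# demonstration scenario and fixes the output layout. Run the drivers from
# the repository root, in order.

suppressMessages(library(bescan))

scenario <- read_scenario(system.file("extdata", "toy_scenario.yaml",
                                      package = "bescan"))

paths <- list(
  data = "results/data",       # simulated raw data (FASTQ, plate counts...)
  tables = "results/tables")   # derived tables
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)

sample_sheet <- do.call(rbind, lapply(scenario$samples, function(s) {
  data.frame(sample = s$sample, role = s$role,
             replicate = paste0("r", seq_len(s$replicates)))
}))

fastq_path <- function(sample, replicate, frag, mate) {
  file.path(paths$data,
            sprintf("%s_%s_%s_R%d.fastq", sample, replicate, frag, mate))
}
aligned_path <- function(sample, replicate, frag) {
  file.path(paths$tables,
            sprintf("aligned_%s_%s_%s.tsv", sample, replicate, frag))
}
pileup_path <- function(sample, replicate, frag) {
  file.path(paths$tables,
            sprintf("pileup_%s_%s_%s.tsv", sample, replicate, frag))
}
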