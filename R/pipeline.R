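# End-to-end scenario runner: simulate -> merge -> align -> pileup ->
# spectra -> diversity -> phenotype -> clones, with one top-level seed
# fanned out per stage and a machine-readable run manifest.

#' Read a scenario configuration from YAML
#'
#' Paths inside the file are resolved relative to its directory. See
#' `inst/extdata/toy_scenario.yaml` for the layout.
#'
#' @param path YAML scenario path.
#' @return A scenario list (gene, guides, fragments, editor, samples,
#'   parameters, pheno, sanger, seed).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  gene <- read_gene_fasta(resolve(y$gene_fasta))
  feats <- read_features_tsv(resolve(y$features_tsv), gene)
  editor_of <- function(e) {
    maker <- switch(e$type, cytidine = cytidine_editor,
                    adenine = adenine_editor,
                    stop("unknown editor type: ", e$type, call. = FALSE))
    maker(prob = e$prob %||% 0.01, synergy_factor = e$synergy_factor %||% 1)
  }
  list(gene = gene, guides = feats$guides, fragments = feats$fragments,
       editor = editor_of(y$editor),
       samples = y$samples, parameters = y$parameters %||% list(),
       pheno = y$pheno, sanger = y$sanger,
       depth = y$depth %||% 5000L,
       seq_error_rate = y$seq_error_rate %||% 0.001,
       background_rate = y$background_rate %||% 1e-4,
       seed = y$seed %||% 1L)
}

# Deterministic per-stage/per-sample sub-seeds from one top-level seed.
fan_out_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run a full analysis scenario
#'
#' Simulates every sample of the sheet, merges and aligns its reads, builds
#' pileups and variant tables, computes WT-subtracted spectra with the WT
#' background band, the editing-diversity summaries with significance
#' against the control samples, the canavanine-resistance rates, and the
#' Sanger clone profile. All outputs are written as TSV/FASTA under
#' `outdir`, together with a YAML run manifest (parameters, seed, output
#' hashes). Reruns with the same seed are byte-identical.
#'
#' @param scenario A scenario list from [read_scenario()].
#' @param outdir Output directory (created if missing).
#' @param seed Optional override of the scenario seed.
#' @param write_fastq Also write the simulated FASTQ pairs (off by default;
#'   they are the largest outputs).
#' @return Invisibly, a list with the main result tables (spectra, band,
#'   diversity, pheno, sanger, truth) and the manifest path.
#' @export
run_scenario <- function(scenario, outdir, seed = NULL, write_fastq = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% scenario$seed
  prm <- scenario$parameters
  min_depth <- prm$min_depth %||% 50000L
  n_trim <- prm$n_trim %||% 5L
  max_mismatch <- prm$max_mismatch %||% 0L
  min_occurrences <- prm$min_occurrences %||% 5L
  coverage <- prm$coverage %||% 0.95
  max_depth <- prm$max_depth %||% 600000L

  sheet <- dplyr::bind_rows(lapply(scenario$samples, function(s) {
    tibble::tibble(sample = s$sample, role = s$role,
                   replicate = paste0("r", seq_len(s$replicates %||% 1L)))
  }))
  seeds <- fan_out_seeds(seed, nrow(sheet) + 2L)

  spectra <- list(); wt_spectra <- list(); unique_tabs <- list()
  truth <- list(); pileups <- list()
  frag_of <- function(name) scenario$fragments[[name]]

  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
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
    for (fname in names(scenario$fragments)) {
      frag <- frag_of(fname)
      reads <- sim$reads[sim$reads$fragment == fname, ]
      if (write_fastq) {
        write_fastq_pairs(reads,
          file.path(outdir, sprintf("%s_%s_%s_R1.fastq", row$sample,
                                    row$replicate, fname)),
          file.path(outdir, sprintf("%s_%s_%s_R2.fastq", row$sample,
                                    row$replicate, fname)))
      }
      merged <- merge_pairs(reads, max_mismatch = max_mismatch)
      al <- align_sample(merged, frag)
      pile <- build_pileup(al, frag, sample = row$sample,
                           replicate = row$replicate, max_depth = max_depth)
      pileups[[length(pileups) + 1]] <- pile
      kept <- filter_depth(trim_fragment_ends(pile, frag, n_trim),
                           min_depth)
      spec <- mutated_proportion(kept)
      key <- paste(row$sample, row$replicate, fname, sep = "|")
      spectra[[key]] <- spec
      if (row$role == "wt") wt_spectra[[key]] <- spec
      ut <- collect_distinct(al, frag, sample = row$sample,
                             replicate = row$replicate,
                             total_reads = nrow(reads))
      ut$role <- row$role
      unique_tabs[[key]] <- ut
    }
  }

  # --- spectra: WT band and WT subtraction -------------------------------
  band <- if (sum(vapply(wt_spectra, nrow, integer(1))) > 0) {
    wt_background_band(wt_spectra, coverage = coverage)
  } else tibble::tibble(class = character(), bound = numeric())
  pooled_wt <- pool_wt_spectra(wt_spectra)
  sub_spectra <- lapply(names(spectra), function(key) {
    sp <- spectra[[key]]
    if (nrow(sp) == 0 || key %in% names(wt_spectra) ||
        nrow(pooled_wt) == 0) return(NULL)
    subtract_wt(sp, pooled_wt)
  })
  spectra_tab <- dplyr::bind_rows(c(spectra, sub_spectra))

  # --- diversity ---------------------------------------------------------
  diversity <- diversity_analysis(unique_tabs, scenario$fragments,
                                  min_occurrences)

  # --- phenotype ---------------------------------------------------------
  pheno <- NULL
  if (!is.null(scenario$pheno)) {
    counts <- dplyr::bind_rows(lapply(seq_along(scenario$pheno$strains),
      function(k) {
        st <- scenario$pheno$strains[[k]]
        simulate_plate_counts(st$true_freq, strain = st$name,
                              seed = (seeds[nrow(sheet) + 1L] + k) %%
                                .Machine$integer.max)
      }))
    pheno <- canr_experiment(counts)
    write_tsv_table(counts, file.path(outdir, "plate_counts.tsv"))
    write_tsv_table(pheno$summary, file.path(outdir, "canr_rates.tsv"))
  }

  # --- Sanger clones -----------------------------------------------------
  sanger <- NULL
  if (!is.null(scenario$sanger)) {
    sc <- scenario$sanger
    clones <- simulate_sanger_clones(sc$n_clones, scenario$editor,
                                     scenario$guides, scenario$gene,
                                     seed = seeds[nrow(sheet) + 2L])
    write_clone_fasta(clones$sequences,
                      file.path(outdir, "sanger_clones_synthetic.fasta"))
    ac <- align_clones(clones$sequences, scenario$gene)
    rates <- clone_mutation_rate(ac$substitutions,
                                 sum(ac$clones$status == "ok"))
    profile <- pam_window_profile(ac$substitutions,
                                  scenario$guides[[sc$guide]])
    sanger <- list(substitutions = ac$substitutions, rates = rates,
                   profile = profile)
    write_tsv_table(rates, file.path(outdir, "clone_mutation_rates.tsv"))
    write_tsv_table(profile, file.path(outdir, "clone_pam_profile.tsv"))
  }

  # --- persist the core tables ------------------------------------------
  for (pile in pileups) {
    write_variant_table(pile, file.path(
      outdir, sprintf("pileup_%s_%s_%s.tsv", pile$sample[1],
                      pile$replicate[1], pile$fragment[1])))
  }
  write_tsv_table(spectra_tab, file.path(outdir, "spectra.tsv"))
  write_tsv_table(band, file.path(outdir, "wt_band.tsv"))
  write_tsv_table(diversity$summaries, file.path(outdir, "diversity.tsv"))
  write_tsv_table(diversity$histograms,
                  file.path(outdir, "diversity_by_snps.tsv"))
  truth_tab <- dplyr::bind_rows(truth)
  write_tsv_table(truth_tab, file.path(outdir, "truth.tsv"))

  manifest <- write_manifest(outdir, seed, scenario)
  invisible(list(spectra = spectra_tab, band = band, diversity = diversity,
                 pheno = pheno, sanger = sanger, truth = truth_tab,
                 manifest = manifest))
}

# Pool WT replicate spectra into one background spectrum by averaging the
# class proportions per position across replicates (per fragment).
pool_wt_spectra <- function(wt_spectra) {
  pooled <- dplyr::bind_rows(wt_spectra)
  if (nrow(pooled) == 0) return(pooled)
  out <- dplyr::summarise(
    dplyr::group_by(pooled, .data$fragment, .data$pos, .data$ref,
                    .data$alt, .data$class),
    proportion = mean(.data$proportion), p_mut = mean(.data$p_mut),
    .groups = "drop")
  out$sample <- "WT_pooled"
  out$replicate <- "pooled"
  out$wt_subtracted <- FALSE
  out
}

# Diversity stage shared by run_scenario and the analysis drivers:
# background-filter every non-WT unique-read table against the WT tables of
# its fragment, summarize, and test each sample against the control role.
diversity_analysis <- function(unique_tabs, fragments, min_occurrences = 5L) {
  tabs <- dplyr::bind_rows(unique_tabs)
  summaries <- list(); hists <- list()
  for (fname in names(fragments)) {
    frag <- fragments[[fname]]
    ft <- tabs[tabs$fragment == fname, ]
    wt_list <- split(ft[ft$role == "wt", ],
                     paste(ft$sample[ft$role == "wt"],
                           ft$replicate[ft$role == "wt"]))
    non_wt <- ft[ft$role != "wt", ]
    for (key in unique(paste(non_wt$sample, non_wt$replicate))) {
      tab <- non_wt[paste(non_wt$sample, non_wt$replicate) == key, ]
      filt <- filter_wt_background(tab, wt_list, frag, min_occurrences)
      summaries[[length(summaries) + 1]] <-
        dplyr::mutate(diversity_summary(filt), role = tab$role[1])
      hists[[length(hists) + 1]] <- group_by_snps(filt)
    }
  }
  summaries <- dplyr::bind_rows(summaries)
  hists <- dplyr::bind_rows(hists)
  # significance vs the control role, per sample and fragment
  if (nrow(summaries) > 0 && any(summaries$role == "control")) {
    tests <- list()
    for (fname in unique(summaries$fragment)) {
      fs <- summaries[summaries$fragment == fname, ]
      ctrl <- fs$unique_reads_per_kiloread[fs$role == "control"]
      if (length(ctrl) < 2) next
      for (smp in unique(fs$sample[fs$role != "control"])) {
        vals <- fs$unique_reads_per_kiloread[fs$sample == smp]
        if (length(vals) < 2) next
        tests[[length(tests) + 1]] <- dplyr::bind_cols(
          tibble::tibble(sample = smp, fragment = fname),
          compare_to_control(vals, ctrl))
      }
    }
    tests <- dplyr::bind_rows(tests)
    if (nrow(tests) > 0) {
      summaries <- dplyr::left_join(summaries, tests,
                                    by = c("sample", "fragment"))
    }
  }
  list(summaries = summaries, histograms = hists)
}

# YAML run manifest: seed, parameters, package version, md5 of every output.
write_manifest <- function(outdir, seed, scenario) {
  files <- sort(setdiff(list.files(outdir), "manifest.yaml"))
  hashes <- as.list(tools::md5sum(file.path(outdir, files)))
  names(hashes) <- files
  manifest <- list(
    package = "bescan",
    version = as.character(utils::packageVersion("bescan")),
    seed = seed,
    depth = scenario$depth,
    seq_error_rate = scenario$seq_error_rate,
    background_rate = scenario$background_rate,
    parameters = scenario$parameters,
    outputs = hashes)
  path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
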