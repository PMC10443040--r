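div_frag <- function() {
  gene <- toy_gene(50, seed = 61)
  fragment_spec("f", 1, 50, gene)
}

mutate_at <- function(seq, pos) {
  substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(seq, pos, pos))[1]
  seq
}

test_that("distinct-read collection tallies counts and excludes indel reads", {
  frag <- div_frag()
  v1 <- mutate_at(frag$sequence, 10)
  del <- paste0(substr(frag$sequence, 1, 19), substr(frag$sequence, 21, 50))
  reads <- c(rep(frag$sequence, 10), rep(v1, 3), del)
  al <- align_sample(tibble::tibble(merged = reads, status = "merged"), frag)
  ut <- collect_distinct(al, frag, total_reads = length(reads))
  expect_identical(ut$count[ut$seq == frag$sequence], 10L)
  expect_identical(ut$count[ut$seq == v1], 3L)
  expect_true(ut$indel[ut$seq == del])
  expect_true(is.na(ut$n_snps[ut$seq == del]))
  expect_identical(ut$n_snps[ut$seq == v1], 1L)
  # tallies equal a brute-force dictionary count
  expect_identical(setNames(ut$count, ut$seq)[names(table(reads))],
                   setNames(as.integer(table(reads)), names(table(reads))))
})

test_that("snp_count is the Hamming distance and rejects unequal lengths", {
  frag <- div_frag()
  expect_identical(snp_count(frag$sequence, frag$sequence), 0L)
  expect_identical(snp_count(mutate_at(frag$sequence, 7), frag$sequence), 1L)
  withr::with_seed(8, {
    for (k in 1:100) {
      a <- rand_dna(40); b <- rand_dna(40)
      expect_identical(snp_count(a, b), as.integer(bf_hamming(a, b)))
    }
  })
  expect_error(snp_count("ACGT", "ACG"), "length")
})

test_that("WT background filtering applies the >=5 summed-occurrence rule", {
  frag <- div_frag()
  v5 <- mutate_at(frag$sequence, 5)
  v4 <- mutate_at(frag$sequence, 6)
  tab <- collect_distinct(
    align_sample(tibble::tibble(merged = c(frag$sequence, v5, v4),
                                status = "merged"), frag),
    frag, total_reads = 3)
  wt1 <- tibble::tibble(seq = c(v5, v4), count = c(3L, 2L))
  wt2 <- tibble::tibble(seq = c(v5, v4), count = c(2L, 2L))
  out <- filter_wt_background(tab, list(wt1, wt2), frag)
  expect_false(v5 %in% out$seq)        # 3 + 2 = 5 -> removed
  expect_true(v4 %in% out$seq)         # 4 -> retained
  expect_false(frag$sequence %in% out$seq)  # reference always removed
  # empty WT tables: only the reference goes
  out2 <- filter_wt_background(tab, list(), frag)
  expect_setequal(out2$seq, c(v5, v4))
})

test_that("per-kiloread normalization has the documented arithmetic", {
  expect_equal(normalize_per_kiloread(50, 100000), 0.5)
  expect_equal(normalize_per_kiloread(0, 1234), 0)
  expect_equal(normalize_per_kiloread(10, 2000),
               normalize_per_kiloread(20, 4000))
  expect_error(normalize_per_kiloread(1, 0), "positive")
})

test_that("SNP histograms group distinct reads and conserve totals", {
  frag <- div_frag()
  singles <- vapply(c(3, 9, 15), function(p) mutate_at(frag$sequence, p),
                    character(1))
  double <- mutate_at(mutate_at(frag$sequence, 20), 30)
  reads <- c(rep(frag$sequence, 5), singles, double, double)
  al <- align_sample(tibble::tibble(merged = reads, status = "merged"), frag)
  ut <- collect_distinct(al, frag, total_reads = 10000)
  ut <- filter_wt_background(ut, list(), frag)
  h <- group_by_snps(ut)
  expect_identical(h$distinct_reads[h$n_snps == 1], 3L)
  expect_identical(h$distinct_reads[h$n_snps == 2], 1L)
  expect_equal(h$distinct_reads_per_kiloread[h$n_snps == 1], 3 / 10)
  expect_identical(sum(h$distinct_reads),
                   sum(!ut$indel & !is.na(ut$n_snps) & ut$n_snps >= 1))
  # all reads reference -> empty histogram
  ref_only <- collect_distinct(
    align_sample(tibble::tibble(merged = rep(frag$sequence, 4),
                                status = "merged"), frag),
    frag, total_reads = 4)
  expect_identical(nrow(group_by_snps(
    filter_wt_background(ref_only, list(), frag))), 0L)
})

test_that("control comparison reproduces a Welch oracle and handles degeneracy", {
  strong <- compare_to_control(c(10, 11, 12), c(0.9, 1.0, 1.1))
  # frozen from the independent Welch oracle below (t on Satterthwaite df)
  expect_lt(strong$p_value, 0.01)
  expect_identical(strong$stars, "**")
  expect_equal(strong$p_value, bf_welch_p(c(10, 11, 12), c(0.9, 1.0, 1.1)))
  # identical constant replicates: degenerate, reported not significant
  deg <- compare_to_control(c(2, 2, 2), c(2, 2, 2))
  expect_equal(deg$p_value, 1)
  expect_identical(deg$stars, "ns")
  # label permutation leaves p unchanged
  a <- c(1.2, 3.4, 2.2); b <- c(2.0, 2.8, 1.4)
  expect_equal(compare_to_control(a, b)$p_value,
               compare_to_control(b, a)$p_value)
  expect_error(compare_to_control(1, c(1, 2)), "replicates")
})

test_that("filtering commutes with read reordering", {
  setup <- toy_setup()
  frag <- setup$fragments$fragA
  cfg <- sim_config(setup$gene, list(fragA = frag), setup$guides["gRNA1"],
                    cytidine_editor(0.05), depth = 600, seed = 30)
  sim <- simulate_reads(cfg)
  wt <- sim_unique_table(cfg, frag, wt = TRUE)
  run <- function(reads) {
    al <- align_sample(merge_pairs(reads), frag)
    ut <- collect_distinct(al, frag, total_reads = nrow(reads))
    out <- filter_wt_background(ut, wt, frag)
    out[order(out$seq), c("seq", "count", "n_snps")]
  }
  shuffled <- sim$reads[withr::with_seed(1, sample(nrow(sim$reads))), ]
  expect_equal(run(sim$reads), run(shuffled))
})

test_that("normalized unique-read counts rise with the editing rate", {
  setup <- toy_setup()
  frag <- setup$fragments$fragB
  per_level <- vapply(c(0.005, 0.02, 0.08), function(p) {
    vals <- vapply(1:6, function(i) {
      cfg <- sim_config(setup$gene, list(fragB = frag), setup$guides["gRNA2"],
                        cytidine_editor(p), depth = 800,
                        seed = 1000 + i + round(p * 1e5))
      wt_cfg <- cfg; wt_cfg$seed <- cfg$seed + 7
      ut <- sim_unique_table(cfg, frag)
      wt <- sim_unique_table(wt_cfg, frag, wt = TRUE)
      diversity_summary(
        filter_wt_background(ut, wt, frag))$unique_reads_per_kiloread
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(per_level) > 0))
})
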