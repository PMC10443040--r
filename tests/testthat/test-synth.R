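# The generator is first-class code: these tests pin its statistical
# behavior with binomial/closed-form oracles at small-to-moderate depth.

toy_editor_setup <- function(len = 120, proto = c(40, 59)) {
  gene <- toy_gene(len, seed = 91)
  guide <- derive_pam(guide_spec("g", proto[1], proto[2], "coding"), gene)
  frag <- fragment_spec("f", 1, len, gene)
  list(gene = gene, guide = guide, frag = frag)
}

test_that("a null editor without error reproduces the reference exactly", {
  s <- toy_editor_setup()
  cfg <- sim_config(s$gene, list(f = s$frag), list(g = s$guide), null_editor(),
                    depth = 50, seq_error_rate = 0, background_rate = 0,
                    seed = 1)
  sim <- simulate_reads(cfg)
  expect_true(all(sim$reads$r1 == s$frag$sequence))
  expect_true(all(sim$reads$r2 == rc_slow(s$frag$sequence)))
  m <- merge_pairs(sim$reads)
  expect_true(all(m$status == "merged"))
  expect_true(all(m$merged == s$frag$sequence))
})

test_that("realized edit fractions match the injected binomial probability", {
  s <- toy_editor_setup()
  # single-offset window with probability 0.05
  ed <- editor_profile("one", "C", c(T = 1), flat_window(-5, -5, 0.05))
  # make sure offset -5 is a C so the position is editable
  pos <- pam_relative_inv(s$guide, -5L)
  ch <- strsplit(s$gene$sequence, "")[[1]]; ch[pos] <- "C"
  gene <- target_gene("toy", paste(ch, collapse = ""))
  frag <- fragment_spec("f", 1, gene$length, gene)
  cfg <- sim_config(gene, list(f = frag), list(g = s$guide), ed,
                    depth = 50000, seq_error_rate = 0, background_rate = 0,
                    seed = 2)
  sim <- simulate_reads(cfg)
  expect_identical(sim$truth$pos, pos)
  se <- sqrt(0.05 * 0.95 / 50000)
  expect_lt(abs(sim$truth$realized - 0.05), 3 * se)
  # and the edits really are C>T on the reads
  expect_true(all(substr(sim$reads$r1[sim$truth$n_edited > 0][1], pos, pos)
                  %in% c("C", "T")))
})

test_that("overlapping windows double the edit rate via the synergy factor", {
  s <- toy_editor_setup()
  g1 <- s$guide
  g2 <- derive_pam(guide_spec("g2", 45, 64, "coding"), s$gene)
  ed <- cytidine_editor(prob = 0.04, synergy_factor = 2)
  cfg <- sim_config(s$gene, list(f = s$frag), list(g1 = g1, g2 = g2), ed,
                    depth = 30000, seq_error_rate = 0, background_rate = 0,
                    seed = 3)
  sim <- simulate_reads(cfg)
  w1 <- editing_window(g1, 20, s$gene); w2 <- editing_window(g2, 20, s$gene)
  overlap <- intersect(w1[1]:w1[2], w2[1]:w2[2])
  tr <- sim$truth
  expect_true(all(tr$injected_prob[tr$pos %in% overlap] == 0.08))
  both <- tr$realized[tr$pos %in% overlap]
  single <- tr$realized[!tr$pos %in% overlap]
  se8 <- 3 * sqrt(0.08 * 0.92 / 30000)
  expect_true(all(abs(both - 0.08) < se8))
  se4 <- 3 * sqrt(0.04 * 0.96 / 30000)
  expect_true(all(abs(single - 0.04) < se4))
})

test_that("WT reads carry only error and background; rejection rate matches closed form", {
  s <- toy_editor_setup()
  eps <- 0.004
  cfg <- sim_config(s$gene, list(f = s$frag), list(g = s$guide),
                    cytidine_editor(0.05), depth = 20000,
                    seq_error_rate = eps, background_rate = 0, seed = 4)
  sim <- simulate_wt_reads(cfg)
  expect_identical(nrow(sim$truth), 0L)
  m <- merge_pairs(sim$reads)
  L <- nchar(s$frag$sequence)
  expected_reject <- 1 - (1 - eps)^(2 * L)
  got <- mean(m$status == "rejected")
  se <- sqrt(expected_reject * (1 - expected_reject) / 20000)
  expect_lt(abs(got - expected_reject), 4 * se)
  # per-base nonreference rate on the raw mate approximates epsilon
  ref_ch <- strsplit(s$frag$sequence, "")[[1]]
  sub <- sim$reads$r1[1:2000]
  mm <- vapply(sub, function(r) sum(strsplit(r, "")[[1]] != ref_ch),
               numeric(1))
  expect_lt(abs(mean(mm) / L - eps), 4 * sqrt(eps / (2000 * L)))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s <- toy_editor_setup()
  cfg <- sim_config(s$gene, list(f = s$frag), list(g = s$guide),
                    cytidine_editor(0.02), depth = 300, seed = 77)
  a <- simulate_reads(cfg); b <- simulate_reads(cfg)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fastq_pairs(a$reads, f1, f2)
  write_fastq_pairs(b$reads, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
  back <- read_fastq_pairs(f1, f2)
  expect_identical(back$r1, a$reads$r1)
  expect_identical(back$r2, a$reads$r2)
})

test_that("truth tables conserve counts", {
  s <- toy_editor_setup()
  cfg <- sim_config(s$gene, list(f = s$frag), list(g = s$guide),
                    cytidine_editor(0.1), depth = 500, seed = 6)
  tr <- simulate_reads(cfg)$truth
  expect_true(all(tr$n_edited >= 0 & tr$n_edited <= 500))
  expect_equal(tr$realized, tr$n_edited / 500)
})

test_that("plate-count simulation respects the frequency limits", {
  zero <- simulate_plate_counts(0, seed = 1)
  expect_true(all(zero$colonies[zero$medium == "selective"] == 0L))
  one <- simulate_plate_counts(1, culture_cfu_per_ml = 1e6, dilutions = 2,
                               drops_per_dilution = 200, n_replicates = 1,
                               seed = 2)
  # identical Poisson mean on both media at freq 1
  lam <- tapply(one$colonies, one$medium, mean)
  expect_lt(abs(lam["selective"] - lam["permissive"]),
            4 * sqrt(2 * lam["permissive"] / 200))
})

test_that("clone simulation injects editor-consistent substitutions only", {
  setup <- toy_setup()
  cl <- simulate_sanger_clones(60, adenine_editor(0.08), setup$guides,
                               setup$gene, seed = 9)
  expect_length(cl$sequences, 60)
  # every clone carries at least one edit
  expect_true(all(names(cl$sequences) %in% cl$truth$clone))
  # adenine editor: A>G on the coding strand for coding guides, T>C for
  # noncoding guides (here gRNA2/gRNA3 bind the noncoding strand)
  expect_true(all(paste0(cl$truth$ref, ">", cl$truth$alt)
                  %in% c("A>G", "T>C")))
  # single-position window concentrates all mutations at one position
  g1 <- setup$guides$gRNA1
  off <- -10L
  pos <- pam_relative_inv(g1, off)
  base_needed <- if (g1$strand == "coding") "A" else "T"
  ch <- strsplit(setup$gene$sequence, "")[[1]]; ch[pos] <- base_needed
  gene2 <- target_gene("g2", paste(ch, collapse = ""))
  ed <- editor_profile("one", "A", c(G = 1), flat_window(off, off, 0.3))
  cl2 <- simulate_sanger_clones(40, ed, setup$guides["gRNA1"], gene2,
                                seed = 10)
  expect_true(all(cl2$truth$pos == pos))
})

test_that("clone mutation frequencies track injected probabilities", {
  s <- toy_editor_setup()
  ed <- cytidine_editor(prob = 0.15)
  cl <- simulate_sanger_clones(500, ed, list(g = s$guide), s$gene, seed = 12)
  freq <- table(factor(cl$truth$pos,
                       levels = sort(unique(cl$truth$pos)))) / 500
  # conditioning on >= 1 edit inflates marginals by 1/(1 - P(no edit));
  # compare against that closed form
  w <- editing_window(s$guide, 20, s$gene)
  ch <- strsplit(s$gene$sequence, "")[[1]]
  editable <- sum(ch[w[1]:w[2]] == "C")
  p_none <- (1 - 0.15)^editable
  expected <- 0.15 / (1 - p_none)
  se <- sqrt(expected * (1 - expected) / 500)
  expect_true(all(abs(as.numeric(freq) - expected) < 4 * se))
})
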