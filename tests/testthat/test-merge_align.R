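test_that("a perfect pair merges to R1 and one overlap mismatch rejects at 0", {
  withr::with_seed(1, r1 <- rand_dna(80))
  ok <- merge_pair(r1, rc_slow(r1))
  expect_identical(ok$status, "merged")
  expect_identical(ok$merged, r1)
  # flip one base of the mate: one overlap mismatch, rejected at 0 tolerated
  r2 <- rc_slow(r1)
  substr(r2, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                substr(r2, 40, 40))[1]
  expect_identical(merge_pair(r1, r2, max_mismatch = 0)$status, "rejected")
  expect_identical(merge_pair(r1, r2, max_mismatch = 1)$status, "merged")
  expect_error(merge_pair("", "ACGT"), "empty")
})

test_that("merge decisions equal the brute-force all-offsets overlap scan", {
  withr::with_seed(99, {
    for (k in 1:120) {
      # random amplicon molecules with partial or full overlap and errors
      mol <- rand_dna(sample(40:90, 1))
      off <- sample(0:15, 1)
      r1 <- substr(mol, 1, nchar(mol) - off)
      r2 <- rc_slow(substr(mol, off + 1, nchar(mol)))
      n_err <- sample(0:2, 1)
      if (n_err > 0) {
        ch <- strsplit(r2, "")[[1]]
        at <- sample(length(ch), n_err)
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        r2 <- paste(ch, collapse = "")
      }
      got <- merge_pair(r1, r2, max_mismatch = 0)
      want <- bf_merge(r1, r2, max_mismatch = 0)
      expect_identical(got$merged, want, label = paste("case", k))
    }
  })
})

test_that("vectorized merging equals the single-pair path", {
  withr::with_seed(5, {
    pairs <- tibble::tibble(
      r1 = replicate(50, rand_dna(60)),
      r2 = NA_character_)
    pairs$r2 <- vapply(pairs$r1, rc_slow, character(1))
    # corrupt a third of the mates
    idx <- seq(1, 50, by = 3)
    pairs$r2[idx] <- vapply(pairs$r2[idx], function(s) {
      substr(s, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(s, 30, 30))[1]
      s
    }, character(1))
  })
  out <- merge_pairs(pairs)
  single <- mapply(function(a, b) merge_pair(a, b)$merged,
                   pairs$r1, pairs$r2)
  expect_identical(out$merged, unname(single))
})

test_that("global alignment reproduces trivial cases and the DP cost oracle", {
  gene <- toy_gene(60, seed = 3)
  frag <- fragment_spec("f", 1, 60, gene)
  same <- align_merged(frag$sequence, frag)
  expect_identical(same$cigar, "60=")
  expect_identical(same$cost, 0L)
  one <- frag$sequence
  substr(one, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(one, 20, 20))[1]
  a1 <- align_merged(one, frag)
  expect_identical(a1$cost, 1L)
  expect_false(grepl("[ID]", a1$cigar))
  expect_identical(align_merged(substr(frag$sequence, 1, 20), frag)$status,
                   "unalignable")
  # random substitution/indel reads vs the independent DP oracle
  withr::with_seed(11, {
    for (k in 1:120) {
      ch <- strsplit(frag$sequence, "")[[1]]
      for (j in sample(60, sample(0:6, 1))) {
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      }
      if (runif(1) < 0.4) ch <- ch[-sample(length(ch), 1)]     # deletion
      if (runif(1) < 0.2) {
        at <- sample(length(ch), 1)
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = at)
      }
      read <- paste(ch, collapse = "")
      got <- align_merged(read, frag)
      expect_identical(got$cost, as.integer(bf_nw_cost(read, frag$sequence)),
                       label = paste("case", k))
      # the op string is consistent with both sequence lengths
      lens <- as.integer(regmatches(got$cigar,
                                    gregexpr("[0-9]+", got$cigar))[[1]])
      ops <- regmatches(got$cigar, gregexpr("[=XID]", got$cigar))[[1]]
      expect_identical(sum(lens[ops != "D"]), nchar(read))
      expect_identical(sum(lens[ops != "I"]), 60L)
    }
  })
})

test_that("pileups tally alleles like a brute-force per-read walk", {
  gene <- toy_gene(40, seed = 8)
  frag <- fragment_spec("f", 1, 40, gene)
  # 10 identical reference reads
  al <- align_sample(tibble::tibble(merged = rep(frag$sequence, 10),
                                    status = "merged"), frag)
  pile <- build_pileup(al, frag)
  expect_true(all(pile$depth == 10L))
  cm <- as.matrix(pile[c("A", "C", "G", "T", "del")])
  expect_true(all(cm[cbind(seq_len(40), match(pile$ref, colnames(cm)))] == 10L))
  # constructed 7 A / 3 G at one position
  pos <- 15
  ref <- frag$sequence
  alt <- ref
  base_a <- ref; substr(base_a, pos, pos) <- "A"
  substr(alt, pos, pos) <- "G"
  al2 <- align_sample(tibble::tibble(
    merged = c(rep(base_a, 7), rep(alt, 3)), status = "merged"), frag)
  p2 <- build_pileup(al2, frag)
  expect_identical(p2$A[pos], 7L)
  expect_identical(p2$G[pos], 3L)
  expect_identical(p2$depth[pos], 10L)
  # random alignment sets vs the oracle, including indel reads
  withr::with_seed(21, {
    for (k in 1:25) {
      reads <- replicate(30, {
        ch <- strsplit(frag$sequence, "")[[1]]
        for (j in sample(40, sample(0:3, 1))) {
          ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
        }
        if (runif(1) < 0.2) ch <- ch[-sample(length(ch), 1)]
        paste(ch, collapse = "")
      })
      al3 <- align_sample(tibble::tibble(merged = reads, status = "merged"),
                          frag)
      p3 <- build_pileup(al3, frag)
      want <- bf_pileup(al3, frag)
      expect_identical(as.matrix(p3[c("A", "C", "G", "T", "del")]),
                       want, ignore_attr = TRUE)
      expect_identical(p3$depth, as.integer(rowSums(want)))
    }
  })
})

test_that("the per-position depth cap keeps the first reads in input order", {
  gene <- toy_gene(20, seed = 13)
  frag <- fragment_spec("f", 1, 20, gene)
  alt <- frag$sequence
  substr(alt, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(alt, 5, 5))[1]
  al <- tibble::tibble(seq = c(frag$sequence, alt), count = c(6L, 6L),
                       cigar = c("20=", align_merged(alt, frag)$cigar),
                       cost = c(0L, 1L), status = "aligned")
  pile <- build_pileup(al, frag, max_depth = 10)
  expect_true(all(pile$depth == 10L))
  # the reference sequence came first and keeps its full 6 counts
  expect_identical(pile[[frag$sequence |> substr(5, 5)]][5], 6L)
})

test_that("variant tables round-trip losslessly and conserve depth", {
  gene <- toy_gene(30, seed = 17)
  frag <- fragment_spec("f", 1, 30, gene)
  withr::with_seed(2, {
    reads <- replicate(20, {
      ch <- strsplit(frag$sequence, "")[[1]]
      j <- sample(30, 1)
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      paste(ch, collapse = "")
    })
  })
  pile <- build_pileup(
    align_sample(tibble::tibble(merged = reads, status = "merged"), frag),
    frag)
  path <- tempfile(fileext = ".tsv")
  write_variant_table(pile, path)
  back <- read_variant_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pile))
  expect_identical(back$depth,
                   as.integer(rowSums(back[c("A", "C", "G", "T", "del")])))
  # empty pileup -> header-only file
  write_variant_table(pile[0, ], path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_variant_table(path)), 0L)
})
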