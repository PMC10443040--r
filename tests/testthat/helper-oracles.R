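# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive re-implementations (loops, full enumeration) kept
# separate from the package code paths they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc_slow <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

toy_gene <- function(len = 200, seed = 42) {
  withr::with_seed(seed, target_gene("toy", rand_dna(len)))
}

toy_setup <- function() {
  gene <- read_gene_fasta(system.file("extdata", "can1_synthetic.fasta",
                                      package = "bescan"))
  feats <- read_features_tsv(system.file("extdata", "can1_features.tsv",
                                         package = "bescan"), gene)
  list(gene = gene, guides = feats$guides, fragments = feats$fragments)
}

# --- merge oracle: scan every relative offset of r2rc against r1 ----------
bf_merge <- function(r1, r2, max_mismatch = 0, min_overlap = 20) {
  b <- rc_slow(r2)
  a1 <- strsplit(r1, "")[[1]]
  a2 <- strsplit(b, "")[[1]]
  n1 <- length(a1); n2 <- length(a2)
  best <- NULL
  for (d in seq(-(n2 - 1), n1 - 1)) {
    lo <- max(1, d + 1); hi <- min(n1, d + n2)
    ov <- hi - lo + 1
    if (ov < min_overlap) next
    i <- lo:hi
    ca <- a1[i]; cb <- a2[i - d]
    mm <- sum(ca != cb | !(ca %in% c("A", "C", "G", "T")) |
                !(cb %in% c("A", "C", "G", "T")))
    if (mm > max_mismatch) next
    if (is.null(best) || ov > best$ov ||
        (ov == best$ov && (abs(d) < abs(best$d) ||
                           (abs(d) == abs(best$d) && d >= 0 && best$d < 0)))) {
      left <- if (d > 0) a1[1:d] else if (d < 0) a2[1:(-d)] else character(0)
      right <- if (d + n2 > n1) a2[(n1 - d + 1):n2]
               else if (n1 > hi) a1[(hi + 1):n1] else character(0)
      best <- list(ov = ov, d = d,
                   merged = paste(c(left, a1[i], right), collapse = ""))
    }
  }
  if (is.null(best)) NA_character_ else best$merged
}

# --- alignment cost oracle: plain quadratic DP, cost only -----------------
bf_nw_cost <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- (0:m) * 2
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- i * 2
    for (j in 1:m) {
      cur[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 2, cur[j] + 2)
    }
    prev <- cur
  }
  prev[m + 1]
}

# --- pileup oracle: per-read walk over the expanded operation string ------
bf_pileup <- function(alignments, fragment) {
  L <- nchar(fragment$sequence)
  tallies <- matrix(0L, L, 5, dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  for (i in seq_len(nrow(alignments))) {
    if (alignments$status[i] != "aligned") next
    lens <- as.integer(regmatches(alignments$cigar[i],
                                  gregexpr("[0-9]+", alignments$cigar[i]))[[1]])
    ops <- regmatches(alignments$cigar[i],
                      gregexpr("[=XID]", alignments$cigar[i]))[[1]]
    ops <- rep(ops, lens)
    rd <- strsplit(alignments$seq[i], "")[[1]]
    ri <- 0; fi <- 0
    for (rep_k in seq_len(alignments$count[i])) {
      ri <- 0; fi <- 0
      for (op in ops) {
        if (op == "I") { ri <- ri + 1; next }
        fi <- fi + 1
        if (op == "D") tallies[fi, "del"] <- tallies[fi, "del"] + 1L
        else { ri <- ri + 1; tallies[fi, rd[ri]] <- tallies[fi, rd[ri]] + 1L }
      }
    }
  }
  tallies
}

bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# --- Welch t oracle -------------------------------------------------------
bf_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Simulate + merge + align + distinct-read table for one fragment; shared
# by the diversity tests.
sim_unique_table <- function(cfg, frag, sample = "s", replicate = "r1",
                             wt = FALSE) {
  sim <- if (wt) simulate_wt_reads(cfg, sample, replicate)
         else simulate_reads(cfg, sample, replicate)
  al <- align_sample(merge_pairs(sim$reads), frag)
  collect_distinct(al, frag, sample = sample, replicate = replicate,
                   total_reads = cfg$depth)
}
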