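# Read-pair merging, global alignment to the fragment, and pileup building.
#
# Amplicon read pairs span their fragment completely, so merging reduces to
# finding the maximal mismatch-free complementary overlap, and alignment is
# a global (end-to-end) pairwise alignment to the fragment sequence — no
# genome-scale mapping is involved.

#' Merge one read pair by complementary overlap
#'
#' R2 is reverse-complemented and slid against R1 over every relative
#' offset; the longest overlap (at least `min_overlap` bp) with at most
#' `max_mismatch` mismatching positions wins (ties: smaller absolute offset,
#' then the non-negative one). Positions with non-ACGT characters count as
#' mismatches. With `max_mismatch = 0` the overlap consensus is exact by
#' construction.
#'
#' @param r1,r2 Mate sequences (R2 in sequencing orientation).
#' @param max_mismatch Mismatches tolerated in the overlap (default 0).
#' @param min_overlap Minimal acceptable overlap length in bp.
#' @return List with `merged` (sequence or `NA` on rejection) and `status`
#'   (`"merged"`/`"rejected"`).
#' @export
merge_pair <- function(r1, r2, max_mismatch = 0L, min_overlap = 20L) {
  if (!nzchar(r1) || !nzchar(r2)) stop("empty mate sequence", call. = FALSE)
  m <- merge_scan_cpp(r1, revcomp(r2), as.integer(max_mismatch),
                      as.integer(min_overlap))[1]
  list(merged = if (is.na(m)) NA_character_ else m,
       status = if (is.na(m)) "rejected" else "merged")
}

#' Merge a table of read pairs
#'
#' Vectorized [merge_pair()]: pairs whose R1 equals the reverse complement
#' of R2 (full-length, mismatch-free overlap — the designed case) take a
#' fast path; the remainder go through the full overlap scan.
#'
#' @param pairs Tibble with columns `r1`, `r2` (and any identifier columns,
#'   which are carried through).
#' @inheritParams merge_pair
#' @return The input tibble with `merged` and `status` columns added;
#'   rejected pairs keep `merged = NA`.
#' @export
merge_pairs <- function(pairs, max_mismatch = 0L, min_overlap = 20L) {
  stopifnot(all(c("r1", "r2") %in% names(pairs)))
  n <- nrow(pairs)
  merged <- rep(NA_character_, n)
  if (n > 0) {
    r2rc <- revcomp(pairs$r2)
    fast <- pairs$r1 == r2rc & nchar(pairs$r1) >= min_overlap
    merged[fast] <- pairs$r1[fast]
    slow <- which(!fast)
    if (length(slow) > 0) {
      merged[slow] <- merge_scan_cpp(pairs$r1[slow], r2rc[slow],
                                     as.integer(max_mismatch),
                                     as.integer(min_overlap))
    }
  }
  pairs$merged <- merged
  pairs$status <- ifelse(is.na(merged), "rejected", "merged")
  pairs
}

#' Globally align a merged read to its fragment
#'
#' End-to-end alignment with unit costs (match 0, mismatch 1, gap 2); ties
#' prefer mismatches over gaps. Reads shorter than half the fragment are
#' flagged unalignable. Equal-length reads within 3 mismatches of the
#' fragment take a Hamming fast path (a gapped alignment costs at least 4,
#' so the substitution-only alignment is provably optimal there).
#'
#' @param read Merged read sequence.
#' @param fragment A [fragment_spec()].
#' @return List with `cigar` (ops over `=`/`X`/`I`/`D`), `cost`, and
#'   `status` (`"aligned"`/`"unalignable"`).
#' @export
align_merged <- function(read, fragment) {
  ref <- fragment$sequence
  if (nchar(read) < nchar(ref) / 2) {
    return(list(cigar = NA_character_, cost = NA_integer_,
                status = "unalignable"))
  }
  if (nchar(read) == nchar(ref)) {
    h <- hamming_cpp(read, ref)[1]
    if (h <= 3) {
      if (h == 0) {
        return(list(cigar = paste0(nchar(ref), "="), cost = 0L,
                    status = "aligned"))
      }
      a <- split_chars(read); b <- split_chars(ref)
      ops <- ifelse(a == b, "=", "X")
      return(list(cigar = compress_ops(ops), cost = as.integer(h),
                  status = "aligned"))
    }
  }
  al <- nw_align_cpp(read, ref)
  list(cigar = al$cigar, cost = as.integer(al$cost), status = "aligned")
}

compress_ops <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

expand_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  rep(ops, lens)
}

#' Align the distinct sequences of a merged-read table
#'
#' Deduplicates merged reads before aligning (each distinct sequence is
#' aligned once) and returns one row per distinct sequence with its
#' occurrence count, in first-seen input order.
#'
#' @param merged Tibble from [merge_pairs()] (rejected rows are dropped).
#' @param fragment A [fragment_spec()].
#' @return Tibble (seq, count, cigar, cost, status) ordered by first
#'   appearance in the input.
#' @export
align_sample <- function(merged, fragment) {
  seqs <- merged$merged[merged$status == "merged"]
  if (length(seqs) == 0) {
    return(tibble::tibble(seq = character(), count = integer(),
                          cigar = character(), cost = integer(),
                          status = character()))
  }
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  counts <- as.integer(table(factor(seqs, levels = uniq)))
  al <- lapply(uniq, align_merged, fragment = fragment)
  tibble::tibble(seq = uniq, count = counts,
                 cigar = vapply(al, `[[`, character(1), "cigar"),
                 cost = vapply(al, function(x) as.integer(x$cost), integer(1)),
                 status = vapply(al, `[[`, character(1), "status"))
}

#' Build a per-position allele-count pileup
#'
#' Walks each alignment's operation string to tally the observed base (or a
#' deletion) at every fragment position, in gene coordinates. Insertions
#' contribute no positional count. Reads are consumed in input order; once
#' a position has reached `max_depth` observations, further reads do not
#' add to it.
#'
#' @param alignments Tibble from [align_sample()] (aligned rows only are
#'   used).
#' @param fragment A [fragment_spec()].
#' @param sample,replicate Identifiers stamped on the table.
#' @param max_depth Per-position depth cap.
#' @return A pileup tibble (sample, replicate, fragment, pos, ref, A, C, G,
#'   T, del, depth).
#' @export
build_pileup <- function(alignments, fragment, sample = "sample",
                         replicate = "r1", max_depth = 600000L) {
  L <- nchar(fragment$sequence)
  counts <- matrix(0L, nrow = L, ncol = 5,
                   dimnames = list(NULL, ALLELES))
  remaining <- rep(as.integer(max_depth), L)
  keep <- alignments$status == "aligned"
  for (i in which(keep)) {
    ops <- expand_cigar(alignments$cigar[i])
    rd <- split_chars(alignments$seq[i])
    n <- alignments$count[i]
    ri <- 0L; fi <- 0L
    for (op in ops) {
      if (op == "I") { ri <- ri + 1L; next }
      fi <- fi + 1L
      allele <- if (op == "D") "del" else { ri <- ri + 1L; rd[ri] }
      if (op != "D" && !(allele %in% DNA_BASES)) next  # ambiguous call
      add <- min(n, remaining[fi])
      if (add > 0) {
        counts[fi, allele] <- counts[fi, allele] + add
        remaining[fi] <- remaining[fi] - add
      }
    }
  }
  positions <- seq.int(fragment$start, fragment$end)
  ref_chars <- split_chars(fragment$sequence)
  tibble::tibble(
    sample = sample, replicate = replicate, fragment = fragment$name,
    pos = positions, ref = ref_chars,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], del = counts[, "del"],
    depth = as.integer(rowSums(counts)))
}

#' Write a pileup as a VCF-like tab-separated variant table
#'
#' One row per position with the reference base, the five allele counts and
#' the depth; the header line starts with `#`. Round-trips losslessly
#' through [read_variant_table()].
#'
#' @param pileup A pileup tibble from [build_pileup()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(pileup, path) {
  cols <- c("sample", "replicate", "fragment", "pos", "ref",
            "A", "C", "G", "T", "del", "depth")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(pileup) > 0) {
    write.table(pileup[cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a VCF-like variant table written by [write_variant_table()]
#'
#' @param path TSV path.
#' @return A pileup tibble.
#' @export
read_variant_table <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  classes <- c(rep("character", 3), "integer", "character", rep("integer", 6))
  if (length(lines) <= 1) {
    empty <- lapply(classes, function(cl) vector(cl, 0))
    names(empty) <- cols
    return(tibble::as_tibble(empty))
  }
  tab <- read.delim(text = lines[-1], header = FALSE, col.names = cols,
                    colClasses = classes)
  tibble::as_tibble(tab)
}
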