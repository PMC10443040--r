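# Sanger clone analysis: pairwise alignment of clone reads to the
# reference, per-position clone mutation rates, and PAM-relative editing
# profiles. Clones are near-identical to the reference, so independent
# pairwise global alignments (same cost scheme as the amplicon aligner)
# replace a multiple alignment without loss for substitution calls.

#' Align one Sanger clone to the reference region
#'
#' Global alignment with unit costs (match 0, mismatch 1, gap 2);
#' substitutions are extracted from mismatch columns. Clones under the
#' identity threshold are flagged as failed reads and carry no calls;
#' ambiguous (non-ACGT) clone positions are treated as failed basecalls and
#' excluded from the substitution list.
#'
#' @param clone_seq Clone sequence (may contain IUPAC ambiguity codes,
#'   which are never called as substitutions).
#' @param reference A [fragment_spec()]-like region (fields `start`,
#'   `sequence`) or a [target_gene()] (aligned from position 1).
#' @param clone Clone identifier.
#' @param min_identity Minimum fraction of alignment columns that are
#'   matches for the read to be accepted (default 0.8).
#' @return List with `clone`, `status` (`"ok"`, `"failed"`), `indel`
#'   (logical), `n_ambiguous`, and `substitutions` — tibble (clone, pos,
#'   ref, alt) in gene coordinates.
#' @export
align_clone <- function(clone_seq, reference, clone = "clone",
                        min_identity = 0.8) {
  start <- reference$start %||% 1L
  ref_seq <- reference$sequence
  clone_seq <- toupper(clone_seq)
  al <- nw_align_cpp(clone_seq, ref_seq)
  ops <- expand_cigar(al$cigar)
  identity <- sum(ops == "=") / length(ops)
  empty <- tibble::tibble(clone = character(), pos = integer(),
                          ref = character(), alt = character())
  if (identity < min_identity) {
    return(list(clone = clone, status = "failed", indel = NA,
                n_ambiguous = NA_integer_, substitutions = empty))
  }
  rd <- split_chars(clone_seq)
  rf <- split_chars(ref_seq)
  ri <- 0L; fi <- 0L
  pos <- integer(0); refb <- character(0); altb <- character(0)
  n_amb <- 0L
  for (op in ops) {
    if (op == "I") { ri <- ri + 1L; next }
    fi <- fi + 1L
    if (op == "D") next
    ri <- ri + 1L
    if (op == "X") {
      if (rd[ri] %in% DNA_BASES) {
        pos <- c(pos, fi); refb <- c(refb, rf[fi]); altb <- c(altb, rd[ri])
      } else {
        n_amb <- n_amb + 1L
      }
    }
  }
  list(clone = clone, status = "ok", indel = any(ops %in% c("I", "D")),
       n_ambiguous = n_amb,
       substitutions = tibble::tibble(clone = clone,
                                      pos = pos + start - 1L,
                                      ref = refb, alt = altb))
}

#' Align a set of clones
#'
#' @param sequences Named character vector of clone sequences.
#' @param reference As in [align_clone()].
#' @param min_identity Identity threshold per clone.
#' @return List with `substitutions` (tibble over all accepted clones),
#'   `clones` (tibble clone, status, indel, n_ambiguous) and `n_failed`.
#' @export
align_clones <- function(sequences, reference, min_identity = 0.8) {
  res <- lapply(names(sequences), function(id) {
    align_clone(sequences[[id]], reference, clone = id,
                min_identity = min_identity)
  })
  clones <- tibble::tibble(
    clone = vapply(res, `[[`, character(1), "clone"),
    status = vapply(res, `[[`, character(1), "status"),
    indel = vapply(res, function(x) as.logical(x$indel), logical(1)),
    n_ambiguous = vapply(res, function(x) as.integer(x$n_ambiguous),
                         integer(1)))
  subs <- dplyr::bind_rows(lapply(res, `[[`, "substitutions"))
  list(substitutions = subs, clones = clones,
       n_failed = sum(clones$status == "failed"))
}

#' Per-position clone mutation rate
#'
#' The percentage of accepted clones that carry a substitution at each
#' mutated position.
#'
#' @param substitutions Tibble (clone, pos, ref, alt) from [align_clones()].
#' @param n_clones Total number of accepted clones.
#' @return Tibble (pos, ref, n_mutated, rate_percent), one row per position
#'   with at least one mutated clone.
#' @export
clone_mutation_rate <- function(substitutions, n_clones) {
  stopifnot(n_clones >= 1)
  if (nrow(substitutions) == 0) {
    return(tibble::tibble(pos = integer(), ref = character(),
                          n_mutated = integer(), rate_percent = numeric()))
  }
  per_pos <- dplyr::summarise(
    dplyr::group_by(substitutions, .data$pos, .data$ref),
    n_mutated = dplyr::n_distinct(.data$clone), .groups = "drop")
  per_pos$rate_percent <- 100 * per_pos$n_mutated / n_clones
  dplyr::arrange(per_pos, .data$pos)
}

#' PAM-relative substitution profile of a clone set
#'
#' Re-indexes clone substitutions to PAM-relative offsets of one guide and
#' tallies them by substitution class; calls farther than 100 bp from the
#' PAM are kept but flagged out-of-window.
#'
#' @param substitutions Tibble (clone, pos, ref, alt).
#' @param guide A guide with a derived PAM.
#' @return Tibble (offset, pos, class, n, out_of_window) sorted by offset.
#' @export
pam_window_profile <- function(substitutions, guide) {
  if (nrow(substitutions) == 0) {
    return(tibble::tibble(offset = integer(), pos = integer(),
                          class = character(), n = integer(),
                          out_of_window = logical()))
  }
  subs <- substitutions
  subs$offset <- pam_relative(guide, subs$pos)
  subs$class <- paste0(subs$ref, ">", subs$alt)
  out <- dplyr::summarise(
    dplyr::group_by(subs, .data$offset, .data$pos, .data$class),
    n = dplyr::n(), .groups = "drop")
  out$out_of_window <- abs(out$offset) > 100
  dplyr::arrange(out, .data$offset)
}
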