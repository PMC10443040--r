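# Read-by-read editing-diversity analysis: distinct-read tallies, SNP
# counts against the fragment template, WT background removal, per-kiloread
# depth normalization and replicate significance testing.

#' Collect distinct merged reads with counts and SNP numbers
#'
#' Deduplicates aligned merged reads; entries whose alignment contains
#' insertion or deletion operations are flagged (`indel = TRUE`) and carry
#' `n_snps = NA` — they are excluded from all downstream SNP statistics.
#' Indel-free reads have the fragment's length by construction, so the SNP
#' count is their Hamming distance to the template.
#'
#' @param alignments Tibble from [align_sample()].
#' @param fragment The [fragment_spec()] template.
#' @param sample,replicate Identifiers stamped on the table.
#' @param total_reads Sequencing depth of the sample (read pairs sequenced);
#'   defaults to the summed occurrence counts of the alignments.
#' @return A unique-read tibble (sample, replicate, fragment, seq, count,
#'   indel, n_snps, total_reads).
#' @export
collect_distinct <- function(alignments, fragment, sample = "sample",
                             replicate = "r1", total_reads = NULL) {
  al <- alignments[alignments$status == "aligned", , drop = FALSE]
  total_reads <- total_reads %||% sum(al$count)
  indel <- grepl("[ID]", al$cigar)
  n_snps <- rep(NA_integer_, nrow(al))
  if (any(!indel)) {
    n_snps[!indel] <- hamming_cpp(al$seq[!indel], fragment$sequence)
    if (anyNA(n_snps[!indel])) {
      stop("indel-free read with length differing from the template",
           call. = FALSE)
    }
  }
  tibble::tibble(sample = sample, replicate = replicate,
                 fragment = fragment$name, seq = al$seq, count = al$count,
                 indel = indel, n_snps = n_snps,
                 total_reads = as.integer(total_reads))
}

#' SNP count between one read and the template
#'
#' Hamming distance; sequences must have equal length (guaranteed for
#' indel-free global alignments).
#'
#' @param sequence,template Equal-length DNA strings.
#' @return Integer substitution count.
#' @export
snp_count <- function(sequence, template) {
  h <- hamming_cpp(sequence, template)[1]
  if (is.na(h)) stop("sequences differ in length", call. = FALSE)
  h
}

#' Remove WT background reads from a unique-read table
#'
#' Sequences whose occurrence count summed over the WT tables reaches
#' `min_occurrences` are removed, as is the reference (template) sequence
#' itself — it is the WT majority read, not an edit.
#'
#' @param table A unique-read tibble ([collect_distinct()]).
#' @param wt_tables List of unique-read tibbles from WT samples of the same
#'   fragment (may be empty).
#' @param fragment The [fragment_spec()] whose sequence is the reference.
#' @param min_occurrences Summed WT count at which a sequence is treated as
#'   background (default 5).
#' @return The filtered unique-read tibble.
#' @export
filter_wt_background <- function(table, wt_tables, fragment,
                                 min_occurrences = 5L) {
  if (is.data.frame(wt_tables)) wt_tables <- list(wt_tables)
  wt <- dplyr::bind_rows(wt_tables)
  background <- character(0)
  if (nrow(wt) > 0) {
    sums <- tapply(wt$count, wt$seq, sum)
    background <- names(sums)[sums >= min_occurrences]
  }
  table[!(table$seq %in% c(background, fragment$sequence)), , drop = FALSE]
}

#' Depth-normalize a count per kiloread sequenced
#'
#' @param count Count(s) to normalize.
#' @param total_reads Reads sequenced in the sample (> 0).
#' @return `count / (total_reads / 1000)`.
#' @export
normalize_per_kiloread <- function(count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive", call. = FALSE)
  count / (total_reads / 1000)
}

#' Distinct-read counts grouped by SNP number
#'
#' The editing-diversity histogram: for each SNP count >= 1, the number of
#' distinct (indel-free) read sequences carrying that many substitutions,
#' with its per-kiloread normalized variant.
#'
#' @param table A filtered unique-read tibble.
#' @return Tibble (sample, replicate, fragment, n_snps, distinct_reads,
#'   distinct_reads_per_kiloread).
#' @export
group_by_snps <- function(table) {
  keep <- table[!table$indel & !is.na(table$n_snps) & table$n_snps >= 1, ,
                drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble::tibble(sample = character(), replicate = character(),
                          fragment = character(), n_snps = integer(),
                          distinct_reads = integer(),
                          distinct_reads_per_kiloread = numeric()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(keep, .data$sample, .data$replicate, .data$fragment,
                    .data$n_snps),
    distinct_reads = dplyr::n(),
    total_reads = .data$total_reads[1], .groups = "drop")
  out$distinct_reads_per_kiloread <-
    normalize_per_kiloread(out$distinct_reads, out$total_reads)
  out$total_reads <- NULL
  out
}

#' Summarize editing diversity of one sample replicate
#'
#' @param table A filtered unique-read tibble.
#' @return One-row tibble (sample, replicate, fragment, unique_reads,
#'   unique_reads_per_kiloread).
#' @export
diversity_summary <- function(table) {
  keep <- table[!table$indel & !is.na(table$n_snps) & table$n_snps >= 1, ,
                drop = FALSE]
  tibble::tibble(
    sample = table$sample[1] %||% NA_character_,
    replicate = table$replicate[1] %||% NA_character_,
    fragment = table$fragment[1] %||% NA_character_,
    unique_reads = nrow(keep),
    unique_reads_per_kiloread =
      if (nrow(table) > 0) normalize_per_kiloread(nrow(keep), table$total_reads[1])
      else 0)
}

#' Compare depth-normalized unique-read counts against a control group
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on the per-replicate
#' normalized unique-read counts. Degenerate data (both groups constant,
#' where the t statistic is undefined) is reported as not significant with
#' p = 1.
#'
#' @param sample_values,control_values Numeric vectors of per-replicate
#'   normalized counts (>= 2 values each).
#' @return Tibble (p_value, stars) where stars are `***`/`**`/`*` at
#'   0.001/0.01/0.05 and `ns` otherwise.
#' @export
compare_to_control <- function(sample_values, control_values) {
  if (length(sample_values) < 2 || length(control_values) < 2) {
    stop("at least two replicates per group are required", call. = FALSE)
  }
  p <- tryCatch(
    t.test(sample_values, control_values)$p.value,
    error = function(e) 1)
  tibble::tibble(p_value = p, stars = significance_stars(p))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
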