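# Mutation spectra: depth filtering, end trimming, per-position and
# per-class mutated proportions, WT subtraction, and the empirical WT
# background band.
#
# Substitution classes are the 12 base substitutions plus the 4
# base-to-deletion classes, written "REF>ALT" with "del" as the deletion
# outcome; proportions are always reported on the coding strand.

#' Remove pileup positions below a depth threshold
#'
#' @param pileup A pileup tibble ([build_pileup()]).
#' @param min_depth Positions with depth strictly below this are discarded.
#' @return The filtered pileup; warns (not errors) when nothing survives.
#' @export
filter_depth <- function(pileup, min_depth = 50000L) {
  out <- pileup[pileup$depth >= min_depth, , drop = FALSE]
  if (nrow(out) == 0 && nrow(pileup) > 0) {
    warning("all ", nrow(pileup), " positions fall below min_depth = ",
            min_depth, "; result is empty", call. = FALSE)
  }
  out
}

#' Trim the ends of a sequenced fragment from a pileup
#'
#' @param pileup A pileup tibble.
#' @param fragment The [fragment_spec()] the pileup was built on.
#' @param n_trim Positions removed from each fragment end.
#' @return The trimmed pileup.
#' @export
trim_fragment_ends <- function(pileup, fragment, n_trim = 5L) {
  stopifnot(n_trim >= 0)
  flen <- fragment$end - fragment$start + 1L
  if (2L * n_trim >= flen) {
    stop("n_trim = ", n_trim, " removes the whole ", flen, "-bp fragment",
         call. = FALSE)
  }
  lo <- fragment$start + n_trim
  hi <- fragment$end - n_trim
  pileup[pileup$pos >= lo & pileup$pos <= hi, , drop = FALSE]
}

#' Per-position and per-class mutated proportions
#'
#' For every retained position, the nonreference proportion
#' `(depth - ref count)/depth` and, for each of the 16 substitution classes
#' possible there (3 substitutions + deletion per reference base), the class
#' count divided by depth.
#'
#' @param pileup A pileup tibble with positive depth at every row.
#' @return A tidy spectrum tibble (sample, replicate, fragment, pos, ref,
#'   class, alt, count, proportion, p_mut, wt_subtracted = FALSE); `p_mut`
#'   repeats the per-position nonreference proportion on each class row.
#' @export
mutated_proportion <- function(pileup) {
  stopifnot(all(pileup$depth > 0))
  if (nrow(pileup) == 0) {
    return(tibble::tibble(sample = character(), replicate = character(),
                          fragment = character(), pos = integer(),
                          ref = character(), alt = character(),
                          class = character(), count = integer(),
                          proportion = numeric(), p_mut = numeric(),
                          wt_subtracted = logical()))
  }
  mat <- as.matrix(pileup[ALLELES])
  ref_count <- mat[cbind(seq_len(nrow(pileup)), match(pileup$ref, ALLELES))]
  pileup$p_mut <- (pileup$depth - ref_count) / pileup$depth
  long <- tidyr::pivot_longer(pileup, cols = dplyr::all_of(ALLELES),
                              names_to = "alt", values_to = "count")
  long <- long[long$alt != long$ref, ]
  long$class <- paste0(long$ref, ">", long$alt)
  long$proportion <- long$count / long$depth
  long$depth <- NULL
  long$wt_subtracted <- FALSE
  long[c("sample", "replicate", "fragment", "pos", "ref", "alt", "class",
         "count", "proportion", "p_mut", "wt_subtracted")]
}

#' Subtract the WT background spectrum from a sample spectrum
#'
#' Elementwise `sample - wt` on both the class proportions and the
#' per-position totals, clamped at zero; only positions present in both
#' tables are kept (the intersection).
#'
#' @param sample_spec,wt_spec Spectrum tibbles from [mutated_proportion()].
#' @return The WT-subtracted spectrum (`wt_subtracted = TRUE`).
#' @export
subtract_wt <- function(sample_spec, wt_spec) {
  common <- intersect(sample_spec$pos, wt_spec$pos)
  if (length(common) == 0) {
    stop("sample and WT spectra share no positions", call. = FALSE)
  }
  s <- sample_spec[sample_spec$pos %in% common, ]
  w <- wt_spec[wt_spec$pos %in% common, c("pos", "class", "proportion", "p_mut")]
  names(w)[3:4] <- c("wt_proportion", "wt_p_mut")
  out <- dplyr::left_join(s, w, by = c("pos", "class"))
  out$wt_proportion[is.na(out$wt_proportion)] <- 0
  out$wt_p_mut[is.na(out$wt_p_mut)] <- 0
  out$proportion <- pmax(0, out$proportion - out$wt_proportion)
  out$p_mut <- pmax(0, out$p_mut - out$wt_p_mut)
  out$wt_proportion <- NULL
  out$wt_p_mut <- NULL
  out$count <- NULL
  out$wt_subtracted <- TRUE
  out
}

#' Empirical WT background band per substitution class
#'
#' For each class, the upper bound below which the requested fraction of all
#' pooled WT (position, replicate) proportions lie — the one-sided empirical
#' quantile (type 1: the smallest observed value with at least `coverage`
#' of the mass at or below it).
#'
#' @param wt_spectra One spectrum tibble, or a list of them (replicates),
#'   from [mutated_proportion()] on WT samples.
#' @param coverage Fraction of WT events the band must cover (in (0, 1)).
#' @return Tibble (class, bound).
#' @export
wt_background_band <- function(wt_spectra, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) {
    stop("coverage must lie in (0, 1)", call. = FALSE)
  }
  if (is.data.frame(wt_spectra)) wt_spectra <- list(wt_spectra)
  pooled <- dplyr::bind_rows(wt_spectra)
  if (nrow(pooled) == 0) stop("no WT spectrum values supplied", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(pooled, .data$class),
    bound = {
      v <- sort(.data$proportion)
      v[ceiling(coverage * length(v))]
    },
    .groups = "drop")
}

#' Per-position total mutated proportion of a spectrum table
#'
#' Collapses class rows to one row per position (the per-position
#' nonreference proportion).
#'
#' @param spectrum A spectrum tibble.
#' @return Tibble (sample, replicate, fragment, pos, ref, p_mut,
#'   wt_subtracted).
#' @export
position_totals <- function(spectrum) {
  dplyr::distinct(spectrum, .data$sample, .data$replicate, .data$fragment,
                  .data$pos, .data$ref, .data$p_mut, .data$wt_subtracted)
}
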