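# Canavanine-resistance frequencies from serial-dilution drop counts.

#' Viable titer per medium from drop counts
#'
#' A drop is countable when its colony count lies in the countable window
#' (default 3–150 colonies per 10 uL drop); the titer is the mean over
#' countable drops of `colonies x dilution_factor / drop_volume`, in
#' cfu/mL. When no drop is countable: all-zero drops give a titer of 0
#' flagged `below_detection`; otherwise, with `rare_event_fallback = TRUE`
#' (the default) the least-diluted dilution's drops are pooled — the
#' practical rule for rare resistant colonies — and with the fallback
#' disabled an error listing every drop is raised.
#'
#' @param counts Plate-count tibble for one replicate of one strain
#'   (columns medium, dilution_factor, colonies; see
#'   [simulate_plate_counts()]).
#' @param drop_volume_ul Spotted volume per drop.
#' @param countable Inclusive colony-count window defining a countable drop.
#' @param rare_event_fallback Pool the least-diluted drops when no drop is
#'   countable but colonies were seen.
#' @return Tibble (medium, cfu_per_ml, n_countable, below_detection).
#' @export
cfu_per_ml <- function(counts, drop_volume_ul = 10, countable = c(3, 150),
                       rare_event_fallback = TRUE) {
  vol_ml <- drop_volume_ul / 1000
  one_medium <- function(cc) {
    ok <- cc$colonies >= countable[1] & cc$colonies <= countable[2]
    if (any(ok)) {
      titer <- mean(cc$colonies[ok] * cc$dilution_factor[ok]) / vol_ml
      return(tibble::tibble(cfu_per_ml = titer, n_countable = sum(ok),
                            below_detection = FALSE))
    }
    if (all(cc$colonies == 0)) {
      return(tibble::tibble(cfu_per_ml = 0, n_countable = 0L,
                            below_detection = TRUE))
    }
    if (!rare_event_fallback) {
      stop("no countable drop (window ", countable[1], "-", countable[2],
           "); drops: ",
           paste0(cc$dilution_factor, ":", cc$colonies, collapse = ", "),
           call. = FALSE)
    }
    low <- cc[cc$dilution_factor == min(cc$dilution_factor), ]
    titer <- sum(low$colonies) * low$dilution_factor[1] /
      (nrow(low) * vol_ml)
    tibble::tibble(cfu_per_ml = titer, n_countable = 0L,
                   below_detection = FALSE)
  }
  out <- lapply(split(counts, counts$medium), one_medium)
  dplyr::bind_rows(out, .id = "medium")
}

#' Resistance frequency from selective and permissive titers
#'
#' @param selective_titer,permissive_titer Titers in cfu/mL (permissive
#'   must be > 0).
#' @return Tibble (rate, log10_rate, below_detection); a selective titer of
#'   0 gives rate 0 with `log10_rate = NA` (below detection).
#' @export
canr_rate <- function(selective_titer, permissive_titer) {
  if (permissive_titer <= 0) {
    stop("permissive titer must be positive", call. = FALSE)
  }
  rate <- selective_titer / permissive_titer
  tibble::tibble(rate = rate,
                 log10_rate = ifelse(rate > 0, log10(rate), NA_real_),
                 below_detection = rate == 0)
}

#' Resistance frequencies of a full plating experiment
#'
#' Technical drops are averaged within each biological replicate (via
#' [cfu_per_ml()]); per-replicate rates are summarized by their geometric
#' mean, the natural center for frequencies spanning orders of magnitude.
#'
#' @param counts Plate-count tibble (possibly several strains/replicates).
#' @inheritParams cfu_per_ml
#' @return List with `replicates` (per-replicate rates) and `summary`
#'   (per-strain geometric-mean rate with log10 spread).
#' @export
canr_experiment <- function(counts, drop_volume_ul = 10,
                            countable = c(3, 150),
                            rare_event_fallback = TRUE) {
  reps <- dplyr::bind_rows(lapply(
    split(counts, list(counts$strain, counts$replicate), drop = TRUE),
    function(cc) {
      titers <- cfu_per_ml(cc, drop_volume_ul, countable, rare_event_fallback)
      sel <- titers$cfu_per_ml[titers$medium == "selective"]
      perm <- titers$cfu_per_ml[titers$medium == "permissive"]
      dplyr::bind_cols(
        tibble::tibble(strain = cc$strain[1], replicate = cc$replicate[1]),
        canr_rate(sel, perm))
    }))
  summary <- dplyr::bind_rows(lapply(split(reps, reps$strain), function(rr) {
    all_pos <- all(rr$rate > 0)
    tibble::tibble(
      strain = rr$strain[1],
      rate = if (all_pos) exp(mean(log(rr$rate))) else 0,
      log10_rate = if (all_pos) mean(log10(rr$rate)) else NA_real_,
      log10_sd = if (all_pos && nrow(rr) > 1) stats::sd(log10(rr$rate))
                 else NA_real_,
      n_replicates = nrow(rr))
  }))
  list(replicates = reps, summary = summary)
}
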