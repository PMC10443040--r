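# Seeded generator of synthetic amplicon read pairs, plate counts, and
# Sanger clone sequences with the statistical structure the downstream
# analysis assumes.
#
# Design notes:
# * Editing is applied at the molecule level before read-pair generation, so
#   both mates carry each edit; sequencing errors are mate-independent and
#   are therefore mostly purged by 0-mismatch overlap merging.
# * A low molecule-level background substitution rate is applied to every
#   sample (including WT) so that WT controls carry the nonzero background
#   band real amplicon data shows.
# * Reads span their fragment exactly (perfect-overlap amplicon design);
#   qualities are constant Q37, Phred+33.

#' Construct a base-editor profile
#'
#' @param name Editor identifier.
#' @param target_base Deaminated base on the protospacer strand: `"C"` for
#'   cytidine editors, `"A"` for adenine editors.
#' @param substitution_weights Named probability weights over the edit
#'   outcomes on the protospacer strand; names from the three alternative
#'   bases and `"del"` (single-base deletion). Must sum to 1.
#' @param window Named numeric vector mapping PAM-relative offsets (names)
#'   to per-molecule editing probabilities in `[0, 1]`.
#' @param synergy_factor Multiplier (>= 1) applied where two or more guides'
#'   windows overlap.
#' @return An `editor_profile` object.
#' @export
editor_profile <- function(name, target_base = c("C", "A"),
                           substitution_weights, window,
                           synergy_factor = 1) {
  target_base <- match.arg(target_base)
  ok_names <- c(setdiff(DNA_BASES, target_base), "del")
  if (!all(names(substitution_weights) %in% ok_names) ||
      abs(sum(substitution_weights) - 1) > 1e-8) {
    stop("substitution_weights must be named over ",
         paste(ok_names, collapse = "/"), " and sum to 1", call. = FALSE)
  }
  if (any(window < 0 | window > 1)) {
    stop("window probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (synergy_factor < 1) stop("synergy_factor must be >= 1", call. = FALSE)
  structure(
    list(name = name, target_base = target_base,
         substitution_weights = substitution_weights,
         window = window, synergy_factor = synergy_factor),
    class = "editor_profile"
  )
}

#' Flat editing window over a PAM-relative offset range
#'
#' @param from,to Offset range (inclusive).
#' @param prob Per-molecule editing probability at each offset.
#' @return Named numeric vector usable as an [editor_profile()] window.
#' @export
flat_window <- function(from, to, prob) {
  offs <- seq.int(min(from, to), max(from, to))
  setNames(rep(prob, length(offs)), offs)
}

#' Default cytidine-deaminase editor (AID-like)
#'
#' Plateau window over offsets -20..+20 around the PAM; C on the protospacer
#' strand is edited mostly to T, with minor G/A outcomes and rare single-base
#' deletions.
#'
#' @param prob Per-molecule editing probability inside the window.
#' @param synergy_factor Overlap multiplier for multiplexed guides.
#' @return An [editor_profile()].
#' @export
cytidine_editor <- function(prob = 0.01, synergy_factor = 2) {
  editor_profile("AID-like", "C",
                 c(T = 0.70, G = 0.15, A = 0.10, del = 0.05),
                 flat_window(-20, 20, prob), synergy_factor)
}

#' Default adenine-deaminase editor (TadA8e-like)
#'
#' Window confined to offsets -21..-7 inside the protospacer; A on the
#' protospacer strand is edited to G exclusively (seen as T>C on the coding
#' strand for noncoding-strand guides).
#'
#' @inheritParams cytidine_editor
#' @return An [editor_profile()].
#' @export
adenine_editor <- function(prob = 0.01, synergy_factor = 1) {
  editor_profile("TadA8e-like", "A", c(G = 1),
                 flat_window(-21, -7, prob), synergy_factor)
}

#' Null editor (no editing activity)
#'
#' @return An [editor_profile()] whose window is identically zero.
#' @export
null_editor <- function() {
  editor_profile("null", "C", c(T = 1), flat_window(-1, 1, 0), 1)
}

#' Simulation configuration
#'
#' @param gene A [target_gene()].
#' @param fragments List of [fragment_spec()]s to sequence.
#' @param guides List of [guide_spec()]s with derived PAMs.
#' @param editor An [editor_profile()].
#' @param depth Read pairs per fragment.
#' @param seq_error_rate Per-base, per-mate sequencing error probability
#'   (must be < 0.01).
#' @param background_rate Per-base molecule-level background substitution
#'   rate applied to all samples (WT band).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(gene, fragments, guides, editor,
                       depth = 50000L, seq_error_rate = 0.001,
                       background_rate = 1e-4, seed = NULL) {
  stopifnot(depth > 0, seq_error_rate >= 0, seq_error_rate < 0.01,
            background_rate >= 0, background_rate < 0.01)
  for (g in guides) {
    if (!has_pam(g)) stop("guide '", g$name, "' has no derived PAM", call. = FALSE)
  }
  structure(
    list(gene = gene, fragments = fragments, guides = guides, editor = editor,
         depth = as.integer(depth), seq_error_rate = seq_error_rate,
         background_rate = background_rate, seed = seed),
    class = "sim_config"
  )
}

# Editable positions of one fragment under the configured editor/guides:
# tibble(idx [fragment-local], pos, prob, alt_bases, alt_weights).
# A position is editable when a guide window covers it and the reference
# base matches the editor's target base on that guide's strand; positions
# covered by >= 2 windows get the synergy multiplier (capped at 1).
editable_positions <- function(cfg, fragment) {
  ed <- cfg$editor
  offs <- as.integer(names(ed$window))
  active <- offs[ed$window > 0]
  if (length(active) == 0 || length(cfg$guides) == 0) {
    return(tibble::tibble(idx = integer(), pos = integer(), prob = numeric(),
                          outcome = list()))
  }
  per_guide <- lapply(cfg$guides, function(g) {
    pos <- pam_relative_inv(g, active)
    keep <- pos >= fragment$start & pos <= fragment$end &
      pos >= 1 & pos <= cfg$gene$length
    tibble::tibble(guide = g$name, strand = g$strand, pos = pos[keep],
                   prob = unname(ed$window[as.character(active)])[keep])
  })
  cov <- dplyr::bind_rows(per_guide)
  if (nrow(cov) == 0) {
    return(tibble::tibble(idx = integer(), pos = integer(), prob = numeric(),
                          outcome = list()))
  }
  ref_base <- substring(cfg$gene$sequence, cov$pos, cov$pos)
  # base the guide sees on its bound strand
  seen <- ifelse(cov$strand == "coding", ref_base, dna_complement(ref_base))
  n_windows <- table(unique(cov[c("guide", "pos")])$pos)
  cov <- cov[seen == ed$target_base, , drop = FALSE]
  if (nrow(cov) == 0) {
    return(tibble::tibble(idx = integer(), pos = integer(), prob = numeric(),
                          outcome = list()))
  }
  cov <- cov[order(cov$pos, -cov$prob), ]
  best <- cov[!duplicated(cov$pos), ]
  synergy <- ifelse(as.integer(n_windows[as.character(best$pos)]) >= 2,
                    cfg$editor$synergy_factor, 1)
  best$prob <- pmin(1, best$prob * synergy)
  # outcome alternatives expressed on the coding strand
  w <- ed$substitution_weights
  outcome <- lapply(seq_len(nrow(best)), function(i) {
    alts <- names(w)
    if (best$strand[i] == "noncoding") {
      alts <- ifelse(alts == "del", "del", dna_complement(alts))
    }
    list(alts = ifelse(alts == "del", "-", alts), weights = unname(w))
  })
  tibble::tibble(idx = best$pos - fragment$start + 1L, pos = best$pos,
                 prob = best$prob, outcome = outcome)
}

# Draw molecule-level edits for one fragment. Returns list(edits = tibble
# (mol, idx, alt), realized = integer per editable row).
draw_edits <- function(edit_tab, depth, background_rate, frag_len) {
  edits <- list()
  realized <- integer(nrow(edit_tab))
  # background substitutions first (window edits overwrite on collision)
  if (background_rate > 0) {
    nb <- rbinom(1, depth * frag_len, background_rate)
    if (nb > 0) {
      mol <- sample.int(depth, nb, replace = TRUE)
      idx <- sample.int(frag_len, nb, replace = TRUE)
      shift <- sample.int(3, nb, replace = TRUE) # resolved against ref later
      edits[[length(edits) + 1]] <-
        tibble::tibble(mol = mol, idx = idx, alt = NA_character_, shift = shift)
    }
  }
  if (nrow(edit_tab) > 0) {
    for (i in seq_len(nrow(edit_tab))) {
      hit <- which(runif(depth) < edit_tab$prob[i])
      realized[i] <- length(hit)
      if (length(hit) > 0) {
        oc <- edit_tab$outcome[[i]]
        alt <- sample(oc$alts, length(hit), replace = TRUE, prob = oc$weights)
        edits[[length(edits) + 1]] <-
          tibble::tibble(mol = hit, idx = edit_tab$idx[i], alt = alt,
                         shift = NA_integer_)
      }
    }
  }
  list(edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(mol = integer(), idx = integer(),
                        alt = character(), shift = integer()),
       realized = realized)
}

# Materialize molecule sequences: reference fragment plus sparse edits.
build_molecules <- function(frag_seq, depth, edits) {
  mols <- rep(frag_seq, depth)
  if (nrow(edits) == 0) return(mols)
  frag_chars <- split_chars(frag_seq)
  # background alts resolved to a base different from the reference
  bg <- is.na(edits$alt)
  if (any(bg)) {
    ref <- frag_chars[edits$idx[bg]]
    others <- matrix(DNA_BASES[t(vapply(ref, function(b)
      which(DNA_BASES != b), integer(3)))], ncol = 3)
    edits$alt[bg] <- others[cbind(seq_len(sum(bg)), edits$shift[bg])]
  }
  # window edits (drawn later) overwrite background at the same spot
  edits <- edits[!duplicated(edits[c("mol", "idx")], fromLast = TRUE), ]
  for (grp in split(edits, edits$mol)) {
    ch <- frag_chars
    ch[grp$idx] <- grp$alt
    del <- ch == "-"
    if (any(del)) ch <- ch[!del]
    mols[grp$mol[1]] <- paste(ch, collapse = "")
  }
  mols
}

# Mate-independent uniform sequencing errors on a vector of read sequences.
apply_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    ch <- split_chars(reads[i])
    at <- sample.int(lens[i], n_err[i])
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate paired-end amplicon reads for every fragment
#'
#' Each simulated molecule starts from its fragment's reference sequence;
#' positions inside a guide's editing window whose base matches the editor's
#' target on the bound strand are edited with the window probability
#' (times the synergy factor where two windows overlap, capped at 1), with
#' the outcome drawn from the editor's substitution weights. A uniform
#' molecule-level background substitution rate and mate-independent
#' sequencing errors are layered on top. R1 is the molecule, R2 its reverse
#' complement (perfect overlap).
#'
#' @param cfg A [sim_config()].
#' @param sample,replicate Identifiers stamped on the outputs.
#' @return List with `reads` — tibble (sample, replicate, fragment, id, r1,
#'   r2) — and `truth` — tibble (sample, replicate, fragment, pos, injected_prob,
#'   n_edited, depth, realized) of per-position molecule-level edit
#'   proportions at editable positions.
#' @export
simulate_reads <- function(cfg, sample = "edited", replicate = "r1") {
  run <- function() {
    reads <- list(); truth <- list()
    for (frag in cfg$fragments) {
      et <- editable_positions(cfg, frag)
      dr <- draw_edits(et, cfg$depth, cfg$background_rate,
                       nchar(frag$sequence))
      mols <- build_molecules(frag$sequence, cfg$depth, dr$edits)
      r1 <- apply_seq_errors(mols, cfg$seq_error_rate)
      r2 <- apply_seq_errors(revcomp(mols), cfg$seq_error_rate)
      reads[[frag$name]] <- tibble::tibble(
        sample = sample, replicate = replicate, fragment = frag$name,
        id = sprintf("%s_%s_%s_%06d", sample, replicate, frag$name,
                     seq_len(cfg$depth)),
        r1 = r1, r2 = r2)
      truth[[frag$name]] <- tibble::tibble(
        sample = sample, replicate = replicate, fragment = frag$name,
        pos = et$pos, injected_prob = et$prob, n_edited = dr$realized,
        depth = cfg$depth, realized = dr$realized / cfg$depth)
    }
    list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

#' Simulate wild-type (unedited) amplicon reads
#'
#' As [simulate_reads()] with the editing windows zeroed: only the background
#' substitution rate and sequencing error remain.
#'
#' @inheritParams simulate_reads
#' @return As [simulate_reads()]; the truth table is empty.
#' @export
simulate_wt_reads <- function(cfg, sample = "WT", replicate = "r1") {
  cfg$editor <- null_editor()
  simulate_reads(cfg, sample = sample, replicate = replicate)
}

#' Simulate serial-dilution drop counts for a canavanine-resistance assay
#'
#' Emulates the drop-plate design: a culture is serially diluted and fixed
#' volumes are spotted on permissive and selective plates; colony counts are
#' Poisson around the expected cell number per drop.
#'
#' @param true_freq True mutant (resistant) frequency in `[0, 1]`.
#' @param culture_cfu_per_ml Viable titer of the undiluted culture.
#' @param dilutions Integer vector of tenfold dilution exponents (0 =
#'   undiluted).
#' @param drops_per_dilution Technical replicate drops per dilution.
#' @param n_replicates Biological replicates (independent cultures; titers
#'   jittered lognormally, sdlog 0.1).
#' @param drop_volume_ul Spotted volume per drop.
#' @param strain Strain label.
#' @param seed Integer seed.
#' @return Tibble (strain, replicate, drop, medium, dilution_factor,
#'   colonies).
#' @export
simulate_plate_counts <- function(true_freq, culture_cfu_per_ml = 2e8,
                                  dilutions = 0:6, drops_per_dilution = 4,
                                  n_replicates = 3, drop_volume_ul = 10,
                                  strain = "strain", seed = NULL) {
  stopifnot(true_freq >= 0, true_freq <= 1)
  run <- function() {
    out <- list()
    vol_ml <- drop_volume_ul / 1000
    for (rep_i in seq_len(n_replicates)) {
      cfu <- culture_cfu_per_ml * exp(stats::rnorm(1, 0, 0.1 * log(10)))
      for (d in dilutions) {
        lam <- cfu * vol_ml / 10^d
        for (medium in c("permissive", "selective")) {
          mean_col <- if (medium == "permissive") lam else lam * true_freq
          out[[length(out) + 1]] <- tibble::tibble(
            strain = strain, replicate = paste0("bio", rep_i),
            drop = seq_len(drops_per_dilution), medium = medium,
            dilution_factor = 10^d,
            colonies = rpois(drops_per_dilution, mean_col))
        }
      }
    }
    dplyr::bind_rows(out)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate Sanger-sequenced resistant clones
#'
#' Each clone is the full gene sequence carrying at least one
#' editor-consistent substitution drawn from the window model (clones stand
#' for selected loss-of-function mutants, so one edit is guaranteed);
#' deletions are not injected (clone calling is substitution-only).
#'
#' @param n_clones Number of clones.
#' @param editor An [editor_profile()].
#' @param guides List of guides with derived PAMs.
#' @param gene A [target_gene()].
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector of clone sequences)
#'   and `truth` (tibble clone, pos, ref, alt).
#' @export
simulate_sanger_clones <- function(n_clones, editor, guides, gene,
                                   seed = NULL) {
  stopifnot(n_clones > 0)
  cfg <- list(gene = gene, guides = guides, editor = editor)
  whole <- structure(list(name = "gene", start = 1L, end = gene$length,
                          sequence = gene$sequence, gene = gene$name),
                     class = "fragment_spec")
  et <- editable_positions(cfg, whole)
  # drop deletion outcomes; clones are substitution-only
  et$outcome <- lapply(et$outcome, function(oc) {
    keep <- oc$alts != "-"
    list(alts = oc$alts[keep], weights = oc$weights[keep] / sum(oc$weights[keep]))
  })
  if (nrow(et) == 0) stop("no editable position under this editor/guide set",
                          call. = FALSE)
  gene_chars <- split_chars(gene$sequence)
  run <- function() {
    seqs <- character(n_clones)
    truth <- list()
    for (k in seq_len(n_clones)) {
      hit <- integer(0); tries <- 0
      while (length(hit) == 0 && tries < 1000) {
        hit <- which(runif(nrow(et)) < et$prob)
        tries <- tries + 1
      }
      if (length(hit) == 0) hit <- sample.int(nrow(et), 1, prob = et$prob)
      alt <- vapply(hit, function(i) {
        oc <- et$outcome[[i]]
        if (length(oc$alts) == 1) oc$alts else
          sample(oc$alts, 1, prob = oc$weights)
      }, character(1))
      ch <- gene_chars
      ch[et$pos[hit]] <- alt
      seqs[k] <- paste(ch, collapse = "")
      truth[[k]] <- tibble::tibble(clone = sprintf("clone%03d", k),
                                   pos = et$pos[hit],
                                   ref = gene_chars[et$pos[hit]], alt = alt)
    }
    names(seqs) <- sprintf("clone%03d", seq_len(n_clones))
    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
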