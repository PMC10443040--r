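---
title: "Methods: amplicon-based characterization of base-editor mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon-based characterization of base-editor mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## Overview

`bescan` quantifies what a catalytically dead Cas9 fused to a deaminase
(a "base editor") does to a target gene, from paired-end amplicon deep
sequencing. A guide RNA positions the editor on the gene; deamination then
converts bases in a window of positions measured relative to the PAM (the
3-bp NGG motif 3′ of the protospacer). The pipeline turns raw read pairs
into (i) per-position, per-substitution-class mutation proportions with a
wild-type background band, (ii) read-level editing-diversity statistics,
(iii) canavanine-resistance frequencies from drop-plate counts, and (iv)
per-position clone mutation rates from Sanger-sequenced resistant clones.
A seeded generator produces synthetic data with the same statistical
structure, so every stage is exercisable and testable at desk scale.

## Coordinate conventions

All coordinates are 1-based, inclusive, and reported on the coding strand,
also for guides that bind the noncoding strand. The PAM is derived as the
3-bp interval immediately 3′ of the protospacer on the bound strand:
downstream of the protospacer for coding-strand guides, upstream (in
coding coordinates) for noncoding-strand guides. PAM-relative offsets run
negative into the protospacer (−1 is the PAM-proximal protospacer base),
0..2 across the PAM, and positive beyond it. This makes editing windows
such as "−7 to −21" lie inside the protospacer, where adenine deaminases
act, and keeps the mapping invertible. Guide spans are taken verbatim from
their printed coordinates (a 21-position span stays 21 nt; nothing forces
a canonical 20-mer, and inter-PAM distances are invariant to that choice).
The distance between two guides' PAMs is the absolute difference of their
PAM-proximal protospacer boundaries, which for same-strand guides equals
the distance between `pam_start` values.

## Read processing

Amplicon fragments (~100–200 bp) are short enough that the two mates of a
pair overlap completely. `merge_pairs()` reverse-complements R2 and scans
every relative offset; the longest overlap with at most `max_mismatch`
mismatching positions (default 0, non-ACGT counts as a mismatch, minimum
overlap 20 bp) is accepted and the pair is otherwise rejected. With
mate-independent errors at per-base rate ε and overlap length L, the
expected rejection fraction is 1 − (1 − ε)^(2L); 0-mismatch merging
therefore purges nearly all sequencing errors while true edits, present on
both mates, survive.

Merged reads are deduplicated and each distinct sequence is aligned
end-to-end to its fragment with unit costs (match 0, mismatch 1, gap 2).
Ties prefer mismatches over gaps, and gaps in the reference are taken last
during backtrace, which left-normalizes indel placement. Equal-length
reads within 3 mismatches of the fragment take a Hamming fast path: a
gapped alignment costs at least 4 there, so the substitution-only
alignment is provably optimal. Pileups tally A/C/G/T/deletion per position
(insertions consume read bases but add no positional count) with a
per-position depth cap of 600 000, filling from the first reads in input
order; depth always equals the sum of the five allele counts.

One consequence of left-normalized gaps worth knowing: a single-base
deletion at the edge of an editing window can be reported one position
further left when the flanking base repeats. Deletion classes are
therefore tallied and reported, but window-boundary detection statements
in the tests rest on substitution classes, which carry 95% of the default
editor's outcome weight.

## Spectra

Positions below 50 000× depth are discarded (strictly below; 50 000
passes), and `n_trim` positions (default 5) are dropped from each fragment
end to avoid primer-proximal artifacts — the trim width is a package
choice, exposed in configuration. Per position the mutated proportion is
(depth − reference count)/depth; per substitution class (12 substitutions
plus 4 deletion classes) it is the class count over depth, so class
proportions sum exactly to the per-position proportion. WT replicates are
pooled by averaging class proportions per position; sample spectra minus
the pooled WT, clamped at zero, give the WT-subtracted spectra. The WT
band is, per class, the one-sided empirical quantile (type 1; default
coverage 0.95) of all pooled WT (position, replicate) proportions — a
one-sided bound because proportions are bounded below by zero.

## Editing diversity

Distinct merged-read sequences are counted per sample; reads whose
alignment contains indel operations are flagged and excluded from SNP
statistics, so the SNP count of the remainder is a plain Hamming distance
to the fragment template. Sequences seen at least 5 times summed across
the WT samples are removed as background, as is the template itself. The
remaining distinct reads with ≥1 SNP, normalized per kiloread sequenced,
measure editing diversity; samples are compared to the no-guide control
with a two-sided Welch t-test on replicate values. The test choice is a
package decision (the natural default for n = 3 group comparisons); when
both groups are constant the statistic is undefined and the comparison is
reported as not significant with p = 1 rather than erroring.

## Phenotype rates

Drop-plate counts (four 10 µL technical drops per tenfold dilution, three
biological replicates) yield titers as the mean over countable drops
(3–150 colonies, standard drop-plate practice, configurable) of
colonies × dilution factor / volume. Rare resistant colonies often leave
no countable selective drop; the estimator then pools the least-diluted
drops (total colonies over total volume), and all-zero selective plates
give a frequency of 0 flagged below detection. Disabling the fallback
restores a hard error listing the drops. The Can^R frequency is the
selective/permissive titer ratio; biological replicates are summarized by
geometric mean, the natural center for frequencies spanning
10^−6..10^−2.

## Sanger clones

Each clone is aligned to the gene with the same global aligner; clones
under 80% alignment identity are excluded as failed reads, and ambiguous
(non-ACGT) basecalls never become substitution calls. The per-position
clone mutation rate is the percentage of accepted clones carrying a
substitution there; calls re-indexed to PAM-relative offsets of a chosen
guide give the editing-window profile, with calls beyond ±100 bp retained
but flagged.

## The synthetic generator

The generator emulates the data-generating process the analysis assumes.
Editing is molecule-level: before read generation, each position inside a
guide window whose base matches the editor's target on the bound strand is
edited with the window probability, doubled (by default) where two guide
windows overlap and capped at 1; outcomes follow the editor's substitution
weights, complemented onto the coding strand for noncoding-strand guides.
The default cytidine editor edits C within ±20 bp of the PAM
(weights T 0.70 / G 0.15 / A 0.10 / single-base deletion 0.05); the
default adenine editor converts A→G exclusively at offsets −21..−7.
Per-molecule window probabilities default to 0.01–0.02: deep-sequencing
editing proportions for dCas9-deaminase fusions sit in the 10^−3..10^−1
range, and these values land the synthetic spectra there. Two further
layers follow: a uniform molecule-level background substitution rate
(default 10^−4/bp) applied to every sample including WT — real amplicon
data shows a nonzero WT band at roughly this scale, and without it the
95% band degenerates to zero because 0-mismatch merging removes nearly
all read errors — and mate-independent sequencing errors (default
10^−3/base). R1 is the molecule, R2 its reverse complement, qualities
constant Q37 (Phred+33). Plate counts are Poisson around the expected
cells per drop with lognormal (sdlog 0.1·ln 10) biological titer jitter;
clones are gene copies carrying at least one window edit (selected
mutants), substitution-only.

What the generator does not emulate: PCR amplification bias and chimeras,
quality-dependent or cycle-dependent error profiles, multi-base indels,
real-genome sequence context (the bundled 1773-bp reference is a seeded
random synthetic sequence), and any mechanistic coupling between editing
and phenotype. Passing tests therefore demonstrate that the analysis
recovers what this model injects — window locations, proportions,
frequencies — not that real libraries are free of the artifacts above.
The synergy multiplier on overlapping windows is a deliberately minimal
mechanism for the qualitative boost seen with proximal multiplexed
guides; its magnitude is a free parameter, not a measured quantity.

## Determinism and problem sizes

All randomness flows from one top-level seed fanned out per sample and
stage; reruns are byte-identical, and every scenario run writes a manifest
(seed, parameters, output hashes). The shipped tests use desk-scale sizes
chosen to make the statistics decisive: depth 100 000 for window
recovery (binomial SE ≪ the 0.01 window probability), 200 seeded
WT-vs-WT trials at depth 2 000 for the type-I check, 3 editing levels ×
20 seeds for monotonicity, 1 000 plating simulations across the
10^−6..10^−2 grid, and a depth-600 scenario for byte-level determinism.
The demonstration scenario under `analysis/` uses depth 4 000 with its
depth filter scaled accordingly.

## Repository shape

The package is organized as an analysis workflow: every computation lives
in the package (`R/`), and the numbered drivers under `analysis/` are thin
narrative scripts that generate data, run each stage, and write tables
under `results/` — they, together with `run_scenario()`, are the
command-line surface; no separate CLI binary is provided.

## Known limitations

Insertions are recorded in alignments but contribute no positional counts,
so insertion-heavy editors would be under-characterized. The WT band is a
marginal per-class bound, not a per-position test, and no per-position
significance calling is attempted. The unique-read statistics treat each
distinct sequence equally regardless of abundance beyond the WT filter.
Frequencies below the plating detection limit are reported as zero rather
than as censored estimates.
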