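# Guide/PAM geometry on a single target gene.
#
# All coordinates are 1-based inclusive on the coding strand, matching the
# "position 88-108 bp" style used for amplicon work on CAN1-like targets.
# Results are reported in coding-strand coordinates even for guides that
# bind the noncoding strand.

#' Construct a target gene record
#'
#' @param name Gene identifier.
#' @param sequence Coding-strand DNA sequence (A/C/G/T only).
#' @return A `target_gene` object (list with `name`, `sequence`, `length`).
#' @export
target_gene <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("gene sequence must contain only A/C/G/T", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "target_gene"
  )
}

#' Read a target gene from a FASTA file
#'
#' @param path Path to a single-record FASTA file (coding strand).
#' @return A [target_gene()] object.
#' @export
read_gene_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) stop("expected exactly one FASTA record", call. = FALSE)
  target_gene(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' Construct an amplicon fragment record
#'
#' A fragment is the sequenced amplicon interval of the gene; its sequence is
#' taken from the gene slice (and validated against `sequence` if supplied).
#'
#' @param name Fragment identifier.
#' @param start,end 1-based inclusive gene positions.
#' @param gene A [target_gene()].
#' @param sequence Optional explicit sequence; must equal the gene slice.
#' @return A `fragment_spec` object.
#' @export
fragment_spec <- function(name, start, end, gene, sequence = NULL) {
  stopifnot(start >= 1, start <= end, end <= gene$length)
  slice <- substr(gene$sequence, start, end)
  if (!is.null(sequence) && !identical(toupper(sequence), slice)) {
    stop("fragment sequence does not match the gene slice", call. = FALSE)
  }
  structure(
    list(name = name, start = as.integer(start), end = as.integer(end),
         sequence = slice, gene = gene$name),
    class = "fragment_spec"
  )
}

#' Construct a guide (protospacer) record
#'
#' Coordinates may be given in printed 5'-to-3' order on the bound strand
#' (descending for noncoding-strand guides); they are normalized so that
#' `proto_start <= proto_end` on the coding strand.
#'
#' @param name Guide identifier.
#' @param start,end Protospacer gene positions (either order).
#' @param strand `"coding"` or `"noncoding"` — the strand the guide binds.
#' @return A `guide_spec` object; PAM fields are `NA` until [derive_pam()].
#' @export
guide_spec <- function(name, start, end, strand = c("coding", "noncoding")) {
  strand <- match.arg(strand)
  proto_start <- min(start, end)
  proto_end <- max(start, end)
  structure(
    list(name = name, proto_start = as.integer(proto_start),
         proto_end = as.integer(proto_end), strand = strand,
         spacer_len = as.integer(proto_end - proto_start + 1L),
         pam_start = NA_integer_, pam_end = NA_integer_),
    class = "guide_spec"
  )
}

#' Derive the PAM interval of a guide
#'
#' The PAM is the 3-bp interval immediately 3' of the protospacer on the
#' bound strand, reported in coding-strand coordinates: downstream
#' (`proto_end + 1 .. proto_end + 3`) for coding-strand guides, upstream
#' (`proto_start - 3 .. proto_start - 1`) for noncoding-strand guides.
#'
#' @param guide A [guide_spec()].
#' @param gene A [target_gene()]; the protospacer and PAM must fit inside it.
#' @return The guide with `pam_start`/`pam_end` filled in.
#' @export
derive_pam <- function(guide, gene) {
  stopifnot(inherits(guide, "guide_spec"), inherits(gene, "target_gene"))
  if (guide$proto_start < 1 || guide$proto_end > gene$length) {
    stop("protospacer of '", guide$name, "' lies outside the gene", call. = FALSE)
  }
  if (guide$strand == "coding") {
    pam <- c(guide$proto_end + 1L, guide$proto_end + 3L)
  } else {
    pam <- c(guide$proto_start - 3L, guide$proto_start - 1L)
  }
  if (pam[1] < 1 || pam[2] > gene$length) {
    stop("guide '", guide$name,
         "' leaves no room for a PAM inside the gene", call. = FALSE)
  }
  guide$pam_start <- pam[1]
  guide$pam_end <- pam[2]
  guide
}

has_pam <- function(guide) !is.na(guide$pam_start)

#' Distance between two guides' PAM sites
#'
#' Absolute difference between the PAM-proximal protospacer boundary
#' coordinates; for same-strand guides this equals the distance between
#' `pam_start` values.
#'
#' @param g1,g2 Guides with derived PAMs (see [derive_pam()]).
#' @return Non-negative integer distance in bp.
#' @export
pam_distance <- function(g1, g2) {
  if (!has_pam(g1) || !has_pam(g2)) {
    stop("derive the PAM of both guides before computing distances", call. = FALSE)
  }
  proximal <- function(g) if (g$strand == "coding") g$proto_end else g$proto_start
  abs(proximal(g1) - proximal(g2))
}

#' Convert gene positions to PAM-relative offsets
#'
#' Offsets count away from the PAM along the protospacer as negative values
#' (-1 is the PAM-proximal protospacer base); the PAM-proximal PAM base is 0
#' and positions beyond the PAM on the non-protospacer side are positive.
#'
#' @param guide A guide with a derived PAM.
#' @param pos Vector of gene positions (coding strand, 1-based).
#' @return Integer vector of signed offsets.
#' @export
pam_relative <- function(guide, pos) {
  if (!has_pam(guide)) stop("PAM not derived", call. = FALSE)
  if (guide$strand == "coding") {
    as.integer(pos - guide$pam_start)
  } else {
    as.integer(guide$pam_end - pos)
  }
}

#' Convert PAM-relative offsets back to gene positions
#'
#' Inverse of [pam_relative()].
#'
#' @param guide A guide with a derived PAM.
#' @param offset Vector of signed offsets.
#' @return Integer vector of gene positions.
#' @export
pam_relative_inv <- function(guide, offset) {
  if (!has_pam(guide)) stop("PAM not derived", call. = FALSE)
  if (guide$strand == "coding") {
    as.integer(guide$pam_start + offset)
  } else {
    as.integer(guide$pam_end - offset)
  }
}

#' Symmetric editing window around a guide's PAM
#'
#' The closed gene interval covering PAM-relative offsets
#' `-half_width .. +half_width`, clipped to the gene.
#'
#' @param guide A guide with a derived PAM.
#' @param half_width Window half-width in bp (> 0).
#' @param gene A [target_gene()] used for clipping.
#' @return Integer vector `c(start, end)` in gene coordinates.
#' @export
editing_window <- function(guide, half_width, gene) {
  stopifnot(half_width > 0)
  pos <- pam_relative_inv(guide, c(-half_width, half_width))
  c(max(1L, min(pos)), min(gene$length, max(pos)))
}

#' Read guides or fragments from a BED-like 6-column TSV
#'
#' Columns: name, start, end, strand (`+` coding / `-` noncoding / `.`),
#' sequence (spacer for guides, `.` to derive from the gene), role
#' (`"guide"` or `"fragment"`).
#'
#' @param path TSV path (lines starting with `#` are skipped).
#' @param gene A [target_gene()].
#' @return A list with elements `guides` (list of [guide_spec()] with PAMs
#'   derived) and `fragments` (list of [fragment_spec()]).
#' @export
read_features_tsv <- function(path, gene) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("name", "start", "end", "strand",
                                  "sequence", "role"),
                    stringsAsFactors = FALSE)
  guides <- list()
  fragments <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (row$role == "guide") {
      strand <- if (row$strand == "-") "noncoding" else "coding"
      g <- derive_pam(guide_spec(row$name, row$start, row$end, strand), gene)
      if (row$sequence != ".") {
        slice <- substr(gene$sequence, g$proto_start, g$proto_end)
        if (strand == "noncoding") slice <- revcomp(slice)
        if (!identical(toupper(row$sequence), slice)) {
          stop("spacer of '", row$name, "' does not match the gene", call. = FALSE)
        }
      }
      guides[[row$name]] <- g
    } else if (row$role == "fragment") {
      seq <- if (row$sequence == ".") NULL else row$sequence
      fragments[[row$name]] <- fragment_spec(row$name, row$start, row$end,
                                             gene, sequence = seq)
    } else {
      stop("unknown feature role: ", row$role, call. = FALSE)
    }
  }
  list(guides = guides, fragments = fragments)
}
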