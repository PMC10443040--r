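# FASTQ/FASTA and tabular I/O helpers.

#' Write simulated read pairs as paired FASTQ files
#'
#' Standard 4-line FASTQ with constant Q37 qualities (Phred+33, character
#' `F`).
#'
#' @param reads Tibble with columns `id`, `r1`, `r2` (e.g. from
#'   [simulate_reads()]).
#' @param r1_path,r2_path Output paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("F", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  write_one(reads$r1, paste0(reads$id, "/1"), r1_path)
  write_one(reads$r2, paste0(reads$id, "/2"), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param r1_path,r2_path FASTQ paths (Phred+33).
#' @return Tibble (id, r1, r2).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in length", call. = FALSE)
  tibble::tibble(id = sub("/1$", "", sub("\\s.*$", "", names(s1))),
                 r1 = unname(as.character(s1)),
                 r2 = unname(as.character(s2)))
}

#' Write clone sequences as multi-FASTA
#'
#' @param sequences Named character vector of clone sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read clone sequences from multi-FASTA
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_clone_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a tidy table as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read plate counts from TSV
#'
#' Expects columns strain, replicate, drop, medium, dilution_factor,
#' colonies.
#'
#' @param path TSV path.
#' @return Tibble of plate counts.
#' @export
read_plate_counts <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
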