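# Character-level sequence helpers shared by all modules. Sequences travel as
# plain uppercase character vectors; Biostrings does the heavy lifting for
# IUPAC-aware reverse complement and for FASTA/FASTQ IO.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' IUPAC-aware reverse complement, vectorized over a character vector.
#'
#' @param x Character vector of DNA sequences (IUPAC alphabet).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' @keywords internal
is_iupac <- function(x) {
  !grepl(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), x)
}

#' @keywords internal
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# Write sequences (named character vector) as FASTA.
#' @keywords internal
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

# read as BStringSet so that invalid characters survive to the loader's own
# per-record alphabet check
#' @keywords internal
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

# FASTQ with constant qualities; ids must not contain whitespace.
#' @keywords internal
write_fastq <- function(seqs, ids, path, quality_char = "I") {
  stopifnot(length(seqs) == length(ids))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(strrep(quality_char, nchar(seqs))))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

#' @keywords internal
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped when building the
  # QualityScaledDNAStringSet; the drop is intentional here
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path,
                                                   quality.scoring = "phred")
    list(seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))),
         id = names(x))
  })
}
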