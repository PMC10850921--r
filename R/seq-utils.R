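## Low-level DNA string helpers shared across modules. Sequences are plain
## uppercase character scalars; Biostrings objects are used only at the I/O
## and alignment boundaries.

DNA_BASES_ACGT <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A/C/G/T (N allowed).
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Random DNA string
#'
#' Uniform i.i.d. bases. Callers are responsible for seeding.
#' @param n Length in nucleotides.
#' @return Character scalar of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES_ACGT, n, replace = TRUE), collapse = "")
}

## substring as character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## assert a sequence is nonempty uppercase DNA (optionally allowing N)
check_dna <- function(x, allow = "ACGT", what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a nonempty character scalar")
  bad <- gsub(sprintf("[%s]", allow), "", x)
  if (nchar(bad) > 0L)
    stop(what, " contains characters outside {",
         paste(strsplit(allow, "")[[1]], collapse = ","), "}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  invisible(TRUE)
}

## maximal run length of base `b` in `x` extending left from position `pos`
## (inclusive); returns 0 if x[pos] != b
run_left <- function(chars, pos, b) {
  n <- 0L
  while (pos >= 1L && chars[pos] == b) {
    n <- n + 1L
    pos <- pos - 1L
  }
  n
}

run_right <- function(chars, pos, b) {
  n <- 0L
  while (pos <= length(chars) && chars[pos] == b) {
    n <- n + 1L
    pos <- pos + 1L
  }
  n
}

is_homopolymer <- function(x) {
  ch <- unique(seq_chars(x))
  length(ch) == 1L
}

#' Read a multi-record FASTA file into named character strings
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
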