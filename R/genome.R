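#' Create a genome record
#'
#' A light container for a single (phage) genome: an identifier, the
#' plus-strand sequence and its length. Sequences are upper-cased on input;
#' characters outside `A`, `C`, `G`, `T`, `N` are rejected.
#'
#' @param sequence Character scalar, the plus-strand DNA sequence.
#' @param id Genome identifier used in output tracks and files.
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   and `length`.
#' @examples
#' g <- genome_record("ACGTACGT", id = "toy")
#' g$length
#' @export
genome_record <- function(sequence, id = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  bad <- gregexpr("[^ACGTN]", sequence)[[1]]
  if (bad[1] != -1L) {
    abort(paste0(
      "genome contains characters outside {A,C,G,T,N} at positions (0-based): ",
      paste(head(bad - 1L, 10L), collapse = ", "),
      if (length(bad) > 10L) " ..."
    ))
  }
  structure(
    list(id = as.character(id), sequence = sequence, length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", format(x$length, big.mark = ","),
      " nt\n", sep = "")
  invisible(x)
}

# accept a genome_record or a plain DNA string
as_genome <- function(genome) {
  if (inherits(genome, "genome_record")) return(genome)
  if (is.character(genome) && length(genome) == 1L) return(genome_record(genome))
  abort("`genome` must be a genome_record or a single DNA string")
}

#' Read a genome from a FASTA file
#'
#' Reads the first record of a FASTA file into a [genome_record()].
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A `genome_record`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such FASTA file: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) abort(paste0("empty FASTA file: ", path))
  if (length(ss) > 1L) {
    warn(paste0(path, " has ", length(ss), " records; using the first"))
  }
  genome_record(as.character(ss[[1L]]), id = sub("\\s.*$", "", names(ss)[1L]))
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_record()] or DNA string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring of a genome's plus strand
genome_slice <- function(genome, start, end) {
  substring(genome$sequence, start + 1L, end)
}
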