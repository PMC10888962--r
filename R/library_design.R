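#' Design a dense tiled spacer library over a phage genome
#'
#' Enumerates spacers of length `k` starting every `stride` nucleotides on
#' both strands of the genome, the layout used to screen a complete phage
#' genome for protospacers. Plus-strand spacers are the genome substring on
#' `[start, end)`; minus-strand spacers are its reverse complement. Both are
#' reported by their plus-strand interval (0-based, half-open), so the total
#' library size is `2 * (floor((L - k) / stride) + 1)` for a genome of
#' length `L`.
#'
#' @param genome A [genome_record()] or DNA string.
#' @param k Spacer length in nt (default 35, typical for type III-A systems).
#' @param stride Tiling stride in nt; the screen design uses 2.
#' @param strict If `TRUE`, any ambiguous base (`N`) in the genome is an
#'   error listing the offending positions. If `FALSE` (default), spacers
#'   overlapping an `N` are emitted but flagged `ambiguous`.
#' @return A tibble with columns `spacer_id`, `start`, `end`, `strand`
#'   (`"plus"`/`"minus"`), `sequence` and `ambiguous`, ordered plus strand by
#'   ascending start, then minus strand by ascending start.
#' @examples
#' g <- genome_record(strrep("ACGT", 25))
#' nrow(design_tiled_spacers(g, k = 35, stride = 2))  # 66
#' @export
design_tiled_spacers <- function(genome, k = 35, stride = 2, strict = FALSE) {
  genome <- as_genome(genome)
  k <- as.integer(k)
  stride <- as.integer(stride)
  L <- genome$length
  if (k < 1L) abort("`k` must be >= 1")
  if (stride < 1L) abort("`stride` must be >= 1")
  if (k > L) abort("spacer longer than genome")
  n_pos <- gregexpr("N", genome$sequence, fixed = TRUE)[[1L]]
  has_n <- n_pos[1L] != -1L
  if (has_n && strict) {
    abort(paste0(
      "genome contains non-ACGT characters at positions (0-based): ",
      paste(head(n_pos - 1L, 10L), collapse = ", "),
      if (length(n_pos) > 10L) " ..."
    ))
  }

  starts <- seq.int(0L, L - k, by = stride)
  fwd <- substring(genome$sequence, starts + 1L, starts + k)
  plus <- tibble(
    spacer_id = sprintf("spc_plus_%d", starts),
    start = starts, end = starts + k,
    strand = "plus", sequence = fwd
  )
  minus <- tibble(
    spacer_id = sprintf("spc_minus_%d", starts),
    start = starts, end = starts + k,
    strand = "minus", sequence = revcomp(fwd)
  )
  out <- bind_rows(plus, minus)
  out$ambiguous <- if (has_n) grepl("N", out$sequence, fixed = TRUE) else FALSE
  out
}

#' Oligo layout for cloning-ready spacer oligos
#'
#' Describes the constant flanks placed around each spacer in the synthesized
#' oligo pool (universal priming sites, Golden-Gate cloning sites and repeat
#' homology). The flank sequences are supplied by the user for their cloning
#' scheme; [default_oligo_layout()] provides placeholder flanks sized so that
#' a `k`-nt spacer yields the standard 90-nt pool oligo.
#'
#' @param upstream_flank,downstream_flank Constant DNA flanks.
#' @param total_length Expected total oligo length in nt (default 90).
#' @return An object of class `oligo_layout`.
#' @export
oligo_layout <- function(upstream_flank, downstream_flank, total_length = 90) {
  stopifnot(is.character(upstream_flank), length(upstream_flank) == 1L,
            is.character(downstream_flank), length(downstream_flank) == 1L)
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  if (grepl("[^ACGTN]", paste0(upstream_flank, downstream_flank))) {
    abort("oligo flanks must be DNA over {A,C,G,T,N}")
  }
  structure(
    list(upstream_flank = upstream_flank,
         downstream_flank = downstream_flank,
         total_length = as.integer(total_length)),
    class = "oligo_layout"
  )
}

#' @export
print.oligo_layout <- function(x, ...) {
  cat("<oligo_layout> ", nchar(x$upstream_flank), " nt + spacer + ",
      nchar(x$downstream_flank), " nt = ", x$total_length, " nt\n", sep = "")
  invisible(x)
}

#' @rdname oligo_layout
#' @param k Spacer length the layout must accommodate.
#' @export
default_oligo_layout <- function(k = 35, total_length = 90) {
  up_len <- 30L
  down_len <- as.integer(total_length) - as.integer(k) - up_len
  if (down_len < 0L) abort("total_length too short for k with 30-nt upstream flank")
  # placeholder flanks: priming site + BsaI site + repeat homology stand-ins
  up <- substr(strrep("GACTGGTACCAGGTCTCAACGATCGGTAGC", 3L), 1L, up_len)
  down <- substr(strrep("GCTACCGATCGTTGAGACCTGGTACCAGTC", 3L), 1L, down_len)
  oligo_layout(up, down, total_length)
}

#' Assemble pool oligos around designed spacers
#'
#' Concatenates `upstream_flank + spacer + downstream_flank` for every
#' spacer and checks the result against the layout's `total_length`.
#'
#' @param spacers Tibble from [design_tiled_spacers()] (needs a `sequence`
#'   column).
#' @param layout An [oligo_layout()]; default sized for the spacer length of
#'   the first spacer.
#' @return `spacers` with an added `oligo` column.
#' @export
build_oligos <- function(spacers, layout = NULL) {
  stopifnot(is.data.frame(spacers), "sequence" %in% names(spacers))
  if (nrow(spacers) == 0L) abort("no spacers to build oligos for")
  if (is.null(layout)) layout <- default_oligo_layout(k = nchar(spacers$sequence[1L]))
  stopifnot(inherits(layout, "oligo_layout"))
  oligo <- paste0(layout$upstream_flank, spacers$sequence, layout$downstream_flank)
  lens <- unique(nchar(oligo))
  if (!identical(lens, layout$total_length)) {
    abort(sprintf("oligo length mismatch: expected %d nt, got %s nt",
                  layout$total_length, paste(lens, collapse = ", ")))
  }
  spacers$oligo <- oligo
  spacers
}

#' Expected spacer frequency in a uniform library
#'
#' In a perfectly uniform library of `n` spacers every spacer is expected at
#' frequency `1/n`; for the 40,338-spacer phage-tiling library this is
#' 2.4e-5 (two significant figures), the reference line against which
#' observed spacer frequencies are judged.
#'
#' @param n Library size (number of distinct spacers), `n >= 1`.
#' @return `1/n`.
#' @examples
#' expected_uniform_frequency(40338)
#' @export
expected_uniform_frequency <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single number >= 1")
  }
  1 / n
}

#' Write and read a spacer library
#'
#' `write_library()` emits the library as a TSV manifest (columns exactly
#' `spacer_id`, `start`, `end`, `strand`, `sequence`, `oligo`) plus a FASTA
#' of spacer sequences; `read_library()` reads the manifest back. The pair
#' round-trips losslessly.
#'
#' @param spacers Tibble with the manifest columns (see [build_oligos()]).
#' @param prefix Output path prefix; files written are
#'   `<prefix>_manifest.tsv` and `<prefix>_spacers.fasta`.
#' @return `write_library()` returns the two paths invisibly;
#'   `read_library()` returns the manifest tibble.
#' @export
write_library <- function(spacers, prefix) {
  cols <- c("spacer_id", "start", "end", "strand", "sequence", "oligo")
  if (!is.data.frame(spacers) || nrow(spacers) == 0L) {
    abort("empty spacer collection: nothing to write")
  }
  missing_cols <- setdiff(cols, names(spacers))
  if (length(missing_cols)) {
    abort(paste0("manifest columns missing: ", paste(missing_cols, collapse = ", "),
                 " (run build_oligos() first)"))
  }
  manifest_path <- paste0(prefix, "_manifest.tsv")
  fasta_path <- paste0(prefix, "_spacers.fasta")
  readr::write_tsv(spacers[cols], manifest_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(spacers$sequence, spacers$spacer_id)),
    fasta_path
  )
  invisible(c(manifest = manifest_path, fasta = fasta_path))
}

#' @rdname write_library
#' @param path Path to a `*_manifest.tsv` written by `write_library()`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) abort(paste0("no such manifest: ", path))
  readr::read_tsv(
    path,
    col_types = readr::cols(
      spacer_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      sequence = readr::col_character(),
      oligo = readr::col_character()
    )
  )
}
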