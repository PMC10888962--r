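#' Find direct-repeat-flanked inserts in reads
#'
#' Scans each read (and, by default, its reverse complement) for occurrences
#' of the CRISPR direct repeat (DR) within a Hamming mismatch budget, chains
#' the occurrences left-to-right so that consecutive repeats share no bases,
#' and returns every insert lying between two consecutive repeats whose
#' length falls inside `[min_len, max_len]`. This is the amplicon-read
#' signature of a spacer residing in a repeat-spacer-repeat array.
#'
#' Inserts found on the reverse complement of a read are reported in the
#' orientation that places the repeat 5'->3' as given in `repeat_seq`.
#'
#' @param reads Character vector of read sequences (any case).
#' @param repeat_seq The direct-repeat sequence (>= 8 nt).
#' @param max_mismatches Hamming mismatch budget per repeat occurrence;
#'   must be less than half the repeat length.
#' @param min_len,max_len Insert length window in nt; the default
#'   `[30, 45]` brackets type III-A spacer lengths.
#' @param search_rc Also scan the reverse complement of each read.
#' @return A tibble with columns `read` (1-based index into `reads`) and
#'   `insert` (uppercase DNA), ordered by read then position. Reads without
#'   a flanked insert contribute no rows.
#' @examples
#' dr <- "GATCGATACCCACGCAGGTTCGGG"
#' find_repeat_flanked_inserts(paste0(dr, strrep("A", 35), dr), dr)
#' @export
find_repeat_flanked_inserts <- function(reads, repeat_seq, max_mismatches = 1,
                                        min_len = 30, max_len = 45,
                                        search_rc = TRUE) {
  check_repeat(repeat_seq, max_mismatches)
  if (min_len <= 0 || min_len > max_len) {
    abort("need 0 < min_len <= max_len")
  }
  if (length(reads) == 0L) {
    return(tibble(read = integer(), insert = character()))
  }
  reads <- toupper(reads)
  fwd <- scan_orientation(reads, repeat_seq, max_mismatches, min_len, max_len)
  if (search_rc) {
    rc <- scan_orientation(revcomp(reads), repeat_seq, max_mismatches,
                           min_len, max_len)
    out <- bind_rows(fwd, rc)
    out <- out[order(out$read), , drop = FALSE]
  } else {
    out <- fwd
  }
  as_tibble(out)
}

check_repeat <- function(repeat_seq, max_mismatches) {
  stopifnot(is.character(repeat_seq), length(repeat_seq) == 1L)
  if (nchar(repeat_seq) < 8L) abort("repeat must be >= 8 nt")
  if (max_mismatches < 0 || max_mismatches >= nchar(repeat_seq) / 2) {
    abort("max_mismatches must be in [0, repeat length / 2)")
  }
  invisible(TRUE)
}

# One-orientation scan: vmatchPattern for all repeat occurrences, then a
# vectorized greedy left-to-right chain (kept occurrences never overlap),
# emitting the gaps between consecutive kept occurrences.
scan_orientation <- function(reads, repeat_seq, max_mismatches,
                             min_len, max_len) {
  empty <- tibble(read = integer(), insert = character())
  rs <- Biostrings::DNAStringSet(reads)
  m <- Biostrings::vmatchPattern(toupper(repeat_seq), rs,
                                 max.mismatch = max_mismatches)
  nhit <- S4Vectors::elementNROWS(m)
  keep_reads <- which(nhit >= 2L)
  if (length(keep_reads) == 0L) return(empty)

  ir <- IRanges::IRanges(unlist(Biostrings::startIndex(m)[keep_reads]),
                         unlist(Biostrings::endIndex(m)[keep_reads]))
  read_of <- rep.int(keep_reads, nhit[keep_reads])
  s <- IRanges::start(ir)
  e <- IRanges::end(ir)
  o <- order(read_of, s)
  read_of <- read_of[o]; s <- s[o]; e <- e[o]

  # rank of each occurrence within its read (reads are contiguous blocks)
  lens <- rle(read_of)$lengths
  rk <- sequence(lens)
  row <- rep.int(seq_along(lens), lens)
  maxocc <- max(rk)
  S <- matrix(NA_integer_, nrow = length(lens), ncol = maxocc)
  E <- S
  S[cbind(row, rk)] <- s
  E[cbind(row, rk)] <- e
  block_read <- read_of[cumsum(lens)]

  last_end <- integer(length(lens))        # end of last kept occurrence
  has_prev <- logical(length(lens))
  ins_read <- vector("list", maxocc)
  ins_s <- vector("list", maxocc)
  ins_e <- vector("list", maxocc)
  for (j in seq_len(maxocc)) {
    sj <- S[, j]
    keep <- !is.na(sj) & sj > last_end
    gap_s <- last_end + 1L
    gap_e <- sj - 1L
    emit <- keep & has_prev &
      (gap_e - gap_s + 1L) >= min_len & (gap_e - gap_s + 1L) <= max_len
    emit[is.na(emit)] <- FALSE
    if (any(emit)) {
      ins_read[[j]] <- block_read[emit]
      ins_s[[j]] <- gap_s[emit]
      ins_e[[j]] <- gap_e[emit]
    }
    last_end[keep] <- E[keep, j]
    has_prev <- has_prev | keep
  }
  ins_read <- unlist(ins_read)
  if (is.null(ins_read)) return(empty)
  ins_s <- unlist(ins_s); ins_e <- unlist(ins_e)
  o <- order(ins_read, ins_s)
  ins_read <- ins_read[o]; ins_s <- ins_s[o]; ins_e <- ins_e[o]
  tibble(read = ins_read,
         insert = substring(reads[ins_read], ins_s, ins_e))
}

#' Extract a spacer count table from a FASTQ file
#'
#' Applies [find_repeat_flanked_inserts()] to every read of a FASTQ file and
#' tallies the extracted insert sequences verbatim (no error correction or
#' clustering; quality scores are ignored). Deterministic for fixed input.
#'
#' @inheritParams find_repeat_flanked_inserts
#' @param fastq Path to a FASTQ file, plain or gzipped.
#' @param sample_id Sample label stored with the table.
#' @return A `spacer_counts` tibble with columns `spacer_sequence`, `count`
#'   (sorted by decreasing count, ties by sequence) and attributes
#'   `sample_id`, `total_reads`, `total_spacers` and `config`.
#' @export
extract_spacer_counts <- function(fastq, repeat_seq, max_mismatches = 1,
                                  min_len = 30, max_len = 45,
                                  search_rc = TRUE, sample_id = "sample") {
  reads <- read_fastq_sequences(fastq)
  config <- list(repeat_seq = toupper(repeat_seq),
                 max_mismatches = max_mismatches,
                 min_len = min_len, max_len = max_len, search_rc = search_rc)
  if (length(reads) == 0L) {
    return(new_spacer_counts(tibble(spacer_sequence = character(),
                                    count = integer()),
                             sample_id, 0L, 0L, config))
  }
  ins <- find_repeat_flanked_inserts(reads, repeat_seq, max_mismatches,
                                     min_len, max_len, search_rc)
  tab <- table(ins$insert)
  counts <- tibble(spacer_sequence = names(tab), count = as.integer(tab))
  counts <- counts[order(-counts$count, counts$spacer_sequence), , drop = FALSE]
  new_spacer_counts(counts, sample_id, length(reads), nrow(ins), config)
}

new_spacer_counts <- function(counts, sample_id, total_reads, total_spacers,
                              config = NULL) {
  out <- as_tibble(counts)
  attr(out, "sample_id") <- sample_id
  attr(out, "total_reads") <- as.integer(total_reads)
  attr(out, "total_spacers") <- as.integer(total_spacers)
  attr(out, "config") <- config
  class(out) <- c("spacer_counts", class(out))
  out
}

# FASTQ sequence reader: validates the 4-line record structure so that a
# malformed record is reported with its index; qualities are discarded.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) abort(paste0("no such FASTQ file: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(character())
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ %s: truncated record %d",
                  path, length(lines) %/% 4L + 1L))
  }
  hdr <- lines[seq.int(1L, length(lines), by = 4L)]
  sep <- lines[seq.int(3L, length(lines), by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(sep, 1L, 1L) != "+")
  if (length(bad)) {
    abort(sprintf("malformed FASTQ %s: bad record %d", path, bad[1L]))
  }
  seqs <- lines[seq.int(2L, length(lines), by = 4L)]
  qual <- lines[seq.int(4L, length(lines), by = 4L)]
  badlen <- which(nchar(seqs) != nchar(qual))
  if (length(badlen)) {
    abort(sprintf("malformed FASTQ %s: sequence/quality length differ at record %d",
                  path, badlen[1L]))
  }
  toupper(seqs)
}

#' Merge spacer count tables from the same sample
#'
#' Element-wise sum of counts across tables (e.g. sequencing lanes of one
#' sample); totals are summed. All tables must carry the same `sample_id`.
#'
#' @param ... `spacer_counts` tables, or a single list of them.
#' @return A merged `spacer_counts` table.
#' @export
merge_spacer_counts <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && !is.data.frame(tables[[1L]])) {
    tables <- tables[[1L]]
  }
  if (length(tables) == 0L) abort("no tables to merge")
  ids <- unique(vapply(tables, function(t) attr(t, "sample_id") %||% NA_character_,
                       character(1L)))
  if (length(ids) > 1L) {
    abort(paste0("cannot merge counts from different samples: ",
                 paste(ids, collapse = ", ")))
  }
  all <- bind_rows(lapply(tables, function(t) t[c("spacer_sequence", "count")]))
  merged <- all |>
    group_by(.data$spacer_sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count), .data$spacer_sequence)
  new_spacer_counts(
    merged, ids,
    sum(vapply(tables, function(t) as.numeric(attr(t, "total_reads") %||% 0), numeric(1L))),
    sum(vapply(tables, function(t) as.numeric(attr(t, "total_spacers") %||% 0), numeric(1L))),
    attr(tables[[1L]], "config")
  )
}

#' Write and read spacer count tables
#'
#' `write_spacer_counts()` writes the count TSV (columns `spacer_sequence`,
#' `count`) plus a JSON sidecar (`<path>.json`) holding the sample id,
#' totals and the extraction configuration; `read_spacer_counts()` restores
#' both.
#'
#' @param counts A `spacer_counts` table.
#' @param path Output TSV path.
#' @return `write_spacer_counts()` returns `path` invisibly;
#'   `read_spacer_counts()` returns a `spacer_counts` table.
#' @export
write_spacer_counts <- function(counts, path) {
  stopifnot(is.data.frame(counts),
            all(c("spacer_sequence", "count") %in% names(counts)))
  readr::write_tsv(counts[c("spacer_sequence", "count")], path)
  side <- list(
    sample_id = attr(counts, "sample_id"),
    total_reads = attr(counts, "total_reads"),
    total_spacers = attr(counts, "total_spacers"),
    config = attr(counts, "config")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spacer_counts
#' @export
read_spacer_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("no such count table: ", path))
  counts <- readr::read_tsv(path, col_types = readr::cols(
    spacer_sequence = readr::col_character(),
    count = readr::col_integer()
  ))
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else {
    list(sample_id = NA_character_, total_reads = sum(counts$count),
         total_spacers = sum(counts$count), config = NULL)
  }
  new_spacer_counts(counts, side$sample_id, side$total_reads,
                    side$total_spacers, side$config)
}
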