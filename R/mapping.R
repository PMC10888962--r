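#' Align spacer queries to a genome (ungapped)
#'
#' Finds all ungapped (Hamming) matches of each query on either strand of
#' the genome within the mismatch budget, then keeps only the best hits
#' (fewest mismatches) per query. Queries whose best mismatch count is
#' shared by several positions are multi-hit (`n_hits > 1`); acquired
#' spacers are exact genome substrings barring sequencing error, so the
#' default budget is 1.
#'
#' @param queries Tibble with `query_id` and `sequence` columns, or a
#'   character vector of sequences (named or not).
#' @param genome A [genome_record()] or DNA string.
#' @param max_mismatches Hamming budget (default 1).
#' @return A tibble of best hits: `query_id`, `start`, `end` (0-based
#'   half-open, plus-strand interval), `strand`, `mismatches`, `n_hits`
#'   (number of tied best hits for that query). Unmapped queries contribute
#'   no rows; attribute `qc` tallies queries, unmapped and multi-hit.
#' @export
align_spacers <- function(queries, genome, max_mismatches = 1) {
  genome <- as_genome(genome)
  if (is.character(queries)) {
    ids <- names(queries) %||% sprintf("q%d", seq_along(queries))
    queries <- tibble(query_id = ids, sequence = unname(queries))
  }
  stopifnot(is.data.frame(queries),
            all(c("query_id", "sequence") %in% names(queries)))
  if (nrow(queries) == 0L) {
    out <- tibble(query_id = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer(),
                  n_hits = integer())
    attr(out, "qc") <- list(n_queries = 0L, n_unmapped = 0L, n_multi = 0L)
    return(out)
  }
  seqs <- toupper(queries$sequence)
  if (any(nchar(seqs) < 20L)) abort("queries must be >= 20 nt")
  hits <- hamming_hits(seqs, genome, max_mismatches)
  if (nrow(hits) == 0L) {
    out <- hits[c("start", "end", "strand", "mismatches")]
    out <- tibble(query_id = character(), out, n_hits = integer())
    attr(out, "qc") <- list(n_queries = nrow(queries),
                            n_unmapped = nrow(queries), n_multi = 0L)
    return(out)
  }
  best <- hits |>
    group_by(.data$query) |>
    filter(.data$mismatches == min(.data$mismatches)) |>
    mutate(n_hits = n()) |>
    ungroup()
  out <- tibble(
    query_id = queries$query_id[best$query],
    start = best$start, end = best$end, strand = best$strand,
    mismatches = best$mismatches, n_hits = best$n_hits
  )
  mapped <- unique(best$query)
  attr(out, "qc") <- list(
    n_queries = nrow(queries),
    n_unmapped = nrow(queries) - length(mapped),
    n_multi = length(unique(best$query[best$n_hits > 1L]))
  )
  out
}

#' Strand-resolved per-nucleotide coverage from alignment hits
#'
#' Increments every genome position in `[start, end)` on the hit's strand by
#' one, at single-nucleotide resolution. Multi-hit queries are dropped (and
#' tallied) rather than double-counted.
#'
#' @param hits Best-hit tibble from [align_spacers()].
#' @param L Genome length.
#' @param genome_id Track name used when writing bedGraph files.
#' @return A `coverage_track` tibble with columns `position` (0-based),
#'   `plus_count`, `minus_count`; attributes `genome_id`, `n_hits_used`,
#'   `n_multi_dropped`.
#' @export
strand_coverage <- function(hits, L, genome_id = "genome") {
  stopifnot(is.data.frame(hits),
            all(c("start", "end", "strand") %in% names(hits)))
  L <- as.integer(L)
  n_multi <- 0L
  if ("n_hits" %in% names(hits)) {
    n_multi <- length(unique(hits$query_id[hits$n_hits > 1L]))
    hits <- hits[hits$n_hits == 1L, , drop = FALSE]
  }
  if (nrow(hits) > 0L &&
      (min(hits$start) < 0L || max(hits$end) > L)) {
    abort("alignment hit outside [0, L)")
  }
  cov_one <- function(sub) {
    if (nrow(sub) == 0L) return(integer(L))
    d_start <- tabulate(sub$start + 1L, nbins = L + 1L)
    d_end <- tabulate(sub$end + 1L, nbins = L + 1L)
    cumsum(d_start - d_end)[seq_len(L)]
  }
  out <- tibble(
    position = seq_len(L) - 1L,
    plus_count = cov_one(hits[hits$strand == "plus", , drop = FALSE]),
    minus_count = cov_one(hits[hits$strand == "minus", , drop = FALSE])
  )
  attr(out, "genome_id") <- genome_id
  attr(out, "n_hits_used") <- nrow(hits)
  attr(out, "n_multi_dropped") <- n_multi
  class(out) <- c("coverage_track", class(out))
  out
}

#' RPM-normalize a coverage track
#'
#' Converts per-position counts to reads per million total aligned reads:
#' `rpm[pos] = 1e6 * count[pos] / total_aligned_reads`, per strand. The
#' denominator is the number of reads aligned anywhere (phage plus host),
#' supplied explicitly to keep the normalization auditable.
#'
#' @param track A `coverage_track` from [strand_coverage()].
#' @param total_aligned_reads Positive denominator.
#' @return The track with added `plus_rpm` and `minus_rpm` columns.
#' @export
rpm_normalize <- function(track, total_aligned_reads) {
  stopifnot(is.data.frame(track),
            all(c("plus_count", "minus_count") %in% names(track)))
  if (!is.numeric(total_aligned_reads) || length(total_aligned_reads) != 1L ||
      is.na(total_aligned_reads) || total_aligned_reads <= 0) {
    abort("total_aligned_reads must be a single positive number")
  }
  track$plus_rpm <- 1e6 * track$plus_count / total_aligned_reads
  track$minus_rpm <- 1e6 * track$minus_count / total_aligned_reads
  attr(track, "total_aligned_reads") <- total_aligned_reads
  track
}

#' Write and read strand coverage tracks as bedGraph
#'
#' `write_coverage_bedgraph()` writes one bedGraph file per available track
#' column (`<prefix>.plus_count.bedgraph` etc.), run-length compressed with
#' zero runs omitted; `read_coverage_bedgraph()` reconstructs the
#' per-position track. The pair round-trips exactly.
#'
#' @param track A `coverage_track`, optionally RPM-normalized.
#' @param prefix Output path prefix.
#' @param genome_id Chromosome name; defaults to the track's.
#' @return `write_coverage_bedgraph()` returns the written paths invisibly.
#' @export
write_coverage_bedgraph <- function(track, prefix, genome_id = NULL) {
  stopifnot(is.data.frame(track), "position" %in% names(track))
  genome_id <- genome_id %||% attr(track, "genome_id") %||% "genome"
  value_cols <- intersect(c("plus_count", "minus_count", "plus_rpm", "minus_rpm"),
                          names(track))
  paths <- character()
  for (col in value_cols) {
    v <- track[[col]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based starts
    keep <- r$values != 0
    bed <- tibble(chrom = genome_id, start = starts[keep], end = ends[keep],
                  value = r$values[keep])
    path <- paste0(prefix, ".", col, ".bedgraph")
    readr::write_tsv(bed, path, col_names = FALSE)
    paths[col] <- path
  }
  invisible(paths)
}

#' @rdname write_coverage_bedgraph
#' @param L Genome length of the reconstructed track.
#' @return `read_coverage_bedgraph()` returns a `coverage_track` tibble with
#'   every `<prefix>.<column>.bedgraph` found.
#' @export
read_coverage_bedgraph <- function(prefix, L) {
  L <- as.integer(L)
  out <- tibble(position = seq_len(L) - 1L)
  genome_id <- "genome"
  found <- FALSE
  for (col in c("plus_count", "minus_count", "plus_rpm", "minus_rpm")) {
    path <- paste0(prefix, ".", col, ".bedgraph")
    if (!file.exists(path)) next
    found <- TRUE
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                           col_types = "ciid")
    v <- numeric(L)
    if (nrow(bed)) {
      if (max(bed$end) > L) abort("bedGraph interval outside [0, L)")
      genome_id <- bed$chrom[1L]
      for (i in seq_len(nrow(bed))) {
        v[(bed$start[i] + 1L):bed$end[i]] <- bed$value[i]
      }
    }
    out[[col]] <- if (grepl("count$", col)) as.integer(v) else v
  }
  if (!found) abort(paste0("no bedGraph files found for prefix: ", prefix))
  attr(out, "genome_id") <- genome_id
  class(out) <- c("coverage_track", class(out))
  out
}

#' Coverage mass by region and strand
#'
#' Sums a coverage track column over each annotated region, per strand —
#' used to compare, e.g., minus-strand acquisition mass inside the early
#' operon against every other region/strand combination.
#'
#' @param track A `coverage_track`.
#' @param regions Region annotation tibble (see [default_regions()]).
#' @param value `"rpm"` or `"count"`.
#' @return A tibble `region`, `strand`, `mass`.
#' @export
coverage_mass_by_region <- function(track, regions, value = c("rpm", "count")) {
  value <- match.arg(value)
  cols <- if (value == "rpm") c("plus_rpm", "minus_rpm") else
    c("plus_count", "minus_count")
  if (!all(cols %in% names(track))) {
    abort(paste0("track lacks columns: ", paste(cols, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    idx <- track$position >= r$start & track$position < r$end
    tibble(region = rep(r$region, 2L), strand = c("plus", "minus"),
           mass = c(sum(track[[cols[1L]]][idx]), sum(track[[cols[2L]]][idx])))
  })
  bind_rows(rows)
}
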