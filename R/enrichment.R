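#' Per-spacer frequencies in a sample
#'
#' Converts a spacer count table into frequencies `f_s = c_s / sum(c)` over
#' the spacers counted in the sample.
#'
#' @param counts A `spacer_counts` table (see [extract_spacer_counts()]), or
#'   any data frame with `spacer_sequence` and `count` columns.
#' @return The table with an added `freq` column; attribute `depth` holds
#'   the total counted reads.
#' @export
spacer_frequencies <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("spacer_sequence", "count") %in% names(counts)))
  depth <- sum(as.numeric(counts$count))
  if (depth <= 0) abort("empty sample: total spacer count is 0")
  counts$freq <- counts$count / depth
  attr(counts, "depth") <- depth
  counts
}

#' Enrichment ratios between two timepoints
#'
#' For every spacer seen at the reference timepoint with at least
#' `min_t0_count` reads, computes the enrichment ratio `E = f_t / f_0`
#' (post-infection frequency over uninfected-library frequency). Spacers
#' below the reference threshold are reported with status `"absent_t0"` and
#' no ratio; spacers undetected post-infection keep `f_t = 0`, giving
#' `E = 0` and status `"absent_t"`. No pseudocounts are used.
#'
#' @param ft Frequencies at the post-infection timepoint
#'   (from [spacer_frequencies()]).
#' @param f0 Frequencies of the uninfected library at `t0`.
#' @param min_t0_count Minimum `t0` read count for a spacer to get a ratio
#'   (default 5).
#' @return A tibble with columns `spacer_sequence`, `count_t0`, `count_t`,
#'   `f0`, `ft`, `ratio`, `status` (`ok`, `absent_t0`, `absent_t`).
#' @export
enrichment_ratios <- function(ft, f0, min_t0_count = 5) {
  for (x in list(ft, f0)) {
    stopifnot(is.data.frame(x),
              all(c("spacer_sequence", "count", "freq") %in% names(x)))
  }
  joined <- full_join(
    tibble(spacer_sequence = f0$spacer_sequence,
           count_t0 = f0$count, f0 = f0$freq),
    tibble(spacer_sequence = ft$spacer_sequence,
           count_t = ft$count, ft = ft$freq),
    by = "spacer_sequence"
  )
  joined <- joined |>
    mutate(
      count_t0 = ifelse(is.na(.data$count_t0), 0L, .data$count_t0),
      count_t = ifelse(is.na(.data$count_t), 0L, .data$count_t),
      f0 = ifelse(is.na(.data$f0), 0, .data$f0),
      ft = ifelse(is.na(.data$ft), 0, .data$ft),
      status = dplyr::case_when(
        .data$count_t0 < min_t0_count ~ "absent_t0",
        .data$count_t == 0L ~ "absent_t",
        TRUE ~ "ok"
      ),
      ratio = ifelse(.data$status == "absent_t0", NA_real_,
                     .data$ft / .data$f0)
    ) |>
    arrange(.data$spacer_sequence)
  as_tibble(joined)
}

#' Locate spacer sequences on a genome
#'
#' Finds, for each query, every position where it matches the genome plus
#' strand or reverse-complement-matches it (i.e. matches the minus strand)
#' within a Hamming mismatch budget. A query with exactly one hit is
#' `unique`; more are `ambiguous`; none is `unmapped`.
#'
#' @param sequences Character vector of query sequences (>= 20 nt each).
#' @param genome A [genome_record()] or DNA string.
#' @param max_mismatches Hamming budget per hit (default 0).
#' @return A tibble with one row per query: `sequence`, `start`, `end`
#'   (0-based half-open plus-strand interval of the hit when unique),
#'   `strand`, `n_hits`, `status`.
#' @export
locate_spacers <- function(sequences, genome, max_mismatches = 0) {
  genome <- as_genome(genome)
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L) {
    return(tibble(sequence = character(), start = integer(), end = integer(),
                  strand = character(), n_hits = integer(), status = character()))
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 20L)) abort("queries must be >= 20 nt")
  hits <- hamming_hits(sequences, genome, max_mismatches)
  per_query <- hits |>
    group_by(.data$query) |>
    summarise(n_hits = n(),
              start = .data$start[1L], end = .data$end[1L],
              strand = .data$strand[1L], .groups = "drop")
  n_hits <- integer(length(sequences))
  n_hits[per_query$query] <- per_query$n_hits
  start <- rep(NA_integer_, length(sequences))
  end <- start
  strand <- rep(NA_character_, length(sequences))
  uq <- per_query[per_query$n_hits == 1L, ]
  start[uq$query] <- uq$start
  end[uq$query] <- uq$end
  strand[uq$query] <- uq$strand
  tibble(
    sequence = sequences, start = start, end = end, strand = strand,
    n_hits = n_hits,
    status = dplyr::case_when(n_hits == 1L ~ "unique",
                              n_hits > 1L ~ "ambiguous",
                              TRUE ~ "unmapped")
  )
}

# All Hamming hits of queries on both strands of a genome, as a tibble
# (query index, 0-based start/end on the plus strand, strand, mismatches).
# Exact matching of equal-width queries goes through a PDict; otherwise the
# queries are matched one by one.
hamming_hits <- function(sequences, genome, max_mismatches) {
  subj <- Biostrings::DNAString(genome$sequence)
  widths <- nchar(sequences)
  res <- list()
  if (max_mismatches == 0L) {
    for (w in unique(widths)) {
      idx <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[idx]))
      for (str in c("plus", "minus")) {
        pats <- if (str == "plus") pd else {
          Biostrings::PDict(Biostrings::DNAStringSet(revcomp(sequences[idx])))
        }
        m <- Biostrings::matchPDict(pats, subj)
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0L) next
        ir <- unlist(m)
        res[[length(res) + 1L]] <- tibble(
          query = rep.int(idx, nh),
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir),
          strand = str,
          mismatches = 0L
        )
      }
    }
  } else {
    for (i in seq_along(sequences)) {
      for (str in c("plus", "minus")) {
        pat <- if (str == "plus") sequences[i] else revcomp(sequences[i])
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
        if (length(m) == 0L) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                          starting.at = IRanges::start(m),
                                          with.indels = FALSE)
        res[[length(res) + 1L]] <- tibble(
          query = i,
          start = IRanges::start(m) - 1L,
          end = IRanges::end(m),
          strand = str,
          mismatches = as.integer(mm)
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble(query = integer(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer()))
  }
  out <- bind_rows(res)
  arrange(out, .data$query, .data$start, .data$strand)
}

#' Region annotations over the genome
#'
#' `region_spec()` builds one annotation row; `default_regions()` returns
#' the canonical two-operon layout of the screen: the early operon (PE,
#' default `[1000, 15000)`) and the late operon (PL, `[15000, 42000)`), both
#' transcribed from the plus strand. With `split_pe = TRUE` the early operon
#' is split at `pe_split` into `PE_upstream` / `PE_downstream`, the
#' functional boundary between Csm6-independent and Csm6-dependent spacers
#' (not quantified in the underlying screen; configurable).
#'
#' @param name Region name.
#' @param start,end 0-based half-open genome interval.
#' @param strand_of_transcription `"plus"` or `"minus"`.
#' @return A tibble with columns `region`, `start`, `end`,
#'   `strand_of_transcription`.
#' @export
region_spec <- function(name, start, end, strand_of_transcription = "plus") {
  if (!(start < end)) abort("region must satisfy start < end")
  stopifnot(strand_of_transcription %in% c("plus", "minus"))
  tibble(region = as.character(name), start = as.integer(start),
         end = as.integer(end),
         strand_of_transcription = strand_of_transcription)
}

#' @rdname region_spec
#' @param L Genome length.
#' @param pe,pl 0-based half-open intervals of the early and late operons.
#' @param split_pe Split PE into upstream/downstream halves.
#' @param pe_split Split coordinate (default: PE midpoint).
#' @export
default_regions <- function(L = 42000, pe = c(1000, 15000),
                            pl = c(15000, min(42000, L)), split_pe = FALSE,
                            pe_split = round(mean(pe))) {
  check_regions_valid(L, pe, pl)
  if (split_pe) {
    bind_rows(
      region_spec("PE_upstream", pe[1], pe_split),
      region_spec("PE_downstream", pe_split, pe[2]),
      region_spec("PL", pl[1], pl[2])
    )
  } else {
    bind_rows(
      region_spec("PE", pe[1], pe[2]),
      region_spec("PL", pl[1], pl[2])
    )
  }
}

check_regions_valid <- function(L, pe, pl) {
  if (pe[1] >= pe[2] || pl[1] >= pl[2]) abort("regions must have start < end")
  if (pl[2] > L || pe[2] > L) abort("region outside genome")
  if (max(pe[1], pl[1]) < min(pe[2], pl[2]) && pe[2] > pl[1] && pl[2] > pe[1]) {
    abort("PE and PL regions may not overlap")
  }
  invisible(TRUE)
}

#' Strand-resolved enrichment landscape over the genome
#'
#' Resolves each enrichment record to its genomic position and matched
#' strand via the library design (or a [locate_spacers()] result) and emits
#' per-strand (position, enrichment) tracks: one value per designed spacer,
#' plotted at the start of its plus-strand interval. Ambiguous or unmapped
#' spacers and records without a ratio are excluded and tallied in the `qc`
#' attribute.
#'
#' @param records Enrichment records from [enrichment_ratios()].
#' @param spacers Library manifest (tibble with `sequence`, `start`,
#'   `strand`) or a [locate_spacers()] result (with a `status` column, in
#'   which case only `unique` locations are used).
#' @return A tibble with columns `spacer_sequence`, `position`, `strand`,
#'   `ratio`, `ft`, `detected`, ordered by strand then position; attribute
#'   `qc` is a list of exclusion tallies.
#' @export
position_profile <- function(records, spacers) {
  stopifnot(is.data.frame(records),
            all(c("spacer_sequence", "ratio", "ft") %in% names(records)))
  stopifnot(is.data.frame(spacers))
  if ("status" %in% names(spacers) && "n_hits" %in% names(spacers)) {
    n_ambiguous <- sum(spacers$status == "ambiguous")
    n_unmapped <- sum(spacers$status == "unmapped")
    spacers <- spacers[spacers$status == "unique", , drop = FALSE]
  } else {
    n_ambiguous <- 0L
    n_unmapped <- 0L
  }
  stopifnot(all(c("sequence", "start", "strand") %in% names(spacers)))
  joined <- dplyr::inner_join(
    records, distinct(spacers[c("sequence", "start", "strand")]),
    by = c(spacer_sequence = "sequence")
  )
  n_no_design <- nrow(records) - nrow(joined)
  n_no_ratio <- sum(is.na(joined$ratio))
  out <- joined |>
    filter(!is.na(.data$ratio)) |>
    mutate(position = .data$start, detected = .data$ft > 0) |>
    select("spacer_sequence", "position", "strand", "ratio", "ft",
           "detected") |>
    arrange(.data$strand, .data$position)
  attr(out, "qc") <- list(
    n_records = nrow(records), n_ambiguous = n_ambiguous,
    n_unmapped = n_unmapped, n_no_design = n_no_design,
    n_excluded_no_ratio = n_no_ratio, n_profiled = nrow(out)
  )
  out
}

#' Region-level enrichment summaries
#'
#' For each annotated region and each matched strand, the number of profiled
#' spacers whose start lies in `[start, end)`, the mean and sample standard
#' deviation (n-1 denominator) of their enrichment ratios, and the number
#' detected post-infection. This is the statistic behind region-level
#' statements such as mean enrichment of early- vs late-operon targeting
#' spacers.
#'
#' @param profile Output of [position_profile()].
#' @param regions Region annotation tibble (see [default_regions()]).
#' @param L Optional genome length; if supplied, regions extending past it
#'   are an error.
#' @return A tibble with columns `region`, `start`, `end`, `strand_matched`,
#'   `n_spacers`, `mean_enrichment`, `sd_enrichment` (`NA` for n < 2),
#'   `n_detected`.
#' @export
region_summary <- function(profile, regions, L = NULL) {
  stopifnot(is.data.frame(profile),
            all(c("position", "strand", "ratio", "detected") %in% names(profile)))
  stopifnot(is.data.frame(regions),
            all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end)) abort("region with start >= end")
  if (!is.null(L) && any(regions$end > L)) abort("region outside genome")
  combos <- tidyr::expand_grid(
    ri = seq_len(nrow(regions)),
    strand_matched = c("plus", "minus")
  )
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- regions[combos$ri[i], ]
    str <- combos$strand_matched[i]
    sub <- profile[profile$strand == str &
                     profile$position >= r$start &
                     profile$position < r$end, , drop = FALSE]
    tibble(
      region = r$region, start = r$start, end = r$end,
      strand_matched = str, n_spacers = nrow(sub),
      mean_enrichment = if (nrow(sub)) mean(sub$ratio) else NA_real_,
      sd_enrichment = if (nrow(sub) >= 2L) sd(sub$ratio) else NA_real_,
      n_detected = sum(sub$detected)
    )
  })
  bind_rows(rows)
}

#' Distinct detected spacers per region and strand
#'
#' A spacer is "detected" in a sample if its count is positive. Counts the
#' distinct detected spacers per region and matched strand — the statistic
#' behind genotype comparisons of how many minus-strand spacers survive
#' selection.
#'
#' @param counts A `spacer_counts` table for one sample.
#' @param spacers Library manifest (tibble with `sequence`, `start`, `strand`).
#' @param regions Region annotation tibble.
#' @return A tibble `region`, `strand_matched`, `n_detected`.
#' @export
unique_detection_by_region <- function(counts, spacers, regions) {
  stopifnot(is.data.frame(counts),
            all(c("spacer_sequence", "count") %in% names(counts)))
  stopifnot(all(c("sequence", "start", "strand") %in% names(spacers)))
  det <- counts[counts$count > 0L, "spacer_sequence", drop = FALSE]
  located <- dplyr::inner_join(det,
                               distinct(spacers[c("sequence", "start", "strand")]),
                               by = c(spacer_sequence = "sequence"))
  combos <- tidyr::expand_grid(
    ri = seq_len(nrow(regions)),
    strand_matched = c("plus", "minus")
  )
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- regions[combos$ri[i], ]
    str <- combos$strand_matched[i]
    tibble(
      region = r$region, strand_matched = str,
      n_detected = sum(located$strand == str &
                         located$start >= r$start & located$start < r$end)
    )
  })
  bind_rows(rows)
}

#' Read and write region annotations as BED
#'
#' Minimal BED interchange for region annotations: columns chrom, start,
#' end, name, score, strand (strand is the strand of transcription).
#'
#' @param regions Region tibble (see [region_spec()]).
#' @param path BED file path.
#' @param genome_id Chromosome name to write.
#' @return `write_regions_bed()` returns `path` invisibly;
#'   `read_regions_bed()` returns a region tibble.
#' @export
write_regions_bed <- function(regions, path, genome_id = "genome") {
  bed <- tibble(
    chrom = genome_id, start = regions$start, end = regions$end,
    name = regions$region, score = 0L,
    strand = ifelse((regions$strand_of_transcription %||% "plus") == "plus",
                    "+", "-")
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such BED file: ", path))
  bed <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  tibble(region = bed$name, start = bed$start, end = bed$end,
         strand_of_transcription = ifelse(bed$strand == "-", "minus", "plus"))
}
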