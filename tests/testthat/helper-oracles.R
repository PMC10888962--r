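# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-position loops, string chopping) so they share no
# code path with the package implementations they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# every valid (start, strand) for tiling a genome of length L: the oracle
# enumerates starts one by one instead of using the closed-form count
oracle_tile_starts <- function(L, k, stride) {
  starts <- integer()
  s <- 0L
  while (s + k <= L) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# all-substring scan for repeat-flanked inserts in a single read
oracle_find_inserts <- function(read, repeat_seq, max_mismatches,
                                min_len, max_len) {
  rl <- nchar(repeat_seq)
  n <- nchar(read)
  occ <- integer()
  for (i in seq_len(max(0, n - rl + 1))) {
    if (hamming(substr(read, i, i + rl - 1), repeat_seq) <= max_mismatches) {
      occ <- c(occ, i)
    }
  }
  kept <- integer()
  last_end <- 0L
  for (i in occ) {
    if (i > last_end) {
      kept <- c(kept, i)
      last_end <- i + rl - 1L
    }
  }
  inserts <- character()
  if (length(kept) >= 2L) {
    for (j in 2:length(kept)) {
      s <- kept[j - 1L] + rl
      e <- kept[j] - 1L
      len <- e - s + 1L
      if (len >= min_len && len <= max_len) {
        inserts <- c(inserts, substr(read, s, e))
      }
    }
  }
  inserts
}

# exhaustive all-position Hamming scan of a query over both genome strands;
# returns a data.frame of hits (0-based start, strand, mismatches)
oracle_hamming_scan <- function(query, genome_seq, max_mismatches) {
  k <- nchar(query)
  L <- nchar(genome_seq)
  subs <- substring(genome_seq, 1:(L - k + 1), k:L)
  sub_mat <- matrix(unlist(strsplit(subs, "")), nrow = k)
  hits <- list()
  for (str in c("plus", "minus")) {
    pat <- if (str == "plus") query else rc_chr(query)
    mm <- colSums(sub_mat != strsplit(pat, "")[[1]])
    at <- which(mm <= max_mismatches)
    if (length(at)) {
      hits[[str]] <- data.frame(start = at - 1L, strand = str,
                                mismatches = mm[at])
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(start = integer(), strand = character(),
                      mismatches = integer())
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# small deterministic screen fixture shared by several test files
toy_screen <- function(seed = 424, L = 3000, n_reads = 20000) {
  sim <- simulate_genome(length = L, pe = c(200, 1500), pl = c(1500, L),
                         seed = seed)
  spacers <- design_tiled_spacers(sim$genome, k = 35, stride = 10)
  list(sim = sim, spacers = spacers,
       pe = c(200, 1500), pl = c(1500, L), pe_split = 850)
}

write_toy_fastq <- function(reads, path) {
  lines <- character(4L * length(reads))
  lines[seq(1, length(lines), 4)] <- sprintf("@r%d", seq_along(reads))
  lines[seq(2, length(lines), 4)] <- reads
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep("I", nchar(reads))
  writeLines(lines, path)
  path
}
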