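# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- a two-operon phage genome, repeat-spacer-repeat
# amplicon reads, class-dependent post-infection selection, two-phase
# transcription, strand-biased acquisition and bimodal well regrowth --
# and return ground truth alongside every artifact. All magnitudes
# (fitness weights, dropout rates, acquisition biases) are simulator
# conventions chosen to reproduce qualitative orderings only, never
# measured values. Every generator is deterministic for a fixed seed.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a two-operon phage genome
#'
#' Generates a seeded pseudo-random genome with an early operon (PE) and a
#' late operon (PL), both transcribed from the plus strand, and guarantees
#' that no exact 20-mer occurs twice (duplicated 20-mers are
#' rejection-resampled), so every spacer of length >= 20 maps uniquely.
#'
#' @param length Genome length in nt (default 42,000).
#' @param pe,pl 0-based half-open operon intervals (defaults `[1000, 15000)`
#'   and `[15000, 42000)`).
#' @param seed Integer seed (mandatory).
#' @param id Genome identifier.
#' @return A list with elements `genome` (a [genome_record()]), `regions`
#'   (tibble from [default_regions()]) and `pe_split` (the PE midpoint used
#'   to subdivide the early operon).
#' @export
simulate_genome <- function(length = 42000, pe = c(1000, 15000),
                            pl = c(15000, 42000), seed, id = "sim_phage") {
  stopifnot(!missing(seed))
  check_regions_valid(length, pe, pl)
  seq <- withr::with_seed(derive_seed(seed, 11L), {
    s <- sample(DNA_BASES, length, replace = TRUE)
    # resample any window participating in a duplicated 20-mer, counting
    # occurrences on both strands so spacers of length >= 20 map uniquely
    repeat {
      big <- paste(s, collapse = "")
      if (length < 20L) break
      kf <- substring(big, 1:(length - 19L), 20:length)
      kr <- revcomp(kf)
      d <- duplicated(c(kf, kr)) | duplicated(c(kf, kr), fromLast = TRUE)
      nk <- base::length(kf)
      dup <- d[seq_len(nk)] | d[nk + seq_len(nk)]
      if (!any(dup)) break
      for (i in which(dup)) {
        off <- sample.int(20L, 1L)
        s[i + off - 1L] <- sample(DNA_BASES, 1L)
      }
    }
    big
  })
  list(
    genome = genome_record(seq, id = id),
    regions = default_regions(L = length, pe = pe, pl = pl),
    pe_split = as.integer(round(mean(pe)))
  )
}

#' Classify spacers by strand and operon region
#'
#' Assigns each designed spacer to one of the selection classes
#' `plus_strand`, `minus_PE_up`, `minus_PE_down`, `minus_PL` from its
#' matched strand and start position. Boundaries partition the whole
#' genome, so every spacer is classifiable: minus-strand starts before
#' `pe_split` are `minus_PE_up`, before `pe_end` are `minus_PE_down`, and
#' the rest `minus_PL`.
#'
#' @param spacers Library manifest tibble (`start`, `strand`).
#' @param pe_split,pe_end Class boundaries (defaults 8000 and 15000).
#' @return `spacers` with an added `class` column.
#' @export
classify_spacers <- function(spacers, pe_split = 8000, pe_end = 15000) {
  stopifnot(is.data.frame(spacers),
            all(c("start", "strand") %in% names(spacers)))
  if (!pe_split < pe_end) abort("need pe_split < pe_end")
  cls <- ifelse(spacers$strand == "plus", "plus_strand",
                ifelse(spacers$start < pe_split, "minus_PE_up",
                       ifelse(spacers$start < pe_end, "minus_PE_down",
                              "minus_PL")))
  spacers$class <- cls
  spacers
}

#' Post-infection selection model
#'
#' Relative post-infection fitness weight and lineage-dropout probability
#' for each spacer class under the three screened genotypes. The numbers
#' are simulator defaults chosen to reproduce the screens' qualitative rank
#' orderings (wild type: early-operon minus-strand spacers win; dCsm6: the
#' Csm6-dependent downstream class and the late operon collapse; Cas10-HD:
#' late-operon spacers outgrow early-operon ones), not measured values.
#'
#' @param genotype `"wt"`, `"dcsm6"` or `"cas10hd"`.
#' @return A tibble with columns `class`, `fitness`, `dropout` and
#'   attribute `genotype`.
#' @export
selection_model <- function(genotype = c("wt", "dcsm6", "cas10hd")) {
  genotype <- match.arg(genotype)
  classes <- c("plus_strand", "minus_PE_up", "minus_PE_down", "minus_PL")
  params <- switch(
    genotype,
    wt = list(fitness = c(0.3, 10, 8, 0.3), dropout = c(0, 0, 0, 0)),
    dcsm6 = list(fitness = c(0.3, 10, 0.1, 0.05),
                 dropout = c(0.8, 0, 0.5, 0.9)),
    cas10hd = list(fitness = c(0.3, 0.8, 0.8, 2.0), dropout = c(0, 0, 0, 0))
  )
  out <- tibble(class = classes, fitness = params$fitness,
                dropout = params$dropout)
  attr(out, "genotype") <- genotype
  out
}

#' @rdname selection_model
#' @param class Character vector of class labels.
#' @param fitness,dropout Numeric vectors aligned with `class`.
#' @export
custom_selection_model <- function(class, fitness, dropout = 0) {
  stopifnot(length(class) == length(fitness))
  if (any(fitness < 0)) abort("fitness weights must be >= 0")
  dropout <- rep_len(dropout, length(class))
  if (any(dropout < 0 | dropout > 1)) abort("dropout must be in [0, 1]")
  out <- tibble(class = as.character(class), fitness = fitness,
                dropout = dropout)
  attr(out, "genotype") <- "custom"
  out
}

# -- amplicon read emission -------------------------------------------------

# Build repeat+spacer+repeat reads for an expanded spacer index vector,
# apply uniform substitution errors through one raw-byte pass, and write a
# FASTQ file. Constant read length; constant 'I' qualities.
emit_amplicon_fastq <- function(spacer_seqs, expanded_idx, path, read_length,
                                repeat_seq, error_rate, orient_rc_frac,
                                seed) {
  k <- unique(nchar(spacer_seqs))
  if (length(k) != 1L) abort("spacers must share one length")
  rep_len_nt <- nchar(repeat_seq)
  insert_len <- 2L * rep_len_nt + k
  if (insert_len > read_length) {
    abort(sprintf("read length %d too short for repeat-spacer-repeat insert (%d nt)",
                  read_length, insert_len))
  }
  pad_len <- read_length - insert_len
  n <- length(expanded_idx)
  withr::with_seed(derive_seed(seed, 23L), {
    pads <- if (pad_len > 0L) {
      pool <- vapply(seq_len(min(997L, max(n, 1L))), function(i)
        random_dna(pad_len), character(1L))
      pool[sample.int(length(pool), n, replace = TRUE)]
    } else rep("", n)
    reads <- paste0(repeat_seq, spacer_seqs[expanded_idx], repeat_seq, pads)
    if (error_rate > 0 && n > 0L) {
      reads <- mutate_bases(reads, error_rate, read_length)
    }
    if (orient_rc_frac > 0 && n > 0L) {
      flip <- runif(n) < orient_rc_frac
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
    }
    write_fastq(reads, path, read_length)
  })
  invisible(path)
}

# uniform substitution errors over equal-length reads via one raw-byte pass
mutate_bases <- function(reads, rate, read_length) {
  n <- length(reads)
  total <- n * read_length
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  pos <- sample(total, n_err)
  big <- charToRaw(paste(reads, collapse = ""))
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  cur <- match(big[pos], base_raw)
  shift <- sample.int(3L, n_err, replace = TRUE)
  big[pos] <- base_raw[((cur - 1L + shift) %% 4L) + 1L]
  big_chr <- rawToChar(big)
  starts <- seq.int(1L, by = read_length, length.out = n)
  substring(big_chr, starts, starts + read_length - 1L)
}

write_fastq <- function(reads, path, read_length) {
  n <- length(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq.int(1L, by = 4L, length.out = n)] <- sprintf("@read%d", seq_len(n))
    lines[seq.int(2L, by = 4L, length.out = n)] <- reads
    lines[seq.int(3L, by = 4L, length.out = n)] <- "+"
    lines[seq.int(4L, by = 4L, length.out = n)] <- strrep("I", read_length)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate amplicon sequencing of a spacer library
#'
#' Draws reads multinomially from per-spacer weights, embeds each spacer
#' between two direct repeats in a constant-length read (random padding,
#' half the reads reverse-complemented to emulate unoriented single-end
#' sequencing), applies uniform substitution errors, writes a FASTQ file
#' and returns the ground-truth count table.
#'
#' @param spacers Library manifest tibble (`spacer_id`, `sequence`).
#' @param path Output FASTQ path (`.gz` for gzip).
#' @param n_reads Number of reads to draw.
#' @param repeat_seq Direct repeat placed around each spacer; `NULL` draws
#'   a random 24-mer from the seed (returned in the attributes).
#' @param weights Per-spacer sampling weights (default uniform).
#' @param error_rate Per-base substitution error probability.
#' @param read_length Read length in nt (default 100).
#' @param orient_rc_frac Fraction of reads emitted reverse-complemented
#'   (default 0.5).
#' @param seed Integer seed (mandatory).
#' @return A tibble `spacer_id`, `spacer_sequence`, `weight`, `true_count`
#'   with attributes `repeat_seq`, `n_reads`, `path`.
#' @export
simulate_library_fastq <- function(spacers, path, n_reads = 1e6,
                                   repeat_seq = NULL, weights = NULL,
                                   error_rate = 0, read_length = 100,
                                   orient_rc_frac = 0.5, seed) {
  stopifnot(!missing(seed), is.data.frame(spacers),
            all(c("spacer_id", "sequence") %in% names(spacers)))
  if (is.null(repeat_seq)) {
    repeat_seq <- withr::with_seed(derive_seed(seed, 7L), random_dna(24L))
  }
  n_sp <- nrow(spacers)
  weights <- weights %||% rep(1, n_sp)
  if (length(weights) != n_sp || any(weights < 0) || sum(weights) == 0) {
    abort("weights must be non-negative, one per spacer, not all zero")
  }
  counts <- withr::with_seed(
    derive_seed(seed, 13L),
    as.integer(rmultinom(1L, n_reads, weights / sum(weights)))
  )
  expanded <- withr::with_seed(derive_seed(seed, 17L),
                               sample(rep.int(seq_len(n_sp), counts)))
  emit_amplicon_fastq(spacers$sequence, expanded, path, read_length,
                      repeat_seq, error_rate, orient_rc_frac, seed)
  truth <- tibble(spacer_id = spacers$spacer_id,
                  spacer_sequence = spacers$sequence,
                  weight = weights / sum(weights), true_count = counts)
  attr(truth, "repeat_seq") <- repeat_seq
  attr(truth, "n_reads") <- n_reads
  attr(truth, "path") <- path
  truth
}

#' Simulate post-infection amplicon sequencing under selection
#'
#' Classifies each spacer by strand and region, drops lineages with the
#' class dropout probability, weights survivors by `f0 * fitness(class)`
#' (uniform `f0`), then emits reads as in [simulate_library_fastq()].
#'
#' @inheritParams simulate_library_fastq
#' @param model Selection model tibble from [selection_model()].
#' @param pe_split,pe_end Class boundaries passed to [classify_spacers()].
#' @return A tibble `spacer_id`, `spacer_sequence`, `class`, `surviving`,
#'   `weight`, `true_count`, with the same attributes as
#'   [simulate_library_fastq()] plus `genotype`.
#' @export
simulate_selection_fastq <- function(spacers, model, path, n_reads = 1e6,
                                     repeat_seq = NULL, error_rate = 0,
                                     read_length = 100, orient_rc_frac = 0.5,
                                     pe_split = 8000, pe_end = 15000, seed) {
  stopifnot(!missing(seed), is.data.frame(model),
            all(c("class", "fitness", "dropout") %in% names(model)))
  cls <- classify_spacers(spacers, pe_split, pe_end)
  unknown <- setdiff(unique(cls$class), model$class)
  if (length(unknown)) {
    abort(paste0("selection model lacks classes: ",
                 paste(unknown, collapse = ", ")))
  }
  fit <- setNames(model$fitness, model$class)[cls$class]
  drop_p <- setNames(model$dropout, model$class)[cls$class]
  surviving <- withr::with_seed(derive_seed(seed, 19L),
                                runif(nrow(cls)) >= drop_p)
  w <- ifelse(surviving, fit, 0)
  if (sum(w) == 0) abort("all lineages dropped out; nothing to sequence")
  truth <- simulate_library_fastq(
    spacers, path, n_reads = n_reads, repeat_seq = repeat_seq, weights = w,
    error_rate = error_rate, read_length = read_length,
    orient_rc_frac = orient_rc_frac, seed = seed
  )
  truth$class <- cls$class
  truth$surviving <- surviving
  attr(truth, "genotype") <- attr(model, "genotype")
  truth[c("spacer_id", "spacer_sequence", "class", "surviving", "weight",
          "true_count")] -> out
  for (a in c("repeat_seq", "n_reads", "path", "genotype")) {
    attr(out, a) <- attr(truth, a) %||% attr(model, "genotype")
  }
  out
}

#' Simulate strand-aware RNA-seq coverage over the phage genome
#'
#' Two-phase transcription from the plus strand: the early operon (PE) is
#' covered from the first timepoint with a linear 5'->3' decay (so
#' downstream PE positions see less RNA than upstream ones), while the late
#' operon (PL) is silent at 5 minutes and rises between 5 and 15 minutes.
#' Per-timepoint depth factors emulate library-size variability and Poisson
#' noise is applied per position.
#'
#' @param L Genome length.
#' @param timepoints Minutes post-infection (default `c(5, 15, 30)`).
#' @param pe,pl Operon intervals (0-based half-open).
#' @param pe_level Mean PE coverage at the operon 5' end.
#' @param pe_decay Fractional 5'->3' coverage loss across PE (default 0.8).
#' @param pl_level Mean PL coverage once fully on.
#' @param depth_factors Per-timepoint library-depth multipliers, recycled.
#' @param seed Integer seed (mandatory).
#' @return A long tibble `timepoint`, `position`, `coverage` (plus-strand
#'   transcript coverage).
#' @export
simulate_rnaseq_coverage <- function(L = 42000, timepoints = c(5, 15, 30),
                                     pe = c(1000, 15000), pl = c(15000, 42000),
                                     pe_level = 200, pe_decay = 0.8,
                                     pl_level = 120,
                                     depth_factors = c(1, 1.4, 0.7), seed) {
  stopifnot(!missing(seed))
  check_regions_valid(L, pe, pl)
  depth_factors <- rep_len(depth_factors, length(timepoints))
  pos <- seq_len(L) - 1L
  pe_idx <- pos >= pe[1] & pos < pe[2]
  pl_idx <- pos >= pl[1] & pos < pl[2]
  pe_shape <- numeric(L)
  pe_shape[pe_idx] <- pe_level *
    (1 - pe_decay * (pos[pe_idx] - pe[1]) / (pe[2] - pe[1]))
  # PL switches on between 5 and 15 minutes post-infection
  pl_on <- function(t) min(1, max(0, (t - 5) / 10))
  rows <- lapply(seq_along(timepoints), function(i) {
    t <- timepoints[i]
    lambda <- pe_shape
    lambda[pl_idx] <- pl_level * pl_on(t)
    lambda <- lambda * depth_factors[i]
    cov <- withr::with_seed(derive_seed(seed, 29L + i),
                            rpois(L, lambda))
    tibble(timepoint = t, position = pos, coverage = as.integer(cov))
  })
  bind_rows(rows)
}

#' Simulate naively acquired spacers
#'
#' Samples (position, strand) pairs with genotype-specific bias and emits
#' the corresponding exact genome substrings (or reverse complements) of
#' length `k`: wild type draws 90% from the early operon minus strand, 5%
#' from the late operon minus strand and 5% from the plus strand; dCsm6
#' draws 90% from the upstream half of the early operon (minus strand);
#' Cas10-HD yields only a uniform background at 1% of the wild-type yield.
#'
#' @param genome A [genome_record()] or DNA string.
#' @param n Nominal number of acquired spacers at wild-type yield.
#' @param genotype `"wt"`, `"dcsm6"` or `"cas10hd"`.
#' @param k Spacer length (default 35).
#' @param pe,pl Operon intervals; `pe_split` bounds the upstream half.
#' @param pe_split Upstream/downstream boundary inside PE.
#' @param seed Integer seed (mandatory).
#' @return A tibble `query_id`, `sequence`, `start`, `end`, `strand`,
#'   `class`; attribute `genotype`.
#' @export
simulate_acquisition_spacers <- function(genome, n = 10000,
                                         genotype = c("wt", "dcsm6", "cas10hd"),
                                         k = 35, pe = c(1000, 15000),
                                         pl = c(15000, 42000), pe_split = 8000,
                                         seed) {
  stopifnot(!missing(seed))
  genotype <- match.arg(genotype)
  genome <- as_genome(genome)
  L <- genome$length
  empty <- tibble(query_id = character(), sequence = character(),
                  start = integer(), end = integer(), strand = character(),
                  class = character())
  draw <- withr::with_seed(derive_seed(seed, 31L), {
    if (genotype == "cas10hd") n <- round(0.01 * n)
    if (n <= 0L) NULL else {
      if (genotype == "wt") {
        cls <- sample(c("minus_PE", "minus_PL", "plus"), n, replace = TRUE,
                      prob = c(0.90, 0.05, 0.05))
      } else if (genotype == "dcsm6") {
        cls <- sample(c("minus_PE_up", "minus_PL", "plus"), n, replace = TRUE,
                      prob = c(0.90, 0.05, 0.05))
      } else {
        cls <- sample(c("plus", "minus"), n, replace = TRUE)
      }
      start <- integer(n)
      rng_for <- list(
        minus_PE = c(pe[1], pe[2] - k), minus_PE_up = c(pe[1], pe_split - k),
        minus_PL = c(pl[1], pl[2] - k), plus = c(0, L - k),
        minus = c(0, L - k)
      )
      for (cl in unique(cls)) {
        idx <- cls == cl
        rng <- rng_for[[cl]]
        start[idx] <- sample.int(rng[2] - rng[1] + 1L, sum(idx),
                                 replace = TRUE) + rng[1] - 1L
      }
      strand <- ifelse(cls == "plus", "plus", "minus")
      if (genotype == "cas10hd") strand <- cls  # already plus/minus
      list(cls = cls, start = start, strand = strand)
    }
  })
  if (is.null(draw)) {
    attr(empty, "genotype") <- genotype
    return(empty)
  }
  fwd <- genome_slice(genome, draw$start, draw$start + k)
  seqs <- ifelse(draw$strand == "minus", revcomp(fwd), fwd)
  out <- tibble(
    query_id = sprintf("acq%d", seq_along(seqs)),
    sequence = seqs, start = draw$start, end = draw$start + as.integer(k),
    strand = draw$strand, class = draw$cls
  )
  attr(out, "genotype") <- genotype
  out
}

#' Write spacer sequences as FASTA
#'
#' @param spacers Tibble with id and sequence columns (`query_id`/`spacer_id`
#'   and `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_spacer_fasta <- function(spacers, path) {
  id_col <- intersect(c("query_id", "spacer_id"), names(spacers))[1L]
  if (is.na(id_col)) abort("spacers need a query_id or spacer_id column")
  ss <- Biostrings::DNAStringSet(setNames(spacers$sequence, spacers[[id_col]]))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Simulate sorted-well growth curves and fluorescence
#'
#' Each sorted single-cell well regrows with probability `p_regrow`.
#' Regrowers follow a logistic OD600 curve whose lag is drawn uniformly
#' from `lag_range` (hours); non-regrowers stay at baseline OD. Initial GFP
#' intensity is drawn from two normal distributions, with the non-regrower
#' mean shifted upward by `gfp_shift` (higher phage burden in arrested
#' cells).
#'
#' @param n_replicates Number of replicate plates (default 5).
#' @param wells_per_replicate Wells per plate (default 96).
#' @param p_regrow Regrowth probability (default 0.44).
#' @param lag_range Lag-time range in hours (default `c(10, 15)`).
#' @param times Measurement times in hours (default 0-24 h every 30 min).
#' @param od_baseline,od_max Baseline and plateau OD600.
#' @param od_rate Logistic growth rate per hour.
#' @param od_noise_sd SD of measurement noise added to every OD value.
#' @param gfp_mean Mean initial GFP of regrowing cells.
#' @param gfp_shift Upward shift of the non-regrower mean.
#' @param gfp_sd GFP standard deviation (both groups).
#' @param seed Integer seed (mandatory).
#' @return A list with `od` (long tibble `well_id`, `replicate`, `time_h`,
#'   `od600`) and `meta` (`well_id`, `replicate`, `initial_gfp`,
#'   `regrew_true`, `lag_h`).
#' @export
simulate_wells <- function(n_replicates = 5, wells_per_replicate = 96,
                           p_regrow = 0.44, lag_range = c(10, 15),
                           times = seq(0, 24, by = 0.5),
                           od_baseline = 0.05, od_max = 1.15, od_rate = 1.5,
                           od_noise_sd = 0.004,
                           gfp_mean = 100, gfp_shift = 30, gfp_sd = 15,
                           seed) {
  stopifnot(!missing(seed), p_regrow >= 0, p_regrow <= 1)
  n <- n_replicates * wells_per_replicate
  withr::with_seed(derive_seed(seed, 37L), {
    regrew <- runif(n) < p_regrow
    lag <- runif(n, lag_range[1], lag_range[2])
    gfp <- rnorm(n, mean = ifelse(regrew, gfp_mean, gfp_mean + gfp_shift),
                 sd = gfp_sd)
    meta <- tibble(
      well_id = sprintf("r%d_w%d",
                        rep(seq_len(n_replicates), each = wells_per_replicate),
                        rep(seq_len(wells_per_replicate), n_replicates)),
      replicate = rep(seq_len(n_replicates), each = wells_per_replicate),
      initial_gfp = gfp, regrew_true = regrew, lag_h = ifelse(regrew, lag, NA)
    )
    nt <- length(times)
    tm <- rep(times, times = n)
    well_i <- rep(seq_len(n), each = nt)
    midpoint <- lag + 3  # logistic midpoint sits ~3 h past the lag
    od <- od_baseline +
      ifelse(regrew[well_i],
             (od_max - od_baseline) /
               (1 + exp(-od_rate * (tm - midpoint[well_i]))),
             0)
    od <- pmax(0, od + rnorm(length(od), sd = od_noise_sd))
    list(
      od = tibble(well_id = meta$well_id[well_i],
                  replicate = meta$replicate[well_i],
                  time_h = tm, od600 = od),
      meta = meta
    )
  })
}
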