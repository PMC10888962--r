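test_that("simulated genomes are deterministic and map-unique", {
  g1 <- simulate_genome(length = 3000, pe = c(200, 1500), pl = c(1500, 3000),
                        seed = 7)
  g2 <- simulate_genome(length = 3000, pe = c(200, 1500), pl = c(1500, 3000),
                        seed = 7)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  g3 <- simulate_genome(length = 3000, pe = c(200, 1500), pl = c(1500, 3000),
                        seed = 8)
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
  # no 20-mer occurs twice on either strand, so all spacers map uniquely
  s <- g1$genome$sequence
  kf <- substring(s, 1:(3000 - 19), 20:3000)
  expect_false(any(duplicated(c(kf, rc_chr(kf)))))
  sp <- design_tiled_spacers(g1$genome, 35, 2)
  loc <- locate_spacers(sp$sequence[seq(1, nrow(sp), 37)], g1$genome, 0)
  expect_true(all(loc$status == "unique"))
  expect_equal(loc$start, sp$start[seq(1, nrow(sp), 37)])
})

test_that("tiling a 42 kb genome at stride 2 yields the designed library size", {
  sim <- simulate_genome(seed = 1)
  sp <- design_tiled_spacers(sim$genome, k = 35, stride = 2)
  expect_equal(nrow(sp), 2 * (floor((42000 - 35) / 2) + 1))
  expect_equal(nrow(sp), 41966)
})

test_that("library FASTQ simulation is seeded and multinomially faithful", {
  tmp <- withr::local_tempdir()
  fix <- toy_screen()
  sp <- fix$spacers
  f1 <- file.path(tmp, "a.fastq"); f2 <- file.path(tmp, "b.fastq")
  t1 <- simulate_library_fastq(sp, f1, n_reads = 5000, seed = 55)
  t2 <- simulate_library_fastq(sp, f2, n_reads = 5000, seed = 55)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$true_count, t2$true_count)
  expect_equal(sum(t1$true_count), 5000)
  # expected count n * weight, observed within 4 multinomial sigma for 99%
  t3 <- simulate_library_fastq(sp, file.path(tmp, "c.fastq"),
                               n_reads = 2e5, seed = 56)
  expe <- 2e5 * t3$weight
  sig <- sqrt(2e5 * t3$weight * (1 - t3$weight))
  within <- abs(t3$true_count - expe) <= 4 * sig
  expect_gte(mean(within), 0.99)
  # reads too short for the insert are rejected
  expect_error(simulate_library_fastq(sp, file.path(tmp, "d.fastq"),
                                      n_reads = 10, read_length = 50,
                                      seed = 5),
               "too short")
})

test_that("zero-error amplicon reads are recovered exactly end-to-end", {
  tmp <- withr::local_tempdir()
  fix <- toy_screen()
  fq <- file.path(tmp, "lib.fastq")
  truth <- simulate_library_fastq(fix$spacers, fq, n_reads = 20000, seed = 77)
  ct <- extract_spacer_counts(fq, attr(truth, "repeat_seq"))
  expect_equal(attr(ct, "total_spacers"), 20000L)
  j <- dplyr::full_join(ct, truth, by = "spacer_sequence")
  j$count[is.na(j$count)] <- 0L
  expect_identical(as.integer(j$count), j$true_count)
})

test_that("selection simulation reproduces the screen's rank orderings", {
  tmp <- withr::local_tempdir()
  fix <- toy_screen()
  sp <- fix$spacers
  dr <- "GTTTTAGAGCTATGCTGTTTTGAA"
  t0 <- simulate_library_fastq(sp, file.path(tmp, "t0.fastq"),
                               n_reads = 60000, repeat_seq = dr, seed = 90)
  f0 <- spacer_frequencies(extract_spacer_counts(file.path(tmp, "t0.fastq"), dr))
  run <- function(genotype, seed) {
    tt <- simulate_selection_fastq(
      sp, selection_model(genotype), file.path(tmp, paste0(genotype, ".fastq")),
      n_reads = 60000, repeat_seq = dr, pe_split = fix$pe_split,
      pe_end = fix$pe[2], seed = seed)
    ftab <- spacer_frequencies(
      extract_spacer_counts(file.path(tmp, paste0(genotype, ".fastq")), dr))
    er <- enrichment_ratios(ftab, f0, min_t0_count = 5)
    prof <- position_profile(er, sp)
    cls <- classify_spacers(
      dplyr::rename(prof, start = position), fix$pe_split, fix$pe[2])
    tapply(cls$ratio, cls$class, mean)
  }
  wt <- run("wt", 91)
  expect_gt(wt[["minus_PE_up"]], wt[["minus_PL"]])
  expect_gt(wt[["minus_PE_down"]], wt[["minus_PL"]])
  hd <- run("cas10hd", 92)
  expect_gt(hd[["minus_PL"]], hd[["minus_PE_up"]])
  # neutral model: ratios concentrate around 1
  neutral <- custom_selection_model(
    c("plus_strand", "minus_PE_up", "minus_PE_down", "minus_PL"),
    fitness = rep(1, 4))
  tt <- simulate_selection_fastq(sp, neutral, file.path(tmp, "null.fastq"),
                                 n_reads = 60000, repeat_seq = dr,
                                 pe_split = fix$pe_split, pe_end = fix$pe[2],
                                 seed = 93)
  ftab <- spacer_frequencies(extract_spacer_counts(file.path(tmp, "null.fastq"), dr))
  er <- enrichment_ratios(ftab, f0, min_t0_count = 5)
  expect_equal(mean(er$ratio[er$status != "absent_t0"]), 1, tolerance = 0.1)
  # unclassifiable designs are an error
  expect_error(
    simulate_selection_fastq(sp, neutral[-1, ], file.path(tmp, "x.fastq"),
                             n_reads = 10, repeat_seq = dr, seed = 1),
    "lacks classes")
})

test_that("selection truth tables label classes and dropouts", {
  tmp <- withr::local_tempdir()
  fix <- toy_screen()
  tt <- simulate_selection_fastq(
    fix$spacers, selection_model("dcsm6"), file.path(tmp, "d.fastq"),
    n_reads = 10000, pe_split = fix$pe_split, pe_end = fix$pe[2], seed = 44)
  expect_setequal(unique(tt$class),
                  c("plus_strand", "minus_PE_up", "minus_PE_down", "minus_PL"))
  # dropped lineages never receive reads
  expect_true(all(tt$true_count[!tt$surviving] == 0))
  # dcsm6 drops most late-operon lineages
  pl_drop <- 1 - mean(tt$surviving[tt$class == "minus_PL"])
  expect_gt(pl_drop, 0.8)
  expect_equal(mean(tt$surviving[tt$class == "minus_PE_up"]), 1)
})

test_that("simulated RNA-seq coverage switches the late operon on after 5 min", {
  rna <- simulate_rnaseq_coverage(L = 3000, timepoints = c(5, 15, 30),
                                  pe = c(200, 1500), pl = c(1500, 3000),
                                  seed = 12)
  t5 <- rna[rna$timepoint == 5, ]
  t30 <- rna[rna$timepoint == 30, ]
  pl_idx <- t5$position >= 1500
  pe_idx <- t5$position >= 200 & t5$position < 1500
  expect_equal(sum(t5$coverage[pl_idx]), 0)
  expect_gt(mean(t5$coverage[pe_idx]), 0)
  expect_gt(mean(t30$coverage[pl_idx]), 0)
  # early operon decays 5' -> 3'
  up <- t5$position >= 200 & t5$position < 500
  down <- t5$position >= 1200 & t5$position < 1500
  expect_gt(mean(t5$coverage[up]), mean(t5$coverage[down]))
  expect_identical(rna, simulate_rnaseq_coverage(L = 3000,
                                                 timepoints = c(5, 15, 30),
                                                 pe = c(200, 1500),
                                                 pl = c(1500, 3000), seed = 12))
})

test_that("acquired spacers follow the genotype-specific strand bias", {
  fix <- toy_screen()
  acq <- simulate_acquisition_spacers(
    fix$sim$genome, n = 3000, genotype = "wt", pe = fix$pe, pl = fix$pl,
    pe_split = fix$pe_split, seed = 66)
  expect_equal(nrow(acq), 3000)
  expect_gt(mean(acq$class == "minus_PE"), 0.85)
  # emitted sequences are exact genome substrings / reverse complements
  i <- sample(nrow(acq), 20)
  fwd <- substring(fix$sim$genome$sequence, acq$start[i] + 1, acq$end[i])
  expect_equal(acq$sequence[i],
               ifelse(acq$strand[i] == "minus", rc_chr(fwd), fwd))
  # cas10hd yields ~1% of wild type, uniform
  hd <- simulate_acquisition_spacers(
    fix$sim$genome, n = 3000, genotype = "cas10hd", pe = fix$pe, pl = fix$pl,
    pe_split = fix$pe_split, seed = 66)
  expect_equal(nrow(hd), 30)
  none <- simulate_acquisition_spacers(
    fix$sim$genome, n = 0, genotype = "wt", pe = fix$pe, pl = fix$pl,
    pe_split = fix$pe_split, seed = 66)
  expect_equal(nrow(none), 0)
  expect_identical(acq, simulate_acquisition_spacers(
    fix$sim$genome, n = 3000, genotype = "wt", pe = fix$pe, pl = fix$pl,
    pe_split = fix$pe_split, seed = 66))
})

test_that("simulated wells regrow with the requested probability structure", {
  w0 <- simulate_wells(n_replicates = 2, wells_per_replicate = 24,
                       p_regrow = 0, seed = 3)
  expect_equal(attr(regrowth_fraction(w0$od), "pooled_fraction"), 0)
  w1 <- simulate_wells(n_replicates = 2, wells_per_replicate = 24,
                       p_regrow = 1, seed = 3)
  tt <- time_to_threshold(w1$od)
  expect_true(all(!is.na(tt$t_cross)))
  expect_true(all(tt$t_cross >= 10 & tt$t_cross <= 19))
  # arrested cells carry higher initial GFP on average
  w <- simulate_wells(p_regrow = 0.5, seed = 9)
  cmp <- welch_t(w$meta$initial_gfp[!w$meta$regrew_true],
                 w$meta$initial_gfp[w$meta$regrew_true])
  expect_gt(cmp$statistic, 0)
  expect_lt(cmp$p_value, 0.01)
})
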