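mk_counts <- function(seqs, counts, id = "s") {
  tilescreen:::new_spacer_counts(
    tibble::tibble(spacer_sequence = seqs, count = as.integer(counts)),
    id, sum(counts), sum(counts))
}

test_that("spacer frequencies normalize counts to fractions", {
  one <- spacer_frequencies(mk_counts("AAA", 10))
  expect_equal(one$freq, 1.0)
  two <- spacer_frequencies(mk_counts(c("AAA", "BBB"), c(3, 1)))
  expect_equal(two$freq, c(0.75, 0.25))
  expect_error(spacer_frequencies(mk_counts(character(), integer())), "empty")
  set.seed(3)
  many <- spacer_frequencies(mk_counts(replicate(50, rand_dna(10)),
                                       sample(1:100, 50)))
  expect_equal(sum(many$freq), 1, tolerance = 1e-9)
})

test_that("enrichment ratios divide post-infection by t0 frequencies", {
  f0 <- spacer_frequencies(mk_counts(c("A", "B", "C"), c(10, 10, 20)))
  # identical samples give E = 1 everywhere
  same <- enrichment_ratios(f0, f0, min_t0_count = 5)
  expect_true(all(same$ratio == 1))
  expect_true(all(same$status == "ok"))
  # a 5x frequency jump gives E = 5
  ft <- spacer_frequencies(mk_counts(c("A", "B", "C"), c(50, 10, 20) * 2))
  er <- enrichment_ratios(ft, f0, min_t0_count = 5)
  a <- er[er$spacer_sequence == "A", ]
  expect_equal(a$ratio, (100 / 160) / (10 / 40))
  # spacer absent at t0 is excluded from ratios
  ft2 <- spacer_frequencies(mk_counts(c("A", "D"), c(10, 5)))
  er2 <- enrichment_ratios(ft2, f0, min_t0_count = 5)
  expect_equal(er2$status[er2$spacer_sequence == "D"], "absent_t0")
  expect_true(is.na(er2$ratio[er2$spacer_sequence == "D"]))
  # spacer lost at t keeps ft = 0 and ratio 0
  expect_equal(er2$status[er2$spacer_sequence == "B"], "absent_t")
  expect_equal(er2$ratio[er2$spacer_sequence == "B"], 0)
  # low-count t0 spacers are excluded rather than inflated
  f0_low <- spacer_frequencies(mk_counts(c("A", "B"), c(3, 100)))
  er3 <- enrichment_ratios(f0_low, f0_low, min_t0_count = 5)
  expect_equal(er3$status, c("absent_t0", "ok"))
})

test_that("spacer location agrees with the exhaustive Hamming scan", {
  set.seed(71)
  g <- genome_record(rand_dna(1500))
  # exact plus-strand substring
  q1 <- substr(g$sequence, 1, 35)
  l1 <- locate_spacers(q1, g, 0)
  expect_equal(l1$start, 0L)
  expect_equal(l1$strand, "plus")
  expect_equal(l1$n_hits, 1L)
  # reverse complement locates on the minus strand
  q2 <- rc_chr(substr(g$sequence, 11, 45))
  l2 <- locate_spacers(q2, g, 0)
  expect_equal(l2$start, 10L)
  expect_equal(l2$strand, "minus")
  # oracle equivalence over random queries, exact and with mismatches
  for (mm in c(0, 2)) {
    for (i in 1:25) {
      q <- if (i %% 3 == 0) rand_dna(30) else {
        s <- sample(1400, 1)
        qq <- substr(g$sequence, s, s + 34)
        p <- sample(35, 1)
        substr(qq, p, p) <- sample(c("A", "C", "G", "T"), 1)
        if (i %% 2 == 0) rc_chr(qq) else qq
      }
      want <- oracle_hamming_scan(q, g$sequence, mm)
      got <- locate_spacers(q, g, mm)
      expect_equal(got$n_hits, nrow(want))
      if (nrow(want) == 1) {
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
      }
    }
  }
})

test_that("a planted exact duplication is flagged ambiguous", {
  left <- rand_dna(200)
  dup <- rand_dna(40)
  g <- genome_record(paste0(left, dup, rand_dna(100), dup, rand_dna(50)))
  loc <- locate_spacers(substr(dup, 1, 35), g, 0)
  expect_equal(loc$status, "ambiguous")
  expect_equal(loc$n_hits, 2L)
  none <- locate_spacers(strrep("AC", 18), genome_record(strrep("G", 500)), 0)
  expect_equal(none$status, "unmapped")
})

test_that("position profiles resolve records to strand-split tracks", {
  g <- genome_record(rand_dna(400))
  sp <- design_tiled_spacers(g, 35, 50)
  recs <- tibble::tibble(spacer_sequence = sp$sequence,
                         ratio = 1, ft = 1e-3, count_t0 = 10L)
  prof <- position_profile(recs, sp)
  expect_equal(nrow(prof), nrow(sp))
  expect_true(all(prof$ratio == 1))
  expect_setequal(unique(prof$strand), c("plus", "minus"))
  # one value per designed spacer, positioned at the spacer start
  expect_equal(sort(unique(prof$position)), sort(unique(sp$start)))
  # a spacer never sits in both strand tracks
  expect_equal(anyDuplicated(prof[c("spacer_sequence", "strand")]),
               anyDuplicated(prof$spacer_sequence))
  # records without a ratio are excluded and tallied
  recs$ratio[1] <- NA
  prof2 <- position_profile(recs, sp)
  expect_equal(nrow(prof2), nrow(sp) - 1)
  expect_equal(attr(prof2, "qc")$n_excluded_no_ratio, 1L)
  empty <- position_profile(recs[0, ], sp)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "qc")$n_records, 0L)
})

test_that("region summaries compute mean and n-1 standard deviation", {
  prof <- tibble::tibble(
    spacer_sequence = letters[1:4],
    position = c(10L, 20L, 30L, 150L),
    strand = c("minus", "minus", "minus", "plus"),
    ratio = c(1, 2, 3, 2), ft = c(1e-3, 1e-3, 0, 1e-3),
    detected = c(TRUE, TRUE, FALSE, TRUE)
  )
  regions <- dplyr::bind_rows(region_spec("early", 0, 100),
                              region_spec("late", 100, 200))
  rs <- region_summary(prof, regions)
  em <- rs[rs$region == "early" & rs$strand_matched == "minus", ]
  expect_equal(em$n_spacers, 3L)
  expect_equal(em$mean_enrichment, 2)
  expect_equal(em$sd_enrichment, 1)
  expect_equal(em$n_detected, 2L)
  lp <- rs[rs$region == "late" & rs$strand_matched == "plus", ]
  expect_equal(lp$n_spacers, 1L)
  expect_true(is.na(lp$sd_enrichment))
  expect_error(region_summary(prof, regions, L = 150), "outside genome")
})

test_that("distinct detected spacers are counted per region and strand", {
  g <- genome_record(rand_dna(600))
  sp <- design_tiled_spacers(g, 35, 20)
  regions <- dplyr::bind_rows(region_spec("R1", 0, 300),
                              region_spec("R2", 300, 600))
  all_ct <- mk_counts(sp$sequence, rep(2, nrow(sp)))
  det <- unique_detection_by_region(all_ct, sp, regions)
  per_cell <- sapply(seq_len(nrow(det)), function(i) {
    sum(sp$strand == det$strand_matched[i] & sp$start >= regions$start[match(det$region[i], regions$region)] &
          sp$start < regions$end[match(det$region[i], regions$region)])
  })
  expect_equal(det$n_detected, as.integer(per_cell))
  # dropout confined to R2: only R2 counts fall
  keep <- sp$start < 300
  part_ct <- mk_counts(sp$sequence[keep], rep(1, sum(keep)))
  det2 <- unique_detection_by_region(part_ct, sp, regions)
  expect_equal(det2$n_detected[det2$region == "R1"],
               det$n_detected[det$region == "R1"])
  expect_true(all(det2$n_detected[det2$region == "R2"] == 0))
  empty_det <- unique_detection_by_region(mk_counts(character(), integer()),
                                          sp, regions)
  expect_true(all(empty_det$n_detected == 0))
})

test_that("region BED files round-trip", {
  tmp <- withr::local_tempdir()
  regions <- default_regions(L = 42000, split_pe = TRUE)
  p <- file.path(tmp, "regions.bed")
  write_regions_bed(regions, p)
  back <- read_regions_bed(p)
  expect_equal(back$region, regions$region)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
})
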