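# Family grouping, SSCS/DCS consensus rules and consensus metrics.

test_that("alpha-beta and beta-alpha reads with the same tag pair form one family", {
  rd <- dplyr::bind_rows(
    mk_reads(rep("ACGT", 3), "ab", tag_a = "TTTT", tag_b = "GGGG"),
    mk_reads(rep("ACGT", 3), "ba", tag_a = "GGGG", tag_b = "TTTT")
  )
  rd$read_id <- sprintf("r%02d", 1:6)
  fams <- group_families(rd)
  expect_equal(dplyr::n_distinct(fams$family_id), 1L)
  expect_equal(as.integer(table(fams$orient)), c(3L, 3L))
})

test_that("different fragment coordinates split otherwise identical tags", {
  rd <- dplyr::bind_rows(
    mk_reads(rep("ACGT", 2), "ab", start = 100L),
    mk_reads(rep("ACGT", 2), "ab", start = 104L)
  )
  rd$read_id <- sprintf("r%02d", 1:4)
  expect_equal(dplyr::n_distinct(group_families(rd)$family_id), 2L)
})

test_that("reads missing tags are rejected, counted, never dropped silently", {
  rd <- mk_reads(rep("ACGT", 4), "ab")
  rd$tag_a[2] <- NA
  rd$orient[3] <- "xx"
  fams <- group_families(rd)
  expect_equal(nrow(fams), 2L)
  expect_equal(attr(fams, "n_rejected"), 2L)
  expect_equal(nrow(fams) + nrow(attr(fams, "rejected")), nrow(rd))
})

test_that("SSCS voting follows the strict-majority rule with min 2 reads per strand", {
  # one read on a side: no SSCS for that side
  one <- group_families(mk_reads("ACGT", "ab"))
  expect_equal(nrow(build_sscs(one)), 0L)
  expect_error(build_sscs(one, min_reads = 1L), "min_reads")

  # 3 reads voting A,A,C at base 2: 2/3 > 0.5 -> A
  maj <- group_families(mk_reads(c("AAGT", "AAGT", "ACGT"), "ab"))
  s <- build_sscs(maj, keep_support = TRUE)
  expect_equal(s$seq, "AAGT")
  expect_equal(s$support[[1]], c(3L, 2L, 3L, 3L))

  # 2 reads voting A,C: tie, no strict majority -> N
  tie <- group_families(mk_reads(c("AAGT", "ACGT"), "ab"))
  expect_equal(build_sscs(tie)$seq, "ANGT")
})

test_that("DCS keeps only bases where both strand consensuses agree", {
  rd <- dplyr::bind_rows(
    mk_reads(rep("ACGT", 2), "ab"),
    mk_reads(rep("ACGT", 2), "ba")
  )
  rd$read_id <- sprintf("r%02d", 1:4)
  dcs <- build_dcs(build_sscs(group_families(rd)))
  expect_equal(dcs$seq, "ACGT")
  expect_equal(c(dcs$n_ab, dcs$n_ba), c(2L, 2L))

  rd2 <- dplyr::bind_rows(
    mk_reads(rep("ACGT", 2), "ab"),
    mk_reads(rep("ACTT", 2), "ba")
  )
  rd2$read_id <- sprintf("r%02d", 1:4)
  expect_equal(build_dcs(build_sscs(group_families(rd2)))$seq, "ACNT")

  # a family with only one usable strand contributes no DCS read
  rd3 <- dplyr::bind_rows(mk_reads(rep("ACGT", 3), "ab"), mk_reads("ACGT", "ba"))
  rd3$read_id <- sprintf("r%02d", 1:4)
  expect_equal(nrow(build_dcs(build_sscs(group_families(rd3)))), 0L)

  # explicit pairing rejects mismatched family keys
  a <- build_sscs(group_families(mk_reads(rep("ACGT", 2), "ab", tag_a = "AAAA")))
  b <- build_sscs(group_families(mk_reads(rep("ACGT", 2), "ba", tag_a = "CCCC")))
  expect_error(build_dcs(a, b), "family keys")
})

test_that("single-strand PCR artifacts never reach a duplex consensus base", {
  ref <- one_region_ref()
  cfg <- fast_cfg(n_molecules = 400L, pcr_error_rate = 0.05, seed = 43L)
  rd <- simulate_sample(ref, tibble::tibble(), cfg)
  pcr <- attr(rd, "sim_info")$pcr_errors
  expect_gt(nrow(pcr), 0)
  dcs <- call_consensus(rd)
  mid <- sprintf("m%07d", pcr$molecule)
  # map DCS rows to molecules through the family of any member read
  rd_fam <- group_families(rd)
  rd_fam$molecule <- mol_of(rd_fam$read_id)
  mol_by_fam <- dplyr::distinct(rd_fam[, c("family_id", "molecule")])
  dcs <- dplyr::left_join(dcs, mol_by_fam, by = "family_id")
  for (i in seq_len(nrow(pcr))) {
    row <- dcs[dcs$molecule == mid[i], ]
    if (nrow(row) == 1) {
      off <- pcr$pos[i] - row$start
      expect_true(substr(row$seq, off, off) %in% c(pcr$from[i], "N"))
      expect_false(substr(row$seq, off, off) == pcr$to[i])
    }
  }
})

test_that("consensus output is invariant to read input order", {
  ref <- one_region_ref()
  cfg <- fast_cfg(n_molecules = 150L, seq_error_rate = 2e-3,
                  pcr_error_rate = 2e-3, seed = 47L)
  rd <- simulate_sample(ref, tibble::tibble(), cfg)
  shuffled <- rd[rev(seq_len(nrow(rd))), ]
  expect_equal(
    tibble::as_tibble(call_consensus(rd)),
    tibble::as_tibble(call_consensus(shuffled))
  )
})

test_that("every DCS read is backed by at least two reads on each strand", {
  ref <- one_region_ref()
  rd <- simulate_sample(ref, tibble::tibble(), fast_cfg(n_molecules = 300L, seed = 53L))
  dcs <- call_consensus(rd)
  expect_gt(nrow(dcs), 0)
  expect_true(all(dcs$n_ab >= 2 & dcs$n_ba >= 2))
  # family count equals molecules with >= 1 read surviving strand handling
  ms <- attr(rd, "sim_info")$molecule_stats
  fams <- group_families(rd)
  expect_equal(dplyr::n_distinct(fams$family_id), sum(ms$n_ab + ms$n_ba > 0))
})

test_that("consensus reduction and effective coverage are computed as defined", {
  m <- consensus_metrics(89.8e6, 3.6e6)
  expect_equal(m$reduction_pct, 100 * (1 - 3.6 / 89.8))
  expect_equal(consensus_metrics(1000, 1000)$reduction_pct, 0)
  expect_error(consensus_metrics(0, 0), "positive")
  expect_error(consensus_metrics(10, 20), "outnumber")

  # uniform simulated depth d over the panel -> mean effective coverage d
  ref <- one_region_ref(len = 50L)
  d <- 7L
  rd <- mk_ref_reads(ref, d)
  m2 <- consensus_metrics(rd, rd, ref$panel, coverage_threshold = 5)
  expect_equal(m2$mean_effective_coverage, d)
  expect_equal(m2$pct_target_ge_threshold, 100)
  expect_error(consensus_metrics(rd, rd, ref$panel[0, ]), "panel")
})
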