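# Duplex read simulator: generative-model guarantees and bookkeeping.

test_that("zero error rates and absent variants yield purely reference reads", {
  ref <- tiny_ref()
  rd <- simulate_sample(ref, tibble::tibble(), fast_cfg(n_molecules = 50L))
  expect_gt(nrow(rd), 0)
  wins <- vapply(seq_len(nrow(ref$panel)), function(i) {
    substr(ref$seq, ref$panel$start[i] + 1L, ref$panel$end[i])
  }, character(1))
  expect_true(all(rd$seq %in% wins))
  expect_true(all(rd$ins == ""))
})

test_that("spike-ins at 0% VAF with zero error rates leave no trace", {
  ref <- tiny_ref()
  spk <- dplyr::mutate(sim_spikein_variants(ref, seed = 11L), nominal_vaf = 0)
  rd <- simulate_sample(ref, spk, fast_cfg(n_molecules = 50L))
  pu <- pileup(rd, ref)
  expect_equal(sum(pu$count[pu$class != "ref"]), 0)
})

test_that("a fixed seed gives byte-identical read sets and truth", {
  ref <- tiny_ref()
  spk <- dplyr::mutate(sim_spikein_variants(ref, seed = 11L), nominal_vaf = 1)
  cfg <- fast_cfg(n_molecules = 80L, seq_error_rate = 1e-3, pcr_error_rate = 1e-3)
  rd1 <- simulate_sample(ref, spk, cfg)
  rd2 <- simulate_sample(ref, spk, cfg)
  expect_identical(rd1, rd2)
})

test_that("alt-carrying molecule count matches the binomial expectation", {
  # one SNV at 5% VAF over 2000 molecules: expect 100 +/- 3*sqrt(n p (1-p))
  ref <- one_region_ref()
  snv_pos <- 260L
  base <- substr(ref$seq, snv_pos, snv_pos)
  alt_base <- setdiff(c("A", "C", "G", "T"), base)[1]
  snv <- tibble::tibble(
    variant_id = "V1", chrom = ref$contig, pos = snv_pos,
    ref = base, alt = alt_base, class = "SNV", nominal_vaf = 5
  )
  rd <- simulate_sample(ref, snv, fast_cfg(n_molecules = 2000L, seed = 21L))
  off <- snv_pos - ref$panel$start[1]
  carriers <- unique(mol_of(rd$read_id[substr(rd$seq, off, off) == snv$alt]))
  expect_lt(abs(length(carriers) - 100), 3 * sqrt(2000 * 0.05 * 0.95))
})

test_that("mean family size per strand converges to family_size_mean", {
  ref <- one_region_ref()
  cfg <- fast_cfg(n_molecules = 5000L, family_size_mean = 4,
                  strand_dropout_prob = 0, seed = 31L)
  rd <- simulate_sample(ref, tibble::tibble(), cfg)
  ms <- attr(rd, "sim_info")$molecule_stats
  sizes <- c(ms$n_ab, ms$n_ba) # 10^4 strand families
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 4), 3 * se)
})

test_that("a PCR error reaches every read of its strand family and none of the mate", {
  ref <- one_region_ref()
  cfg <- fast_cfg(n_molecules = 400L, pcr_error_rate = 0.05, seed = 41L)
  rd <- simulate_sample(ref, tibble::tibble(), cfg)
  pcr <- attr(rd, "sim_info")$pcr_errors
  expect_gt(nrow(pcr), 0)
  for (i in seq_len(nrow(pcr))) {
    mid <- sprintf("m%07d", pcr$molecule[i])
    off <- pcr$pos[i] - ref$panel$start[1]
    same <- rd[mol_of(rd$read_id) == mid & rd$orient == pcr$strand[i], ]
    mate <- rd[mol_of(rd$read_id) == mid & rd$orient != pcr$strand[i], ]
    if (nrow(same) > 0) {
      expect_true(all(substr(same$seq, off, off) == pcr$to[i]))
    }
    if (nrow(mate) > 0) {
      expect_true(all(substr(mate$seq, off, off) == pcr$from[i]))
    }
  }
})

test_that("simulate_sample rejects invalid inputs", {
  ref <- tiny_ref()
  outside <- tibble::tibble(
    variant_id = "V1", chrom = ref$contig, pos = 10L,
    ref = substr(ref$seq, 10, 10), alt = "A", class = "SNV", nominal_vaf = 5
  )
  expect_error(simulate_sample(ref, outside, fast_cfg()), "outside the panel")
  expect_error(sim_config(n_molecules = 0), "n_molecules")
  expect_error(sim_config(seq_error_rate = 2), "seq_error_rate")
})

test_that("the validation series has the expected composition", {
  ref <- tiny_ref()
  cfg <- fast_cfg(n_molecules = 20L, seed = 9L)
  single <- make_validation_series(ref, levels = 1, replicates = 1L,
                                   include_wt = FALSE, cfg = cfg)
  expect_equal(nrow(single$manifest), 1L)
  expect_error(
    make_validation_series(ref, replicates = 0L, cfg = cfg), "replicates"
  )
  series <- make_validation_series(ref, cfg = cfg)
  expect_equal(nrow(series$manifest), 11L) # WT + 5 levels x duplicates
  expect_setequal(names(series$reads), series$manifest$sample_id)
  # every sample carries the germline background; level samples the spike-ins
  expect_equal(nrow(attr(series$reads$WT, "truth")), 60L)
  expect_equal(nrow(series$truth$L5_R1), 75L)
})

test_that("in silico dilution thins reads and scales VAF linearly", {
  # 80% VAF source diluted at 10% into wild type: expect ~8% measured VAF
  ref <- one_region_ref(len = 60L)
  n <- 50000L
  src <- mk_ref_reads(ref, n)
  off <- 230L - ref$panel$start[1]
  base <- substr(ref$seq, 230, 230)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  alt_rows <- seq_len(round(0.8 * n))
  src$seq[alt_rows] <- {
    x <- src$seq[alt_rows]
    substr(x, off, off) <- alt
    x
  }
  src$read_id <- paste0("s", src$read_id)
  src$tag_a <- paste0("S", src$tag_a)
  bgd <- mk_ref_reads(ref, n)
  bgd$read_id <- paste0("b", bgd$read_id)

  expect_identical(
    dilute_in_silico(src, bgd, fraction = 0, seed = 3L)$read_id,
    sort(bgd$read_id)
  )
  mix <- dilute_in_silico(src, bgd, fraction = 0.1, seed = 3L)
  vaf <- 100 * mean(substr(mix$seq, off, off) == alt)
  sd_pct <- 100 * sqrt(0.08 * 0.92 / nrow(mix))
  expect_lt(abs(vaf - 8), 3 * sd_pct)
  expect_error(dilute_in_silico(src, bgd, fraction = 1.5), "fraction")
})
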