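# LOB/LOD/LOQ machinery, truth comparison and performance arithmetic.

test_that("LOB estimation: percentile rule with step rounding", {
  expect_equal(estimate_lob(rep(0, 100))$lob, 0)
  # vector engineered so the 95th percentile order statistic is 0.21
  x <- c(seq(0.001, 0.15, length.out = 94), 0.21, rep(0.4, 5))
  brute <- sort(x)[ceiling(0.95 * length(x))] # independent brute-force oracle
  expect_equal(brute, 0.21)
  est <- estimate_lob(x)
  expect_equal(est$raw_estimate, brute)
  expect_equal(est$lob, 0.25) # rounded up to the next 0.05 step
  expect_equal(est$n_positions, 100L)
  expect_error(estimate_lob(rep(0, 59)), "59")
  g <- estimate_lob(x, method = "gaussian")
  expect_equal(g$raw_estimate, mean(x) + 1.645 * sd(x))
})

test_that("truth comparison matches after normalization and counts per class/region", {
  ref <- tiny_ref()
  truth <- dplyr::mutate(sim_spikein_variants(ref, seed = 11L), nominal_vaf = 5)
  calls <- dplyr::mutate(truth, alt_count = 20L, depth = 1000L, vaf = 2,
                         filter = "PASS")
  cc <- compare_to_truth(calls, truth, ref)
  expect_equal(sum(cc$fn), 0L)
  expect_equal(sum(cc$fp), 0L)
  expect_equal(sum(cc$tp), nrow(truth) * 2L) # full panel + hotspot subset

  # a deletion written with redundant padding still matches its trimmed call
  del <- truth[truth$class == "InDel" & nchar(truth$ref) > 1, ][1, ]
  padded <- del
  padded$ref <- paste0(padded$ref, substr(ref$seq, padded$pos + nchar(padded$ref),
                                          padded$pos + nchar(padded$ref)))
  padded$alt <- paste0(padded$alt, substr(padded$ref, nchar(padded$ref), nchar(padded$ref)))
  cc2 <- compare_to_truth(
    dplyr::mutate(padded, filter = "PASS"), del, ref
  )
  expect_equal(sum(cc2$fn), 0L)
  expect_equal(sum(cc2$fp), 0L)
})

test_that("removed calls surface as exactly that many false negatives", {
  ref <- tiny_ref()
  truth <- dplyr::mutate(sim_spikein_variants(ref, seed = 13L), nominal_vaf = 5)
  set.seed(99)
  for (trial in 1:20) {
    drop_n <- sample(0:nrow(truth), 1)
    dropped <- sample(nrow(truth), drop_n)
    calls <- dplyr::mutate(truth[setdiff(seq_len(nrow(truth)), dropped), ],
                           filter = "PASS")
    cc <- compare_to_truth(calls, truth, ref)
    full <- cc[cc$region_set == "full_panel", ]
    expect_equal(sum(full$fn), drop_n)
    expect_equal(sum(full$tp), nrow(truth) - drop_n)
    expect_equal(sum(full$fp), 0L)
  }
})

test_that("sensitivity and PPV arithmetic matches brute-force counting", {
  counts <- tibble::tibble(tp = c(48L, 39L), fn = c(0L, 3L), fp = c(28L, 7L))
  p <- performance(counts)
  expect_equal(p$sensitivity, c(100.0, 92.9))
  expect_equal(p$ppv, c(63.2, 84.8))
  expect_error(performance(tibble::tibble(tp = 0L, fn = 0L, fp = 1L)), "sensitivity")
  expect_error(performance(tibble::tibble(tp = 0L, fn = 1L, fp = 0L)), "ppv")

  # property: agrees with exhaustive counting on random truth/call sets
  set.seed(123)
  for (trial in 1:200) {
    truth_ids <- seq_len(sample(1:40, 1))
    called <- sample(truth_ids, sample(seq_along(truth_ids), 1))
    spurious <- sample(1:10, 1)
    tp <- length(intersect(truth_ids, called))
    fn <- length(setdiff(truth_ids, called))
    p2 <- performance(tibble::tibble(tp = tp, fn = fn, fp = spurious))
    expect_equal(p2$sensitivity_raw, 100 * tp / length(truth_ids))
    expect_equal(p2$ppv_raw, 100 * tp / (tp + spurious))
  }
})

test_that("detection rates are whole-percent averages over replicates", {
  obs <- tibble::tibble(
    class = c(rep("InDel", 14), rep("SNV", 16)),
    level = 0.5,
    detected = c(rep(TRUE, 11), rep(FALSE, 3), rep(TRUE, 16))
  )
  dr <- detection_rate(obs)
  expect_equal(dr$rate[dr$class == "InDel"], 79)
  expect_equal(dr$rate[dr$class == "SNV"], 100)
  none <- detection_rate(tibble::tibble(class = "SNV", level = 1,
                                        detected = rep(FALSE, 5)))
  expect_equal(none$rate, 0)
  expect_error(detection_rate(obs[0, ]), "observations")
})

test_that("LOD is the lowest level reaching the confidence goal", {
  hr <- tibble::tibble(level = c(0.5, 1, 5), detected = c(27L, 30L, 30L),
                       total = 30L)
  lod <- establish_lod(hr, confidence_goal = 90)
  expect_equal(lod$lod, 0.5)
  expect_equal(lod$achieved_confidence, 90)
  expect_true(lod$established)

  lod95 <- suppressMessages(establish_lod(hr, confidence_goal = 95))
  expect_equal(lod95$lod, 1)

  all100 <- establish_lod(tibble::tibble(level = c(0.5, 1), detected = 10L,
                                         total = 10L))
  expect_equal(all100$lod, 0.5)

  none <- establish_lod(tibble::tibble(level = 1, detected = 1L, total = 10L))
  expect_false(none$established)
  expect_true(is.na(none$lod))
})

test_that("level statistics implement the pooled-duplicate formulas", {
  perfect <- tibble::tibble(
    variant_id = rep(c("a", "b"), each = 2), replicate = rep(1:2, 2), vaf = 5
  )
  s0 <- level_stats(perfect, 5)
  expect_equal(s0$trueness, 100)
  expect_equal(s0$repeatability, 100)
  expect_equal(s0$total_error, 0)

  pairs <- tibble::tibble(
    variant_id = rep(c("a", "b"), each = 2),
    replicate = rep(1:2, 2),
    vaf = c(5.0, 5.4, 4.8, 5.2)
  )
  s <- level_stats(pairs, 5)
  expect_equal(s$pooled_sd, sqrt((0.4^2 + 0.4^2) / 4))
  expect_equal(s$cv, 100 * sqrt(0.08) / 5)
  expect_equal(s$repeatability, 100 - 100 * sqrt(0.08) / 5)

  expect_error(level_stats(pairs[1:3, ], 5), "exactly 2")
})

test_that("pooled SD matches a naive per-variant SD computation to 1e-12", {
  set.seed(202)
  for (trial in 1:25) {
    nvar <- sample(3:30, 1)
    nominal <- sample(c(0.5, 1, 5), 1)
    m <- tibble::tibble(
      variant_id = rep(sprintf("v%02d", seq_len(nvar)), each = 2),
      replicate = rep(1:2, nvar),
      vaf = rnorm(2 * nvar, nominal, nominal * 0.1)
    )
    s <- level_stats(m, nominal)
    # two-pass oracle: pool per-variant sample SDs with 1 df each
    per_sd <- vapply(split(m$vaf, m$variant_id), stats::sd, numeric(1))
    oracle <- sqrt(sum(per_sd^2) / nvar)
    expect_equal(s$pooled_sd, oracle, tolerance = 1e-12)
  }
})

test_that("the total error combines bias and twice the CV", {
  # engineer duplicates with mean relative bias 0.1% and CV 8.05%
  nominal <- 5
  d <- nominal * 0.0805 * sqrt(2)
  m <- tibble::tibble(
    variant_id = rep(sprintf("v%d", 1:10), each = 2),
    replicate = rep(1:2, 10),
    vaf = rep(nominal * 1.001, 20) + rep(c(-d / 2, d / 2), 10)
  )
  s <- level_stats(m, nominal)
  expect_equal(s$trueness, 99.9)
  expect_equal(s$cv, 8.05)
  expect_equal(s$total_error, 16.2)
})

test_that("LOQ decision: lowest level meeting both goals", {
  triples <- tibble::tibble(
    nominal_vaf = c(0.5, 1, 5),
    trueness = c(85.0, 92.5, 99.9),
    repeatability = c(34.4, 65.2, 91.9)
  )
  expect_equal(determine_loq(triples)$loq, 5)
  expect_false(determine_loq(triples, precision_goal = 95)$established)
  all_pass <- dplyr::mutate(triples, trueness = 99, repeatability = 95)
  expect_equal(determine_loq(all_pass)$loq, 0.5)
})

test_that("the report enforces lob <= lod <= loq and renders deterministically", {
  lod <- establish_lod(tibble::tibble(level = 0.5, detected = 27L, total = 30L))
  loq <- determine_loq(tibble::tibble(nominal_vaf = 5, trueness = 99.9,
                                      repeatability = 91.9))
  perf <- performance(tibble::tibble(
    region_set = rep(c("full_panel", "hotspot"), each = 2),
    class = rep(c("SNV", "InDel"), 2),
    tp = c(48L, 39L, 48L, 33L), fn = c(0L, 3L, 0L, 3L), fp = c(28L, 7L, 4L, 0L)
  ))
  rep1 <- validation_report(0.25, lod, loq, performance = perf)
  r <- render_report(rep1)
  expect_equal(
    unlist(lapply(r$data$performance, function(x) c(x$sensitivity_pct, x$ppv_pct))),
    c(100.0, 63.2, 92.9, 84.8, 100.0, 92.3, 91.7, 100.0)
  )
  # JSON round trip preserves the cutoffs
  parsed <- jsonlite::fromJSON(r$json, simplifyVector = TRUE)
  expect_equal(parsed$lob$vaf_pct, 0.25)
  expect_equal(parsed$lod$vaf_pct, 0.5)
  expect_equal(parsed$loq$vaf_pct, 5)
  expect_identical(render_report(rep1)$json, r$json)

  expect_error(validation_report(1, lod, loq), "LOB must not exceed")

  g <- glance(rep1)
  expect_equal(g$lob_vaf_pct, 0.25)
  t <- tidy(rep1)
  expect_true(all(c("lob_vaf_pct", "sensitivity_pct") %in% t$metric))
})
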