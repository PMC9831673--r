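# Analytical validation: limit of blank (LOB), limit of detection (LOD),
# limit of quantification (LOQ), sensitivity/PPV against a truth set, and
# the trueness / repeatability / total-error statistics behind the LOQ.

#' Per-position background noise from a wild-type pileup
#'
#' The non-reference allele fraction (percent) at positions expected to be
#' wild type, the raw material for the limit of blank. Positions carrying
#' known variants in any sample should be excluded.
#'
#' @param pu Pileup tibble from [pileup()].
#' @param exclude_pos Integer vector of 1-based positions to drop (known
#'   variant sites).
#' @return Tibble `chrom`, `pos`, `noise_vaf` over covered positions.
#' @export
wt_noise <- function(pu, exclude_pos = integer(0)) {
  per_pos <- summarise(
    group_by(as_tibble(pu), .data$chrom, .data$pos),
    depth = .data$depth[1],
    alt = sum(.data$count[.data$class != "ref"]),
    .groups = "drop"
  )
  per_pos <- filter(per_pos, .data$depth > 0, !(.data$pos %in% exclude_pos))
  mutate(select(per_pos, "chrom", "pos"),
         noise_vaf = 100 * per_pos$alt / per_pos$depth)
}

#' Estimate the limit of blank from blank-sample noise
#'
#' Nonparametric default: the empirical 95th percentile (order statistic at
#' rank `ceiling(0.95 n)`) of the pooled per-position non-reference allele
#' fractions, rounded up to the nearest `step` (0.05 percent VAF). The
#' Gaussian alternative uses mean + 1.645 SD. At least `min_positions`
#' wild-type positions are required.
#'
#' @param noise Numeric vector of noise VAFs in percent, or a [wt_noise()]
#'   tibble (possibly pooled over blanks with [dplyr::bind_rows()]).
#' @param method `"percentile"` (default) or `"gaussian"`.
#' @param step Rounding step in percent VAF.
#' @param min_positions Minimum wild-type positions (default 60).
#' @return One-row tibble: `lob`, `raw_estimate`, `method`, `n_positions`.
#' @export
estimate_lob <- function(noise, method = c("percentile", "gaussian"),
                         step = 0.05, min_positions = 60L) {
  method <- match.arg(method)
  x <- if (is.data.frame(noise)) noise$noise_vaf else noise
  n <- length(x)
  if (n < min_positions) {
    abort(sprintf("only %d wild-type positions available; %d required", n, min_positions))
  }
  raw <- if (method == "percentile") {
    sort(x)[ceiling(0.95 * n)]
  } else {
    mean(x) + 1.645 * sd(x)
  }
  tibble(
    lob = step * ceiling(raw / step - 1e-9),
    raw_estimate = raw,
    method = method,
    n_positions = as.integer(n)
  )
}

#' Compare calls to a truth set
#'
#' Both sides are normalized (left-aligned, minimal representation) and
#' restricted to the trusted regions; a match is an identical
#' `(chrom, pos, ref, alt)` record. Counted separately for SNVs and InDels
#' and for the full panel versus the hotspot subset. Only `PASS` calls
#' count as detections; unmatched `PASS` calls are false positives.
#'
#' @param calls Calls tibble from [call_variants()] (a `filter` column, if
#'   present, is honored).
#' @param truth Truth tibble (`chrom`, `pos`, `ref`, `alt`; a `class`
#'   column is recomputed after normalization).
#' @param ref A [sim_reference()] (or reference sequence string).
#' @param regions Trusted regions tibble (0-based half-open); defaults to
#'   the reference panel.
#' @param hotspots Optional hotspot regions; defaults to the `is_hotspot`
#'   rows of `regions` when that column exists.
#' @return Tibble with one row per (region_set, class): `tp`, `fn`, `fp`.
#' @export
compare_to_truth <- function(calls, truth, ref, regions = NULL, hotspots = NULL) {
  regions <- regions %||% if (inherits(ref, "sim_reference")) ref$panel else NULL
  if (is.null(regions) || nrow(regions) == 0) abort("trusted regions are required")
  if (is.null(hotspots) && "is_hotspot" %in% names(regions) && any(regions$is_hotspot)) {
    hotspots <- regions[regions$is_hotspot, , drop = FALSE]
  }
  calls <- as_tibble(calls)
  if ("filter" %in% names(calls)) calls <- filter(calls, .data$filter == "PASS")
  calls <- normalize_variants(calls[, c("chrom", "pos", "ref", "alt")], ref)
  truth <- normalize_variants(as_tibble(truth)[, c("chrom", "pos", "ref", "alt")], ref)

  in_regions <- function(v, reg) {
    keep <- rep(FALSE, nrow(v))
    for (i in seq_len(nrow(reg))) {
      keep <- keep | (v$chrom == reg$chrom[i] & v$pos > reg$start[i] & v$pos <= reg$end[i])
    }
    v[keep, , drop = FALSE]
  }
  one_set <- function(reg, set_name) {
    tset <- distinct(in_regions(truth, reg))
    cset <- distinct(in_regions(calls, reg))
    keyt <- paste(tset$chrom, tset$pos, tset$ref, tset$alt)
    keyc <- paste(cset$chrom, cset$pos, cset$ref, cset$alt)
    tset$matched <- keyt %in% keyc
    cset$matched <- keyc %in% keyt
    res <- list()
    for (cl in c("SNV", "InDel")) {
      tt <- tset[tset$class == cl, , drop = FALSE]
      cc <- cset[cset$class == cl, , drop = FALSE]
      res[[cl]] <- tibble(
        region_set = set_name, class = cl,
        tp = sum(tt$matched), fn = sum(!tt$matched), fp = sum(!cc$matched)
      )
    }
    bind_rows(res)
  }
  out <- one_set(regions, "full_panel")
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    out <- bind_rows(out, one_set(hotspots, "hotspot"))
  }
  out
}

#' Sensitivity and positive predictive value from confusion counts
#'
#' `sensitivity = 100 * tp / (tp + fn)`, `ppv = 100 * tp / (tp + fp)`,
#' reported at one decimal with the raw values retained.
#'
#' @param counts Tibble with columns `tp`, `fn`, `fp` (one row per class /
#'   region set, e.g. from [compare_to_truth()]).
#' @return `counts` with `sensitivity`, `ppv` (one decimal) and
#'   `sensitivity_raw`, `ppv_raw` appended.
#' @export
performance <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$tp + counts$fn == 0)) {
    abort("sensitivity undefined: tp + fn is zero for at least one row")
  }
  if (any(counts$tp + counts$fp == 0)) {
    abort("ppv undefined: tp + fp is zero for at least one row")
  }
  mutate(counts,
    sensitivity_raw = 100 * .data$tp / (.data$tp + .data$fn),
    ppv_raw = 100 * .data$tp / (.data$tp + .data$fp),
    sensitivity = round(.data$sensitivity_raw, 1),
    ppv = round(.data$ppv_raw, 1)
  )
}

#' Detection rates per variant class and level
#'
#' Percentage of detected observations over all replicates, rounded to the
#' nearest whole percent for reporting.
#'
#' @param observations Tibble with columns `class`, `level` and a logical
#'   `detected` (one row per variant x replicate observation).
#' @return Tibble per (class, level): `detected`, `total`, `rate`
#'   (whole percent) and `rate_raw`.
#' @export
detection_rate <- function(observations) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) abort("no observations")
  out <- summarise(
    group_by(observations, .data$class, .data$level),
    detected = sum(.data$detected), total = n(), .groups = "drop"
  )
  mutate(out,
    rate_raw = 100 * .data$detected / .data$total,
    rate = round(.data$rate_raw)
  )
}

#' Establish the limit of detection from per-level hit rates
#'
#' The LOD is the lowest level whose hit rate reaches the confidence goal;
#' the achieved confidence is the hit rate at that level. Claims at 95%
#' confidence conventionally require at least 60 observations at the
#' candidate level; a message is emitted when that is not met.
#'
#' @param hit_rates Tibble with columns `level` (percent VAF), `detected`,
#'   `total`.
#' @param confidence_goal Required hit rate in percent (default 90).
#' @return One-row tibble: `lod`, `achieved_confidence`, `detected`,
#'   `total`, `confidence_goal`, `established`. When no level qualifies,
#'   `established` is `FALSE` and `lod` is `NA` with the best level's
#'   figures reported.
#' @export
establish_lod <- function(hit_rates, confidence_goal = 90) {
  hr <- arrange(as_tibble(hit_rates), .data$level)
  if (nrow(hr) == 0) abort("no hit rates supplied")
  hr <- mutate(hr, rate = 100 * .data$detected / .data$total)
  ok <- which(hr$rate >= confidence_goal)
  if (length(ok) > 0) {
    i <- ok[which.min(hr$level[ok])]
    if (confidence_goal >= 95 && hr$total[i] < 60) {
      inform(sprintf("only %d observations at the %s%% level; 60 recommended for 95%% claims",
                     hr$total[i], format(hr$level[i])))
    }
    tibble(
      lod = hr$level[i], achieved_confidence = hr$rate[i],
      detected = hr$detected[i], total = hr$total[i],
      confidence_goal = confidence_goal, established = TRUE
    )
  } else {
    i <- which.max(hr$rate)
    tibble(
      lod = NA_real_, achieved_confidence = hr$rate[i],
      detected = hr$detected[i], total = hr$total[i],
      confidence_goal = confidence_goal, established = FALSE
    )
  }
}

#' Trueness, repeatability and total error at one nominal VAF level
#'
#' For duplicate measurements of each variant:
#' mean relative bias is the mean over variants of
#' `100 * (mean(measured) - nominal) / nominal`; trueness is
#' `100 - |mean relative bias|`. The pooled duplicate standard deviation is
#' `sqrt(sum(d_i^2) / (2 n))` with `d_i` the within-variant duplicate
#' difference; the coefficient of variation is
#' `100 * pooled_sd / nominal`, repeatability `100 - CV`, and the total
#' error `|bias| + 2 CV` (Westgard-style combination).
#'
#' @param measured Tibble with columns `variant_id`, `replicate`, `vaf`
#'   (measured VAF in percent); every variant must have exactly two
#'   replicate measurements.
#' @param nominal_vaf Nominal level in percent.
#' @return One-row tibble: `nominal_vaf`, `n_variants`,
#'   `mean_relative_bias`, `trueness`, `pooled_sd`, `cv`, `repeatability`,
#'   `total_error`.
#' @export
level_stats <- function(measured, nominal_vaf) {
  measured <- as_tibble(measured)
  per_var <- summarise(
    group_by(measured, .data$variant_id),
    n = n(), mean_vaf = mean(.data$vaf), d = diff(range(.data$vaf)),
    .groups = "drop"
  )
  if (any(per_var$n != 2)) {
    abort(sprintf("variants without exactly 2 replicate measurements: %s",
                  paste(per_var$variant_id[per_var$n != 2], collapse = ", ")))
  }
  nvar <- nrow(per_var)
  bias_i <- 100 * (per_var$mean_vaf - nominal_vaf) / nominal_vaf
  mrb <- mean(bias_i)
  pooled_sd <- sqrt(sum(per_var$d^2) / (2 * nvar))
  cv <- 100 * pooled_sd / nominal_vaf
  tibble(
    nominal_vaf = nominal_vaf,
    n_variants = nvar,
    mean_relative_bias = mrb,
    trueness = 100 - abs(mrb),
    pooled_sd = pooled_sd,
    cv = cv,
    repeatability = 100 - cv,
    total_error = abs(mrb) + 2 * cv
  )
}

#' Establish the limit of quantification
#'
#' The LOQ is the lowest nominal VAF whose trueness strictly exceeds the
#' trueness goal AND whose repeatability strictly exceeds the precision
#' goal.
#'
#' @param levels Tibble with columns `nominal_vaf`, `trueness`,
#'   `repeatability` (e.g. stacked [level_stats()] rows).
#' @param trueness_goal,precision_goal Acceptance goals in percent
#'   (defaults 90 and 80).
#' @return One-row tibble: `loq`, `trueness_goal`, `precision_goal`,
#'   `established`.
#' @export
determine_loq <- function(levels, trueness_goal = 90, precision_goal = 80) {
  levels <- as_tibble(levels)
  if (nrow(levels) == 0) abort("no levels supplied")
  ok <- levels$trueness > trueness_goal & levels$repeatability > precision_goal
  tibble(
    loq = if (any(ok)) min(levels$nominal_vaf[ok]) else NA_real_,
    trueness_goal = trueness_goal,
    precision_goal = precision_goal,
    established = any(ok)
  )
}
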