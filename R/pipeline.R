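# End-to-end orchestration: simulate the validation series, collapse each
# sample to duplex consensus reads, call variants, and derive the full
# analytical-validation report. Deterministic for a fixed seed.

#' Run the full liquid-biopsy validation pipeline on simulated data
#'
#' Simulates the validation series (wild type once, each spike-in level in
#' replicates), runs consensus building and liquid-biopsy calling on every
#' sample, and assembles the validation report: LOB from wild-type noise,
#' detection rates and LOD from spike-in hits, sensitivity/PPV against the
#' per-sample truth sets, and trueness/repeatability/total error per level
#' feeding the LOQ.
#'
#' @param ref A [sim_reference()].
#' @param cfg A [sim_config()]; `cfg$seed` drives all randomness.
#' @param levels,replicates,spikeins,background Passed to
#'   [make_validation_series()].
#' @param caller A [caller_config()] (liquid-biopsy defaults).
#' @param lod_goal Hit-rate goal in percent for the LOD (default 90).
#' @param trueness_goal,precision_goal LOQ acceptance goals.
#' @param loq_levels Nominal levels eligible for quantification statistics
#'   (defaults to levels strictly above the caller LOB).
#' @param out_dir Optional directory; when given, per-sample VCFs, the
#'   truth files and the rendered report are written there.
#' @return A list of class `duplexlb_run`: `report`
#'   ([validation_report()]), `series`, per-sample `calls`, the spike-in
#'   observation table `observations` (with `detected` and measured `vaf`),
#'   `measured`, `confusion` and per-sample `metrics`.
#' @export
run_validation_pipeline <- function(ref, cfg = sim_config(),
                                    levels = c(0.05, 0.1, 0.5, 1, 5),
                                    replicates = 2L,
                                    spikeins = NULL, background = NULL,
                                    caller = caller_config("lb"),
                                    lod_goal = 90,
                                    trueness_goal = 90, precision_goal = 80,
                                    loq_levels = NULL,
                                    out_dir = NULL) {
  series <- make_validation_series(
    ref, spikeins = spikeins, background = background,
    levels = levels, replicates = replicates, include_wt = TRUE, cfg = cfg
  )
  m <- series$manifest
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  calls <- list()
  metrics <- list()
  confusion <- list()
  wt_noise_tb <- NULL
  truth_pos <- sort(unique(c(series$spikeins$pos, series$background$pos)))
  norm_spk <- normalize_variants(series$spikeins, ref)

  for (i in seq_len(nrow(m))) {
    sid <- m$sample_id[i]
    reads <- series$reads[[sid]]
    dcs <- call_consensus(reads)
    metrics[[sid]] <- consensus_metrics(reads, dcs, ref$panel, mode = caller$mode)
    pu <- pileup(if (caller$mode == "lb") dcs else reads, ref, ref$panel)
    calls[[sid]] <- call_variants(pu, caller)
    if (m$role[i] == "blank") {
      wt_noise_tb <- wt_noise(pu, exclude_pos = truth_pos)
    } else {
      confusion[[sid]] <- mutate(
        compare_to_truth(calls[[sid]], series$truth[[sid]], ref),
        sample_id = sid, level = m$level[i]
      )
    }
    if (!is.null(out_dir)) {
      write_vcf(calls[[sid]], file.path(out_dir, paste0(sid, ".vcf")),
                sample_name = sid, config = caller, ref = ref, seed = m$seed[i])
    }
  }

  # spike-in observations: detection flag and measured VAF per replicate
  obs <- list()
  for (i in which(m$role == "level")) {
    sid <- m$sample_id[i]
    pass <- filter(calls[[sid]], .data$filter == "PASS")
    pass_n <- normalize_variants(pass, ref)
    key_pass <- paste(pass_n$chrom, pass_n$pos, pass_n$ref, pass_n$alt)
    key_spk <- paste(norm_spk$chrom, norm_spk$pos, norm_spk$ref, norm_spk$alt)
    hit <- match(key_spk, key_pass)
    obs[[sid]] <- tibble(
      sample_id = sid, level = m$level[i], replicate = m$replicate[i],
      variant_id = series$spikeins$variant_id, class = series$spikeins$class,
      detected = !is.na(hit),
      vaf = pass$vaf[hit]
    )
  }
  obs <- bind_rows(obs)

  detection <- detection_rate(obs)
  by_level <- summarise(group_by(obs, .data$level),
                        detected = sum(.data$detected), total = n(), .groups = "drop")
  lod <- establish_lod(by_level, confidence_goal = lod_goal)
  lob <- estimate_lob(wt_noise_tb)

  # quantification statistics per level strictly above the LOB
  loq_levels <- loq_levels %||% sort(unique(m$level[m$role == "level" & m$level > caller$lob_vaf]))
  stats <- list()
  for (lv in loq_levels) {
    meas <- filter(obs, .data$level == lv, .data$detected)
    both <- names(which(table(meas$variant_id) == replicates))
    meas <- filter(meas, .data$variant_id %in% both)
    if (nrow(meas) >= 2 && replicates == 2) {
      stats[[as.character(lv)]] <- level_stats(meas, lv)
    }
  }
  stats <- if (length(stats) > 0) bind_rows(stats) else NULL
  loq <- if (!is.null(stats)) {
    determine_loq(stats, trueness_goal = trueness_goal, precision_goal = precision_goal)
  } else NULL

  conf <- NULL
  perf <- NULL
  if (length(confusion) > 0) {
    conf_all <- bind_rows(confusion)
    conf <- summarise(
      group_by(filter(conf_all, .data$level > caller$lob_vaf),
               .data$region_set, .data$class),
      tp = sum(.data$tp), fn = sum(.data$fn), fp = sum(.data$fp), .groups = "drop"
    )
    if (all(conf$tp + conf$fn > 0) && all(conf$tp + conf$fp > 0)) {
      perf <- performance(conf)
    }
  }

  report <- validation_report(
    lob = lob, lod = lod, loq = loq, performance = perf,
    level_stats = stats, detection = detection,
    meta = list(seed = cfg$seed, config_hash = config_hash(unclass(cfg)),
                n_samples = nrow(m))
  )
  if (!is.null(out_dir)) {
    render_report(report, json_path = file.path(out_dir, "validation_report.json"),
                  text_path = file.path(out_dir, "report.txt"))
    write_truth(bind_rows(series$truth[[which(m$role == "level")[1]]]),
                vcf_path = file.path(out_dir, "truth.vcf"),
                tsv_path = file.path(out_dir, "truth.tsv"), ref = ref)
  }
  structure(
    list(report = report, series = series, calls = calls,
         observations = obs, measured = obs[obs$detected, ],
         confusion = conf, metrics = bind_rows(metrics, .id = "sample_id")),
    class = "duplexlb_run"
  )
}

#' @export
print.duplexlb_run <- function(x, ...) {
  cat(sprintf("<duplexlb_run> %d samples\n", nrow(x$series$manifest)))
  print(x$report)
  invisible(x)
}
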