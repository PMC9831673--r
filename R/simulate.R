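# Duplex-tagged read simulation.
#
# Generative model per panel region: `n_molecules` double-stranded fragments
# span the region; each molecule independently carries each variant allele
# with probability nominal_vaf/100. Each molecule yields an alpha-beta and a
# beta-alpha strand family with Poisson(family_size_mean) reads each, either
# of which can drop out entirely. A PCR error hits a molecule strand with
# probability pcr_error_rate and propagates to every read of that strand
# family (the single-strand artifact a duplex consensus must suppress);
# sequencing errors are i.i.d. per read base.

#' Simulate one duplex-tagged sample
#'
#' @param ref A [sim_reference()].
#' @param variants Tibble of variants (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `class`, `nominal_vaf` in percent). May be empty for a pure wild-type
#'   sample. Variants must lie inside panel regions.
#' @param cfg A [sim_config()].
#' @return A tibble of tagged reads (`read_id`, `tag_a`, `tag_b`, `orient`
#'   `"ab"`/`"ba"`, `chrom`, `start`, `end` 0-based half-open, `seq`, `ins`)
#'   sorted by coordinate, with attributes `truth` (the echoed variant
#'   table) and `sim_info` (per-molecule family sizes and the injected PCR
#'   error log, for bookkeeping tests).
#' @export
simulate_sample <- function(ref, variants, cfg = sim_config()) {
  stopifnot(inherits(ref, "sim_reference"), inherits(cfg, "sim_config"))
  variants <- as_tibble(variants)
  if (nrow(variants) > 0) {
    if (any(variants$nominal_vaf < 0 | variants$nominal_vaf > 100)) {
      abort("nominal_vaf must be in [0, 100]")
    }
    ok_ref <- substr(
      rep(ref$seq, nrow(variants)), variants$pos,
      variants$pos + nchar(variants$ref) - 1L
    ) == variants$ref
    if (!all(ok_ref)) {
      abort(sprintf("variant ref allele mismatch at pos %s",
                    paste(variants$pos[!ok_ref], collapse = ", ")))
    }
  }
  panel <- ref$panel
  if (max(panel$end - panel$start) > cfg$read_length) {
    abort("read_length is shorter than the longest panel region")
  }
  if (nrow(variants) > 0) {
    region_of <- vapply(seq_len(nrow(variants)), function(i) {
      p <- variants$pos[i]
      endp <- p + nchar(variants$ref[i]) - 1L
      hit <- which(panel$start < p & endp <= panel$end)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
    if (anyNA(region_of)) {
      abort(sprintf("variants outside the panel at pos %s",
                    paste(variants$pos[is.na(region_of)], collapse = ", ")))
    }
  } else {
    region_of <- integer(0)
  }

  withr::with_seed(cfg$seed, {
    salt <- cfg$seed %% 16384L
    out <- vector("list", nrow(panel))
    stats <- vector("list", nrow(panel))
    pcr_log <- vector("list", nrow(panel))
    mol_offset <- 0L
    for (r in seq_len(nrow(panel))) {
      reg_vars <- variants[which(region_of == r), , drop = FALSE]
      sim <- sim_region(ref, panel$start[r], panel$end[r], reg_vars, cfg,
                        mol_offset, salt)
      out[[r]] <- sim$reads
      stats[[r]] <- sim$stats
      pcr_log[[r]] <- sim$pcr
      mol_offset <- mol_offset + cfg$n_molecules
    }
    reads <- arrange(bind_rows(out), .data$chrom, .data$start, .data$read_id)
    attr(reads, "truth") <- variants
    attr(reads, "sim_info") <- list(
      seed = cfg$seed,
      config_hash = config_hash(unclass(cfg)),
      molecule_stats = bind_rows(stats),
      pcr_errors = bind_rows(pcr_log)
    )
    reads
  })
}

#' @noRd
sim_region <- function(ref, rstart, rend, variants, cfg, mol_offset, salt) {
  len <- rend - rstart
  n <- cfg$n_molecules
  refwin <- strsplit(substr(ref$seq, rstart + 1L, rend), "", fixed = TRUE)[[1]]

  # molecule haplotypes: reference window + Bernoulli(nominal_vaf) edits
  M <- matrix(rep(refwin, each = n), nrow = n)
  ins_entries <- list()
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      carriers <- which(runif(n) < variants$nominal_vaf[i] / 100)
      if (length(carriers) == 0) next
      vref <- variants$ref[i]
      valt <- variants$alt[i]
      col <- variants$pos[i] - rstart
      if (nchar(vref) == nchar(valt)) { # SNV (single base by construction)
        M[carriers, col] <- valt
      } else if (nchar(vref) > nchar(valt)) { # deletion after the anchor
        del <- nchar(vref) - 1L
        M[carriers, (col + 1L):(col + del)] <- "-"
      } else { # insertion after the anchor
        ins_entries[[length(ins_entries) + 1L]] <- tibble(
          mol = carriers, pos = variants$pos[i], seq = substr(valt, 2L, nchar(valt))
        )
      }
    }
  }
  mol_seq <- do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
  ins_mol <- character(n)
  if (length(ins_entries) > 0) {
    ins_tb <- bind_rows(ins_entries)
    ins_tb <- arrange(ins_tb, .data$mol, .data$pos)
    enc <- vapply(
      split(ins_tb, ins_tb$mol),
      function(d) unparse_ins(d$pos, d$seq), character(1)
    )
    ins_mol[as.integer(names(enc))] <- enc
  }

  # per-strand sequences with optional early-PCR substitution
  strand_seq <- list(ab = mol_seq, ba = mol_seq)
  pcr <- list()
  for (strand in c("ab", "ba")) {
    hit <- which(runif(n) < cfg$pcr_error_rate)
    if (length(hit) > 0) {
      off <- sample.int(len, length(hit), replace = TRUE)
      for (j in seq_along(hit)) {
        s <- strand_seq[[strand]][hit[j]]
        cur <- substr(s, off[j], off[j])
        if (cur %in% DNA_BASES) {
          new <- random_other_base(cur)
          substr(s, off[j], off[j]) <- new
          strand_seq[[strand]][hit[j]] <- s
          pcr[[length(pcr) + 1L]] <- tibble(
            molecule = mol_offset + hit[j], strand = strand,
            pos = rstart + off[j], from = cur, to = new
          )
        }
      }
    }
  }

  # read counts per strand family
  k <- list(ab = rpois(n, cfg$family_size_mean), ba = rpois(n, cfg$family_size_mean))
  for (strand in c("ab", "ba")) {
    k[[strand]][runif(n) < cfg$strand_dropout_prob] <- 0L
  }

  mol_idx <- seq_len(n)
  mol_id <- sprintf("m%07d", mol_offset + mol_idx)
  tag_a <- encode_tag(2L * (mol_offset + mol_idx), salt)
  tag_b <- encode_tag(2L * (mol_offset + mol_idx) + 1L, salt)

  strand_reads <- function(strand) {
    kk <- k[[strand]]
    idx <- rep.int(mol_idx, kk)
    if (length(idx) == 0) return(NULL)
    seqs <- rep.int(strand_seq[[strand]], kk)
    seqs <- add_seq_errors(seqs, len, cfg$seq_error_rate)
    # the read observes the tags in strand order: the beta-alpha mate sees
    # the pair swapped
    ta <- rep.int(if (strand == "ab") tag_a else tag_b, kk)
    tb <- rep.int(if (strand == "ab") tag_b else tag_a, kk)
    tibble(
      read_id = sprintf("%s_%s_r%02d", rep.int(mol_id, kk), strand, sequence(kk)),
      tag_a = ta,
      tag_b = tb,
      orient = strand,
      chrom = ref$contig,
      start = rstart,
      end = rend,
      seq = seqs,
      ins = rep.int(ins_mol, kk)
    )
  }
  reads <- bind_rows(strand_reads("ab"), strand_reads("ba"))
  list(
    reads = reads,
    stats = tibble(
      molecule = mol_offset + mol_idx, region_start = rstart,
      n_ab = k$ab, n_ba = k$ba
    ),
    pcr = if (length(pcr) > 0) bind_rows(pcr) else NULL
  )
}

# i.i.d. substitution errors over all read bases (deleted positions are
# skipped: a gap carries no base to mis-read).
#' @noRd
add_seq_errors <- function(seqs, len, rate) {
  n_reads <- length(seqs)
  if (n_reads == 0 || rate <= 0) return(seqs)
  cells <- as.numeric(n_reads) * len
  n_err <- rbinom(1L, size = min(cells, .Machine$integer.max), prob = rate)
  if (n_err == 0) return(seqs)
  cell <- sample.int(cells, n_err)
  read_i <- (cell - 1L) %/% len + 1L
  off <- (cell - 1L) %% len + 1L
  multi <- read_i %in% read_i[duplicated(read_i)]

  # common case, vectorized: reads hit by exactly one error
  if (any(!multi)) {
    ri <- read_i[!multi]; o <- off[!multi]
    cur <- substr(seqs[ri], o, o)
    ok <- cur %in% DNA_BASES # gaps carry no base to mis-read
    if (any(ok)) {
      x <- seqs[ri[ok]]
      substr(x, o[ok], o[ok]) <- random_other_base(cur[ok])
      seqs[ri[ok]] <- x
    }
  }
  if (any(multi)) {
    by_read <- split(off[multi], read_i[multi])
    idxs <- as.integer(names(by_read))
    for (j in seq_along(idxs)) {
      s <- seqs[idxs[j]]
      for (o in by_read[[j]]) {
        cur <- substr(s, o, o)
        if (cur %in% DNA_BASES) substr(s, o, o) <- random_other_base(cur)
      }
      seqs[idxs[j]] <- s
    }
  }
  seqs
}

#' Simulate the analytical-validation sample series
#'
#' Builds the full validation set: one wild-type control plus `replicates`
#' samples per spike-in level. Every sample (including the wild type)
#' carries the germline background variants; level samples additionally
#' carry the spike-ins at the level's nominal VAF.
#'
#' @param ref A [sim_reference()].
#' @param spikeins,background Variant tibbles; defaults are
#'   [sim_spikein_variants()] (8 SNVs + 7 InDels) and
#'   [sim_background_variants()] (59 SNVs + 1 InDel).
#' @param levels Nominal spike-in VAF levels in percent (distinct, > 0).
#' @param replicates Samples per level (default duplicates).
#' @param include_wt Add the wild-type control once.
#' @param cfg A [sim_config()]; per-sample seeds are derived from
#'   `cfg$seed` so the series is reproducible end to end.
#' @return A `duplex_series` list: `manifest` (tibble `sample_id`, `role`,
#'   `level`, `replicate`, `seed`), `reads` and `truth` (named lists per
#'   sample), `spikeins`, `background`.
#' @export
make_validation_series <- function(ref, spikeins = NULL, background = NULL,
                                   levels = c(0.05, 0.1, 0.5, 1, 5),
                                   replicates = 2L, include_wt = TRUE,
                                   cfg = sim_config()) {
  if (replicates < 1) abort("replicates must be >= 1")
  if (anyDuplicated(levels) || any(levels < 0)) {
    abort("levels must be distinct and >= 0")
  }
  if (is.null(spikeins)) spikeins <- sim_spikein_variants(ref, seed = cfg$seed + 101L)
  if (is.null(background)) background <- sim_background_variants(ref, seed = cfg$seed + 202L)

  manifest <- tibble(
    sample_id = character(), role = character(),
    level = numeric(), replicate = integer()
  )
  if (include_wt) {
    manifest <- bind_rows(manifest, tibble(
      sample_id = "WT", role = "blank", level = 0, replicate = 1L
    ))
  }
  for (lv in sort(levels)) {
    for (r in seq_len(replicates)) {
      manifest <- bind_rows(manifest, tibble(
        sample_id = sprintf("L%s_R%d", format(lv, trim = TRUE), r),
        role = "level", level = lv, replicate = as.integer(r)
      ))
    }
  }
  manifest$seed <- cfg$seed + 1000L * seq_len(nrow(manifest))

  reads <- list()
  truth <- list()
  for (i in seq_len(nrow(manifest))) {
    scfg <- cfg
    scfg$seed <- manifest$seed[i]
    vars <- background
    if (manifest$role[i] == "level") {
      vars <- bind_rows(mutate(spikeins, nominal_vaf = manifest$level[i]), background)
    }
    rd <- simulate_sample(ref, vars, scfg)
    reads[[manifest$sample_id[i]]] <- rd
    truth[[manifest$sample_id[i]]] <- attr(rd, "truth")
  }
  structure(
    list(manifest = manifest, reads = reads, truth = truth,
         spikeins = spikeins, background = background, ref = ref, cfg = cfg),
    class = "duplex_series"
  )
}

#' @export
print.duplex_series <- function(x, ...) {
  cat(sprintf(
    "<duplex_series> %d samples (%d levels x %d replicates%s), %d spike-ins, %d background variants\n",
    nrow(x$manifest), dplyr::n_distinct(x$manifest$level[x$manifest$role == "level"]),
    max(x$manifest$replicate), if (any(x$manifest$role == "blank")) " + WT" else "",
    nrow(x$spikeins), nrow(x$background)
  ))
  invisible(x)
}

#' Enumerate variant observations across a validation series
#'
#' One row per (variant, sample) pair: spike-ins appear in every level
#' sample, background variants in every sample including the wild type.
#' `above_lob` flags spike-in observations whose nominal level exceeds the
#' limit of blank.
#'
#' @param series A [make_validation_series()] result.
#' @param lob_vaf Limit of blank in percent VAF (default 0.25).
#' @return Tibble with `sample_id`, `level`, `replicate`, `variant_id`,
#'   `class`, `origin`, `nominal_vaf`, `above_lob`.
#' @export
series_observations <- function(series, lob_vaf = 0.25) {
  stopifnot(inherits(series, "duplex_series"))
  m <- series$manifest
  spk <- tidyr::crossing(
    m[m$role == "level", c("sample_id", "level", "replicate")],
    series$spikeins[, c("variant_id", "class")]
  )
  spk <- mutate(spk, origin = "spike_in", nominal_vaf = .data$level,
                above_lob = .data$level > lob_vaf)
  bgd <- tidyr::crossing(
    m[, c("sample_id", "level", "replicate")],
    series$background[, c("variant_id", "class", "nominal_vaf")]
  )
  bgd <- mutate(bgd, origin = "background", above_lob = TRUE)
  arrange(bind_rows(spk, bgd), .data$sample_id, .data$variant_id)
}

#' Mix two read sets in silico
#'
#' Emulates in silico dilution of a characterized sample into a wild-type
#' background: each sample read is kept with probability `fraction`, each
#' background read with probability `1 - fraction`, so a variant at VAF v in
#' the source is expected at `fraction * v` in the mixture (read-count
#' weighted, for equal source depths).
#'
#' @param sample_reads,background_reads Read tibbles aligned to the same
#'   reference (simulated with different seeds so duplex tags cannot
#'   collide).
#' @param fraction Sample proportion in `[0, 1]`.
#' @param seed Integer seed for the thinning draws.
#' @return The mixed read tibble, coordinate sorted.
#' @export
dilute_in_silico <- function(sample_reads, background_reads, fraction, seed = 1L) {
  assert_fraction(fraction, "fraction")
  if (!setequal(unique(sample_reads$chrom), unique(background_reads$chrom))) {
    abort("read sets must be aligned to the same reference contigs")
  }
  withr::with_seed(seed, {
    keep_s <- runif(nrow(sample_reads)) < fraction
    keep_b <- runif(nrow(background_reads)) < 1 - fraction
    s <- sample_reads[keep_s, , drop = FALSE]
    b <- background_reads[keep_b, , drop = FALSE]
    key <- function(d) paste(pmin(d$tag_a, d$tag_b), pmax(d$tag_a, d$tag_b),
                             d$chrom, d$start, d$end)
    if (nrow(s) > 0 && nrow(b) > 0 && length(intersect(key(s), key(b))) > 0) {
      abort("duplex tag collision between the two read sets; simulate them with different seeds")
    }
    arrange(bind_rows(s, b), .data$chrom, .data$start, .data$read_id)
  })
}
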