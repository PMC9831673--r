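# Synthetic reference, panel and variant-set constructors.
#
# The bundled reference stands in for a targeted hybrid-capture panel: a
# single synthetic contig carrying a small set of non-overlapping target
# regions (0-based half-open intervals), one of which is flagged as a
# cancer-hotspot reporting subset. Spike-in variants are placed in the
# hotspot region (mimicking commercial ctDNA reference material), germline
# background variants in the remaining target regions (mimicking a
# well-characterized genomic background at 50%/100% VAF).

#' Build a synthetic reference with a target panel
#'
#' @param seed Integer seed; fixes the reference sequence.
#' @param contig Contig name.
#' @param length Contig length in bp.
#' @param panel Optional tibble with columns `chrom`, `start`, `end`,
#'   `label`, `is_hotspot` (0-based half-open intervals). Defaults to a
#'   400 bp hotspot region and a 990 bp background region.
#' @return An object of class `sim_reference`: a list with `contig`, `seq`
#'   (a plain DNA string) and `panel` (a tibble).
#' @export
sim_reference <- function(seed = 1L, contig = "chrS", length = 2000L,
                          panel = NULL) {
  if (length < 1 || length > 2e5) {
    abort("reference length must be between 1 bp and 200 kb")
  }
  seq <- withr::with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  })
  if (is.null(panel)) {
    panel <- tibble(
      chrom = contig,
      start = c(300L, 800L),
      end = c(700L, 1790L),
      label = c("hotspot_1", "background_1"),
      is_hotspot = c(TRUE, FALSE)
    )
  }
  panel <- validate_panel(as_tibble(panel), contig, length)
  structure(
    list(contig = contig, seq = seq, panel = panel),
    class = "sim_reference"
  )
}

#' @noRd
validate_panel <- function(panel, contig, len) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(panel))) {
    abort("panel needs columns chrom, start, end")
  }
  if (!"label" %in% names(panel)) panel$label <- sprintf("region_%d", seq_len(nrow(panel)))
  if (!"is_hotspot" %in% names(panel)) panel$is_hotspot <- FALSE
  panel <- arrange(panel, .data$chrom, .data$start)
  if (any(panel$start >= panel$end)) abort("panel intervals must satisfy start < end")
  if (any(panel$chrom != contig)) abort("panel intervals must lie on the reference contig")
  if (any(panel$start < 0) || any(panel$end > len)) {
    abort("panel intervals must lie within the contig")
  }
  if (nrow(panel) > 1 && any(panel$start[-1] < panel$end[-nrow(panel)])) {
    abort("panel intervals must be non-overlapping")
  }
  panel
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf(
    "<sim_reference> contig %s (%d bp), %d target regions (%d bp, %d hotspot bp)\n",
    x$contig, nchar(x$seq), nrow(x$panel), sum(x$panel$end - x$panel$start),
    sum((x$panel$end - x$panel$start)[x$panel$is_hotspot])
  ))
  invisible(x)
}

#' @noRd
ref_base <- function(ref, pos) {
  substr(rep(ref$seq, length.out = length(pos)), pos, pos)
}

# Candidate anchor slots inside regions, spaced so that events up to 12 bp
# (anchor + <=10 bp indel + margin) can never overlap or touch region edges.
#' @noRd
variant_slots <- function(regions, spacing = 13L, margin = 12L) {
  slots <- purrr::pmap(
    list(regions$start, regions$end),
    function(s, e) {
      lo <- s + margin + 1L # 1-based anchor
      hi <- e - margin
      if (hi < lo) integer(0) else seq.int(lo, hi, by = spacing)
    }
  )
  unlist(slots, use.names = FALSE)
}

#' @noRd
make_variants <- function(ref, regions, n_snv, n_indel, seed, prefix,
                          max_indel = 6L, indel_ins_frac = 0.45) {
  slots <- variant_slots(regions)
  n <- n_snv + n_indel
  if (length(slots) < n) {
    abort(sprintf("only %d variant slots available for %d variants", length(slots), n))
  }
  withr::with_seed(seed, {
    pos <- sort(sample(slots, n))
    is_indel <- rep(FALSE, n)
    is_indel[sample.int(n, n_indel)] <- TRUE
    refs <- alts <- character(n)
    for (i in seq_len(n)) {
      anchor <- ref_base(ref, pos[i])
      if (!is_indel[i]) {
        refs[i] <- anchor
        alts[i] <- random_other_base(anchor)
      } else if (runif(1) < indel_ins_frac) {
        len <- sample.int(max_indel, 1)
        refs[i] <- anchor
        alts[i] <- paste0(anchor, paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""))
      } else {
        len <- sample.int(max_indel, 1)
        refs[i] <- paste0(anchor, substr(ref$seq, pos[i] + 1, pos[i] + len))
        alts[i] <- anchor
      }
    }
    tibble(
      variant_id = sprintf("%s%02d", prefix, seq_len(n)),
      chrom = ref$contig,
      pos = as.integer(pos),
      ref = refs,
      alt = alts,
      class = if_else(is_indel, "InDel", "SNV")
    )
  })
}

#' Spike-in variant set for the validation series
#'
#' Places SNV and InDel spike-ins in the hotspot regions of the panel,
#' mirroring commercial ctDNA reference material (default 8 SNVs and
#' 7 InDels). `nominal_vaf` is left `NA`; [make_validation_series()] sets it
#' per dilution level.
#'
#' @param ref A [sim_reference()].
#' @param n_snv,n_indel Number of SNV / InDel spike-ins.
#' @param seed Integer seed.
#' @return Tibble with `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `class`, `nominal_vaf`.
#' @export
sim_spikein_variants <- function(ref, n_snv = 8L, n_indel = 7L, seed = 101L) {
  regions <- filter(ref$panel, .data$is_hotspot)
  if (nrow(regions) == 0) abort("panel has no hotspot regions for spike-ins")
  v <- make_variants(ref, regions, n_snv, n_indel, seed, "SPK")
  mutate(v, nominal_vaf = NA_real_)
}

#' Germline background variant set
#'
#' Heterozygous/homozygous background variants (nominal VAF 50% or 100%)
#' standing in for a well-characterized germline genome present in every
#' validation sample including the wild-type control. Defaults: 59 SNVs and
#' 1 InDel.
#'
#' @inheritParams sim_spikein_variants
#' @param hom_frac Probability that a background variant is homozygous.
#' @export
sim_background_variants <- function(ref, n_snv = 59L, n_indel = 1L,
                                    hom_frac = 0.3, seed = 202L) {
  regions <- filter(ref$panel, !.data$is_hotspot)
  if (nrow(regions) == 0) abort("panel has no non-hotspot regions for background variants")
  v <- make_variants(ref, regions, n_snv, n_indel, seed, "BGD")
  withr::with_seed(seed + 1L, {
    mutate(v, nominal_vaf = if_else(runif(n()) < hom_frac, 100, 50))
  })
}

#' Simulator configuration
#'
#' Statistical parameters of the duplex read simulator. Defaults describe
#' the study conditions the validation emulates: ~10,000 input molecules per
#' target position (roughly 33 ng of cfDNA in genome equivalents, enough to
#' make a 0.5% VAF variant detectable under duplex rules), a mean of 4 PCR
#' copies per strand family, 5% probability of losing a strand entirely,
#' and per-base sequencing / per-molecule-strand PCR error rates of 1e-3.
#'
#' @param n_molecules Original double-stranded molecules per covered
#'   position (each panel region is covered by this many spanning fragments).
#' @param family_size_mean Poisson mean of reads per strand family.
#' @param strand_dropout_prob Probability that a strand family yields no
#'   reads at all (in addition to Poisson zeros).
#' @param seq_error_rate Per read base substitution error rate.
#' @param pcr_error_rate Probability that a molecule strand acquires one
#'   early-PCR substitution that propagates to all reads of that strand.
#' @param read_length Maximum read length; reads span their fragment, so
#'   this must be at least the longest panel region.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_molecules = 10000L, family_size_mean = 4,
                       strand_dropout_prob = 0.05, seq_error_rate = 1e-3,
                       pcr_error_rate = 1e-3, read_length = 1000L,
                       seed = 1L) {
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  if (family_size_mean < 0) abort("family_size_mean must be >= 0")
  assert_fraction(strand_dropout_prob, "strand_dropout_prob")
  assert_fraction(seq_error_rate, "seq_error_rate")
  assert_fraction(pcr_error_rate, "pcr_error_rate")
  if (read_length < 1) abort("read_length must be >= 1")
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      family_size_mean = family_size_mean,
      strand_dropout_prob = strand_dropout_prob,
      seq_error_rate = seq_error_rate,
      pcr_error_rate = pcr_error_rate,
      read_length = as.integer(read_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}
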