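# Pileup construction and dual-mode variant calling.
#
# Liquid-biopsy (LB) mode operates on duplex consensus reads with a limit
# of blank (LOB) of 0.25% VAF and a minimum of eight supporting consensus
# reads; tissue mode operates on raw reads with a 5% LOB and no read-count
# rule. "Above the LOB" is a strict inequality throughout. N consensus
# bases carry no allele information and are excluded from both the allele
# counts and the depth (they are tallied separately in `n_count`).

#' Caller configuration
#'
#' @param mode `"lb"` (duplex consensus pileups) or `"tissue"` (raw read
#'   pileups).
#' @param lob_vaf Limit of blank in percent VAF; a call must be strictly
#'   above it. Defaults: 0.25 (lb), 5 (tissue).
#' @param min_alt_reads Minimum alternate-supporting reads. Defaults: 8
#'   (lb), 0 (tissue).
#' @return A `caller_config` list.
#' @export
caller_config <- function(mode = c("lb", "tissue"), lob_vaf = NULL,
                          min_alt_reads = NULL) {
  mode <- match.arg(mode)
  lob_vaf <- lob_vaf %||% if (mode == "lb") 0.25 else 5
  min_alt_reads <- min_alt_reads %||% if (mode == "lb") 8L else 0L
  if (lob_vaf < 0 || lob_vaf > 100) abort("lob_vaf must be in [0, 100]")
  if (min_alt_reads < 0) abort("min_alt_reads must be >= 0")
  structure(
    list(mode = mode, lob_vaf = lob_vaf, min_alt_reads = as.integer(min_alt_reads)),
    class = "caller_config"
  )
}

#' Pileup over the target panel
#'
#' Tallies, for every panel base, the reads (raw or consensus) supporting
#' each allele. Substitution alleles are counted per column; InDel alleles
#' are anchored at the base preceding the event and left-aligned by
#' construction. Positions are 1-based in the output.
#'
#' @param reads Read tibble (raw reads or DCS reads; both carry the aligned
#'   `seq`/`ins` representation).
#' @param ref A [sim_reference()].
#' @param panel Panel tibble (0-based half-open); must be non-empty.
#' @return Tibble with one row per (position, allele): `chrom`, `pos`,
#'   `ref` (reference allele string), `allele` (observed allele; equals
#'   `ref` for the reference row present at every panel base), `class`
#'   (`"ref"`, `"SNV"` or `"InDel"`), `count`, `depth` (non-N reads
#'   covering the position) and `n_count`. Reads on contigs absent from the
#'   reference are routed to the `rejected` attribute.
#' @export
pileup <- function(reads, ref, panel = NULL) {
  stopifnot(inherits(ref, "sim_reference"))
  panel <- panel %||% ref$panel
  if (is.null(panel) || nrow(panel) == 0) abort("panel must be non-empty")
  reads <- as_tibble(reads)
  known <- reads$chrom == ref$contig
  rejected <- reads[!known, , drop = FALSE]
  reads <- reads[known, , drop = FALSE]

  # per-position tallies over all panel bases
  panel_pos <- unlist(purrr::map2(panel$start + 1L, panel$end, seq.int), use.names = FALSE)
  npos <- length(panel_pos)
  pos_index <- integer(max(c(panel_pos, 1L)))
  pos_index[panel_pos] <- seq_len(npos)
  codes <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L, gap = 45L)
  tal <- matrix(0L, nrow = npos, ncol = length(codes),
                dimnames = list(NULL, names(codes)))
  indel_counts <- list()

  if (nrow(reads) > 0) {
    cohort <- paste(reads$start, reads$end)
    for (co in unique(cohort)) {
      sub <- reads[cohort == co, , drop = FALSE]
      s0 <- sub$start[1]; e0 <- sub$end[1]
      len <- e0 - s0
      M <- vapply(sub$seq, utf8ToInt, integer(len), USE.NAMES = FALSE)
      if (is.null(dim(M))) M <- matrix(M, nrow = len)
      cohort_pos <- (s0 + 1L):e0
      in_panel <- cohort_pos <= length(pos_index) & pos_index[pmin(cohort_pos, length(pos_index))] > 0L
      rows <- pos_index[cohort_pos[in_panel]]
      for (sym in names(codes)) {
        tal[rows, sym] <- tal[rows, sym] + rowSums(M[in_panel, , drop = FALSE] == codes[[sym]])
      }
      # deletion events: one per gap run, anchored at the preceding base
      with_gap <- grep("-", sub$seq, fixed = TRUE)
      if (length(with_gap) > 0) {
        runs <- gregexpr("-+", sub$seq[with_gap])
        for (j in seq_along(with_gap)) {
          st <- as.integer(runs[[j]])
          ln <- attr(runs[[j]], "match.length")
          for (q in seq_along(st)) {
            anchor <- s0 + st[q] - 1L # 1-based ref pos of base before the run
            keyv <- sprintf("D|%d|%d", anchor, ln[q])
            indel_counts[[keyv]] <- (indel_counts[[keyv]] %||% 0L) + 1L
          }
        }
      }
      ins_tb <- parse_ins(sub$ins)
      if (length(ins_tb$pos) > 0) {
        keys <- sprintf("I|%d|%s", ins_tb$pos, ins_tb$seq)
        for (keyv in keys) indel_counts[[keyv]] <- (indel_counts[[keyv]] %||% 0L) + 1L
      }
    }
  }

  depth <- as.integer(rowSums(tal[, c("A", "C", "G", "T", "gap"), drop = FALSE]))
  n_count <- tal[, "N"]
  ref_chars <- substr(rep(ref$seq, npos), panel_pos, panel_pos)

  rows_out <- list()
  rows_out$ref <- tibble(
    chrom = ref$contig, pos = panel_pos, ref = ref_chars, allele = ref_chars,
    class = "ref",
    count = as.integer(tal[cbind(seq_len(npos), match(ref_chars, names(codes)))]),
    depth = depth, n_count = as.integer(n_count)
  )
  for (base in DNA_BASES) {
    hit <- which(ref_chars != base & tal[, base] > 0L)
    if (length(hit) > 0) {
      rows_out[[paste0("snv_", base)]] <- tibble(
        chrom = ref$contig, pos = panel_pos[hit], ref = ref_chars[hit],
        allele = base, class = "SNV",
        count = as.integer(unname(tal[hit, base])),
        depth = depth[hit], n_count = as.integer(n_count[hit])
      )
    }
  }
  if (length(indel_counts) > 0) {
    keys <- names(indel_counts)
    parts <- strsplit(keys, "|", fixed = TRUE)
    typ <- vapply(parts, `[[`, character(1), 1)
    apos <- as.integer(vapply(parts, `[[`, character(1), 2))
    payload <- vapply(parts, `[[`, character(1), 3)
    anchor_char <- substr(rep(ref$seq, length(apos)), apos, apos)
    del_len <- rep(0L, length(apos))
    del_len[typ == "D"] <- as.integer(payload[typ == "D"])
    ref_all <- substr(rep(ref$seq, length(apos)), apos, apos + del_len)
    alt_all <- ifelse(typ == "D", anchor_char, paste0(anchor_char, payload))
    idx <- ifelse(apos <= length(pos_index), pos_index[pmin(apos, length(pos_index))], 0L)
    keep <- idx > 0L
    rows_out$indel <- tibble(
      chrom = ref$contig, pos = apos[keep], ref = ref_all[keep],
      allele = alt_all[keep], class = "InDel",
      count = as.integer(unlist(indel_counts, use.names = FALSE))[keep],
      depth = depth[idx[keep]], n_count = as.integer(n_count[idx[keep]])
    )
  }
  out <- arrange(bind_rows(rows_out), .data$pos, .data$class, .data$allele)
  attr(out, "rejected") <- rejected
  out
}

#' Call variants from pileup columns
#'
#' Emits one candidate call per non-reference allele with positive count
#' and assigns the filter: `PASS` requires the VAF strictly above the limit
#' of blank AND at least `min_alt_reads` supporting reads; a call failing
#' the LOB is `below_LOB`, one failing only the read-count rule is
#' `low_support`.
#'
#' @param pu Pileup tibble from [pileup()].
#' @param config A [caller_config()].
#' @return Calls tibble: `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `alt_count`, `depth`, `vaf` (percent), `filter`, sorted by position.
#' @export
call_variants <- function(pu, config = caller_config("lb")) {
  stopifnot(inherits(config, "caller_config"))
  calls <- filter(as_tibble(pu), .data$class %in% c("SNV", "InDel"), .data$count > 0)
  calls <- mutate(calls,
    alt = .data$allele,
    alt_count = as.integer(.data$count),
    vaf = if_else(.data$depth > 0, 100 * .data$count / .data$depth, NA_real_),
    filter = dplyr::case_when(
      is.na(vaf) | vaf <= config$lob_vaf ~ "below_LOB",
      alt_count < config$min_alt_reads ~ "low_support",
      TRUE ~ "PASS"
    )
  )
  calls <- select(calls, "chrom", "pos", "ref", "alt", "class",
                  "alt_count", "depth", "vaf", "filter")
  arrange(calls, .data$chrom, .data$pos, .data$alt)
}
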