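# Strand-family grouping and SSCS/DCS consensus building.
#
# A family key is the canonicalized duplex tag pair plus fragment
# coordinates: (min(tag_a, tag_b), max(tag_a, tag_b), chrom, start, end).
# The alpha-beta read and its beta-alpha mate observe the same tags in
# swapped order, so lexicographic canonicalization collides both strand
# families of one molecule onto a single key while the per-read orientation
# keeps them apart within it.

#' Group duplex-tagged reads into strand families
#'
#' @param reads Read tibble as produced by [simulate_sample()] or
#'   [read_reads_sam()].
#' @return The reads with family key columns (`tag_lo`, `tag_hi`,
#'   `family_id`) added, ordered deterministically by family, orientation
#'   and read id. Reads missing tag or orientation annotations are routed
#'   to the `rejected` attribute (a tibble), never silently dropped;
#'   `attr(, "n_rejected")` carries the count.
#' @export
group_families <- function(reads) {
  reads <- as_tibble(reads)
  need <- c("read_id", "tag_a", "tag_b", "orient", "chrom", "start", "end", "seq")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols) > 0) {
    abort(sprintf("reads are missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(reads$tag_a) | !nzchar(reads$tag_a) |
    is.na(reads$tag_b) | !nzchar(reads$tag_b) |
    !(reads$orient %in% c("ab", "ba"))
  rejected <- reads[bad, , drop = FALSE]
  fams <- reads[!bad, , drop = FALSE]
  fams <- mutate(fams,
    tag_lo = pmin(.data$tag_a, .data$tag_b),
    tag_hi = pmax(.data$tag_a, .data$tag_b),
    family_id = paste(.data$tag_lo, .data$tag_hi, .data$chrom,
                      .data$start, .data$end, sep = "|")
  )
  fams <- arrange(fams, .data$family_id, .data$orient, .data$read_id)
  attr(fams, "rejected") <- rejected
  attr(fams, "n_rejected") <- nrow(rejected)
  fams
}

#' Build single-strand consensus reads (SSCS)
#'
#' Per strand family with at least `min_reads` members, the consensus call
#' at each base is the allele (A/C/G/T or the deletion gap) supported by
#' strictly more than `majority_frac` of the family's reads; anything else,
#' including ties, becomes N. Insertion alleles at an anchor are voted the
#' same way against the no-insertion alternative. Strand sides below
#' `min_reads` simply yield no SSCS.
#'
#' @param fams Output of [group_families()].
#' @param min_reads Minimum reads per strand family (>= 2).
#' @param majority_frac Vote fraction that must be strictly exceeded.
#' @param keep_support Also return per-base support counts (list column).
#' @return Tibble with one row per (family, orientation): key columns,
#'   `orient`, consensus `seq`/`ins` and `n_reads`.
#' @export
build_sscs <- function(fams, min_reads = 2L, majority_frac = 0.5,
                       keep_support = FALSE) {
  if (min_reads < 2) abort("min_reads must be >= 2 (both PCR copies of a strand are required)")
  if (!"family_id" %in% names(fams)) fams <- group_families(fams)
  fams <- arrange(fams, .data$family_id, .data$orient, .data$read_id)
  gid <- paste(fams$family_id, fams$orient, sep = "/")
  r <- rle(gid)
  keep_grp <- r$lengths >= min_reads
  if (!any(keep_grp)) {
    return(tibble(
      family_id = character(), tag_lo = character(), tag_hi = character(),
      chrom = character(), start = integer(), end = integer(),
      orient = character(), seq = character(), ins = character(),
      n_reads = integer()
    ))
  }
  grp_end <- cumsum(r$lengths)
  grp_start <- grp_end - r$lengths + 1L
  sel_rows <- unlist(purrr::map2(grp_start[keep_grp], grp_end[keep_grp], seq.int),
                     use.names = FALSE)
  sub <- fams[sel_rows, , drop = FALSE]
  sizes <- r$lengths[keep_grp]
  exp_len <- sub$end - sub$start
  if (any(nchar(sub$seq) != exp_len)) {
    abort("read seq length does not match fragment coordinates")
  }
  vote <- cpp_sscs_vote(sub$seq, sizes, majority_frac, keep_support)
  first_of_grp <- cumsum(sizes) - sizes + 1L
  out <- sub[first_of_grp, c("family_id", "tag_lo", "tag_hi", "chrom",
                             "start", "end", "orient"), drop = FALSE]
  out$seq <- as.character(vote$call)
  out$ins <- ""
  out$n_reads <- sizes
  if (keep_support) out$support <- vote$support

  # insertion vote (rare path: only families containing annotated insertions)
  if (any(nzchar(sub$ins))) {
    grp_of_row <- rep.int(seq_along(sizes), sizes)
    all_ins <- parse_ins(sub$ins) # parsed once for the whole batch
    ins_grp <- grp_of_row[all_ins$row]
    for (sel in split(seq_along(ins_grp), ins_grp)) {
      g <- ins_grp[sel[1]]
      res <- vote_insertions(all_ins$pos[sel], all_ins$seq[sel],
                             sizes[g], majority_frac)
      out$ins[g] <- unparse_ins(res$keep_pos, res$keep_seq)
      if (length(res$n_pos) > 0) { # unresolved anchors: mask the anchor base
        offs <- res$n_pos - out$start[g]
        s <- out$seq[g]
        for (o in offs) substr(s, o, o) <- "N"
        out$seq[g] <- s
      }
    }
  }
  out
}

# Vote insertion alleles at each anchor: an insertion sequence wins if
# strictly more than majority_frac of the family's k reads carry exactly
# it; "no insertion" wins likewise; otherwise the anchor is unresolved.
#' @noRd
vote_insertions <- function(pos, seq, k, majority_frac) {
  keep_pos <- integer(0); keep_seq <- character(0); n_pos <- integer(0)
  for (p in unique(pos)) {
    at <- seq[pos == p]
    cnt <- table(at)
    none <- k - length(at)
    best <- which.max(cnt)
    if (cnt[best] > majority_frac * k) {
      keep_pos <- c(keep_pos, p)
      keep_seq <- c(keep_seq, names(cnt)[best])
    } else if (!(none > majority_frac * k)) {
      n_pos <- c(n_pos, p)
    }
  }
  list(keep_pos = keep_pos, keep_seq = keep_seq, n_pos = n_pos)
}

#' Combine strand consensuses into duplex consensus reads (DCS)
#'
#' A duplex consensus base is emitted only where the alpha-beta and
#' beta-alpha single-strand consensuses agree on a non-N call; disagreement
#' (including one-sided insertions) becomes N. Families lacking either
#' strand consensus produce no DCS read, so every DCS read is backed by at
#' least two raw reads on each strand.
#'
#' @param sscs An SSCS tibble from [build_sscs()] containing both
#'   orientations, or the alpha-beta half when `sscs_ba` is given.
#' @param sscs_ba Optional beta-alpha half; family keys must match
#'   `sscs`'s row by row, otherwise the pair is rejected.
#' @return Tibble with `family_id`, key columns, consensus `seq`/`ins` and
#'   the per-strand input read counts `n_ab`, `n_ba`.
#' @export
build_dcs <- function(sscs, sscs_ba = NULL) {
  if (!is.null(sscs_ba)) {
    if (!identical(sscs$family_id, sscs_ba$family_id)) {
      abort("family keys of the two strand consensuses do not match")
    }
    sscs <- bind_rows(sscs, sscs_ba)
  }
  ab <- filter(sscs, .data$orient == "ab")
  ba <- filter(sscs, .data$orient == "ba")
  common <- intersect(ab$family_id, ba$family_id)
  if (length(common) == 0) {
    return(tibble(
      family_id = character(), tag_lo = character(), tag_hi = character(),
      chrom = character(), start = integer(), end = integer(),
      seq = character(), ins = character(),
      n_ab = integer(), n_ba = integer()
    ))
  }
  ab <- ab[match(common, ab$family_id), , drop = FALSE]
  ba <- ba[match(common, ba$family_id), , drop = FALSE]
  out <- ab[, c("family_id", "tag_lo", "tag_hi", "chrom", "start", "end")]
  out$seq <- as.character(cpp_dcs_pair(ab$seq, ba$seq))
  out$ins <- ab$ins
  out$n_ab <- ab$n_reads
  out$n_ba <- ba$n_reads
  disagree <- which(ab$ins != ba$ins)
  for (i in disagree) {
    ia <- parse_ins(ab$ins[i]); ib <- parse_ins(ba$ins[i])
    ka <- paste(ia$pos, ia$seq); kb <- paste(ib$pos, ib$seq)
    agree <- ka %in% kb
    conflicted <- setdiff(union(ia$pos, ib$pos), ia$pos[agree])
    s <- out$seq[i]
    for (p in conflicted) {
      o <- p - out$start[i]
      substr(s, o, o) <- "N"
    }
    out$seq[i] <- s
    out$ins[i] <- unparse_ins(ia$pos[agree], ia$seq[agree])
  }
  arrange(out, .data$chrom, .data$start, .data$family_id)
}

#' Full consensus pipeline: reads to duplex consensus reads
#'
#' Convenience wrapper chaining [group_families()], [build_sscs()] and
#' [build_dcs()].
#'
#' @inheritParams build_sscs
#' @param reads Raw tagged reads.
#' @return DCS tibble (see [build_dcs()]) with attributes `n_raw_reads` and
#'   `n_rejected`.
#' @export
call_consensus <- function(reads, min_reads = 2L, majority_frac = 0.5) {
  fams <- group_families(reads)
  dcs <- build_dcs(build_sscs(fams, min_reads = min_reads, majority_frac = majority_frac))
  attr(dcs, "n_raw_reads") <- nrow(reads)
  attr(dcs, "n_rejected") <- attr(fams, "n_rejected")
  dcs
}

#' Consensus reduction and effective coverage metrics
#'
#' `reduction_pct` is the percentage of raw reads removed by duplex
#' consensus collapsing, `100 * (1 - dcs/raw)`. Effective coverage is the
#' mean depth over panel bases of the duplex consensus reads in
#' liquid-biopsy mode, or of the raw reads in tissue mode (which builds no
#' consensus); `pct_target_ge_threshold` is the percentage of panel bases
#' at or above `coverage_threshold`.
#'
#' @param raw_reads,dcs_reads Read tibbles, or plain read counts (in which
#'   case the coverage fields are `NA`).
#' @param panel Panel tibble (`chrom`, `start`, `end`, 0-based half-open);
#'   required for the coverage fields, must be non-empty.
#' @param coverage_threshold Fold-coverage threshold for
#'   `pct_target_ge_threshold` (default 250, the liquid-biopsy reporting
#'   threshold).
#' @param mode `"lb"` (coverage from DCS reads) or `"tissue"` (raw reads).
#' @return One-row tibble of the metrics.
#' @export
consensus_metrics <- function(raw_reads, dcs_reads, panel = NULL,
                              coverage_threshold = 250, mode = c("lb", "tissue")) {
  mode <- match.arg(mode)
  n_raw <- if (is.numeric(raw_reads)) raw_reads else nrow(raw_reads)
  n_dcs <- if (is.numeric(dcs_reads)) dcs_reads else nrow(dcs_reads)
  if (n_raw <= 0) abort("raw read count must be positive")
  if (n_dcs > n_raw) abort("consensus reads cannot outnumber raw reads")
  mean_cov <- NA_real_
  pct_ge <- NA_real_
  cov_src <- if (mode == "lb") dcs_reads else raw_reads
  if (!is.numeric(cov_src)) {
    if (is.null(panel) || nrow(panel) == 0) abort("a non-empty panel is required for coverage metrics")
    depth <- panel_depth(cov_src, panel)
    mean_cov <- mean(depth)
    pct_ge <- 100 * mean(depth >= coverage_threshold)
  }
  tibble(
    total_raw_reads = n_raw,
    dcs_reads = n_dcs,
    reduction_pct = 100 * (1 - n_dcs / n_raw),
    mean_effective_coverage = mean_cov,
    pct_target_ge_threshold = pct_ge,
    coverage_threshold = coverage_threshold,
    mode = mode
  )
}

# Depth per panel base from read fragment intervals (0-based half-open).
#' @noRd
panel_depth <- function(reads, panel) {
  out <- numeric(0)
  for (ch in unique(panel$chrom)) {
    p <- panel[panel$chrom == ch, , drop = FALSE]
    r <- reads[reads$chrom == ch, , drop = FALSE]
    cov <- if (nrow(r) == 0) {
      NULL
    } else {
      IRanges::coverage(IRanges::IRanges(start = r$start + 1L, end = r$end))
    }
    for (i in seq_len(nrow(p))) {
      pos <- (p$start[i] + 1L):p$end[i]
      if (is.null(cov)) {
        out <- c(out, numeric(length(pos)))
      } else {
        v <- as.numeric(cov)
        d <- ifelse(pos <= length(v), v[pos], 0)
        out <- c(out, d)
      }
    }
  }
  out
}
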