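# Readers and writers for the interchange formats.
#
# Coordinates: BED and the in-memory fragment intervals are 0-based
# half-open; VCF, pileups and variant tables are 1-based. SAM is the read
# interchange format (text, diffable); duplex tags travel in the XA/XB
# read tags and the strand orientation in XO ("ab"/"ba").

#' Read a BED file of panel regions
#'
#' Validates, sorts and merges overlapping intervals (0-based half-open).
#'
#' @param path BED file (3+ columns; column 4, if present, is the label).
#' @param is_hotspot Flag the regions as hotspot regions.
#' @param ref Optional [sim_reference()] to validate contig names against.
#' @return Panel tibble `chrom`, `start`, `end`, `label`, `is_hotspot`,
#'   with the total target length (bp) in `attr(, "total_bp")`.
#' @export
read_bed <- function(path, is_hotspot = FALSE, ref = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) abort(sprintf("empty BED file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns",
                  which(lengths(parts) < 3)[1]))
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-numeric coordinates on BED line %d", which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) abort(sprintf("start >= end on BED line %d", bad[1]))
  if (!is.null(ref)) {
    unk <- which(!(chrom %in% ref$contig))
    if (length(unk) > 0) {
      abort(sprintf("unknown contig '%s' on BED line %d", chrom[unk[1]], unk[1]))
    }
  }
  label <- vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, character(1))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = end)
  ))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = if (all(is.na(label))) sprintf("region_%d", seq_along(gr)) else {
      # label of the first input interval falling in each merged region
      vapply(seq_along(gr), function(i) {
        hit <- which(chrom == as.character(GenomicRanges::seqnames(gr))[i] &
                       start < GenomicRanges::end(gr)[i] &
                       end > GenomicRanges::start(gr)[i] - 1L)
        l <- label[hit[1]]
        if (is.na(l)) sprintf("region_%d", i) else l
      }, character(1))
    },
    is_hotspot = is_hotspot
  )
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}

#' Write panel regions as BED
#'
#' @param panel Panel tibble (0-based half-open intervals).
#' @param path Output path.
#' @export
write_bed <- function(panel, path) {
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", panel$chrom, panel$start, panel$end,
            panel$label %||% sprintf("region_%d", seq_len(nrow(panel)))),
    path
  )
  invisible(path)
}

#' Write the reference as FASTA (+ index)
#'
#' @param ref A [sim_reference()].
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(setNames(ref$seq, ref$contig))
  Biostrings::writeXStringSet(x, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Read a reference FASTA (single contig) with a panel
#'
#' @param fasta_path FASTA file.
#' @param panel Panel tibble (e.g. from [read_bed()]); defaults to one
#'   region spanning the contig.
#' @return A [sim_reference()]-shaped object.
#' @export
read_reference_fasta <- function(fasta_path, panel = NULL) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  if (length(x) != 1) abort("expected a single-contig reference")
  contig <- sub("\\s.*$", "", names(x)[1])
  seq <- as.character(x[[1]])
  if (is.null(panel)) {
    panel <- tibble(chrom = contig, start = 0L, end = nchar(seq),
                    label = "target", is_hotspot = FALSE)
  }
  structure(list(contig = contig, seq = seq, panel = validate_panel(panel, contig, nchar(seq))),
            class = "sim_reference")
}

#' Write tagged reads as coordinate-sorted SAM
#'
#' Duplex tags are written as `XA`/`XB` and orientation as `XO`; the header
#' records the tool version, the configuration hash and the seed.
#'
#' @param reads Read tibble.
#' @param ref A [sim_reference()].
#' @param path Output SAM path.
#' @param seed,config Optional provenance recorded in the header.
#' @export
write_reads_sam <- function(reads, ref, path, seed = NULL, config = NULL) {
  reads <- arrange(as_tibble(reads), .data$chrom, .data$start, .data$read_id)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$contig, nchar(ref$seq)),
    sprintf("@PG\tID:duplexlb\tPN:duplexlb\tVN:%s", duplexlb_version()),
    sprintf("@CO\tseed=%s\tconfig_hash=%s",
            seed %||% attr(reads, "sim_info")$seed %||% "NA",
            if (!is.null(config)) config_hash(unclass(config)) else
              attr(reads, "sim_info")$config_hash %||% "NA")
  )
  plain <- !grepl("-", reads$seq, fixed = TRUE) & !nzchar(reads$ins)
  cigar <- character(nrow(reads))
  sam_seq <- character(nrow(reads))
  cigar[plain] <- sprintf("%dM", reads$end[plain] - reads$start[plain])
  sam_seq[plain] <- reads$seq[plain]
  for (i in which(!plain)) {
    conv <- aligned_to_sam_one(reads$seq[i], reads$ins[i], reads$start[i])
    cigar[i] <- conv$cigar
    sam_seq[i] <- conv$seq
  }
  body <- sprintf(
    "%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tXA:Z:%s\tXB:Z:%s\tXO:Z:%s",
    reads$read_id, reads$chrom, reads$start + 1L, cigar, sam_seq,
    strrep("I", nchar(sam_seq)), reads$tag_a, reads$tag_b, reads$orient
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read duplex-tagged reads from SAM/BAM
#'
#' SAM text is converted through BAM (Rsamtools) and the aligned
#' representation is rebuilt from POS/CIGAR/SEQ; duplex annotations are
#' taken from the XA/XB/XO tags (absent tags leave `NA`, which
#' [group_families()] routes to its reject list).
#'
#' @param path SAM or BAM file.
#' @return Read tibble in the package's aligned representation.
#' @export
read_reads_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"),
    tag = c("XA", "XB", "XO")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  cigar <- res$cigar
  pos <- res$pos
  plain <- grepl("^[0-9]+M$", cigar)
  start <- integer(n); end <- integer(n)
  aligned <- character(n); ins <- character(n)
  start[plain] <- pos[plain] - 1L
  end[plain] <- pos[plain] - 1L + nchar(seqs[plain])
  aligned[plain] <- seqs[plain]
  ins[plain] <- ""
  for (i in which(!plain)) {
    conv <- sam_to_aligned_one(pos[i], cigar[i], seqs[i])
    start[i] <- conv$start; end[i] <- conv$end
    aligned[i] <- conv$seq; ins[i] <- conv$ins
  }
  tag_or_na <- function(tg) {
    v <- res$tag[[tg]]
    if (is.null(v)) rep(NA_character_, n) else v
  }
  tibble(
    read_id = res$qname,
    tag_a = tag_or_na("XA"),
    tag_b = tag_or_na("XB"),
    orient = tag_or_na("XO"),
    chrom = as.character(res$rname),
    start = start, end = end,
    seq = aligned, ins = ins
  )
}

#' Write calls as VCF 4.2
#'
#' FILTER carries the caller decision; the sample column carries
#' `AD` (alternate-supporting reads), `DP` (depth) and `AF` (VAF as a
#' fraction). The header records the caller mode, LOB and read-support
#' rule, plus tool version, configuration hash and seed.
#'
#' @param calls Calls tibble from [call_variants()], sorted by position.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @param config A [caller_config()].
#' @param ref Optional [sim_reference()] for the contig header line.
#' @param seed Optional seed recorded in the header.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE",
                      config = caller_config("lb"), ref = NULL, seed = NULL) {
  calls <- as_tibble(calls)
  if (nrow(calls) > 1) {
    o <- order(calls$chrom, calls$pos, calls$alt)
    if (!identical(o, seq_len(nrow(calls)))) abort("calls must be sorted by (chrom, pos)")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=duplexlb-%s", duplexlb_version()),
    sprintf("##duplexlb_mode=%s,lob_vaf=%s,min_alt_reads=%d",
            config$mode, format(config$lob_vaf), config$min_alt_reads),
    sprintf("##duplexlb_run=seed=%s,config_hash=%s",
            seed %||% "NA", config_hash(unclass(config))),
    if (!is.null(ref)) sprintf("##contig=<ID=%s,length=%d>", ref$contig, nchar(ref$seq)),
    "##FILTER=<ID=below_LOB,Description=\"VAF not strictly above the limit of blank\">",
    "##FILTER=<ID=low_support,Description=\"Fewer supporting reads than required\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class (SNV or InDel)\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alternate-supporting read count\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth (non-N)\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s", sample_name)
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tCLASS=%s\tAD:DP:AF\t%d:%d:%s",
      calls$chrom, calls$pos, calls$ref, calls$alt, calls$filter,
      calls$class, calls$alt_count, calls$depth,
      sprintf("%.6g", calls$vaf / 100)
    )
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read calls back from a duplexlb VCF
#'
#' @param path VCF path.
#' @return Calls tibble (`chrom`, `pos`, `ref`, `alt`, `class`,
#'   `alt_count`, `depth`, `vaf`, `filter`).
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), class = character(), alt_count = integer(),
      depth = integer(), vaf = numeric(), filter = character()
    ))
  }
  gt <- v@gt[, 2]
  parts <- strsplit(gt, ":", fixed = TRUE)
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    class = sub("^CLASS=", "", fix$INFO),
    alt_count = as.integer(vapply(parts, `[[`, character(1), 1)),
    depth = as.integer(vapply(parts, `[[`, character(1), 2)),
    vaf = 100 * as.numeric(vapply(parts, `[[`, character(1), 3)),
    filter = fix$FILTER
  )
}

#' Write / read the spike-in truth set
#'
#' The truth travels as a VCF (1-based, left-aligned) plus a TSV sidecar
#' `chrom pos ref alt class nominal_vaf`.
#'
#' @param truth Truth tibble.
#' @param vcf_path,tsv_path Output paths (either may be `NULL`).
#' @param ref Optional [sim_reference()] for the contig line.
#' @export
write_truth <- function(truth, vcf_path = NULL, tsv_path = NULL, ref = NULL) {
  truth <- arrange(as_tibble(truth), .data$chrom, .data$pos)
  if (!is.null(tsv_path)) {
    readr::write_tsv(truth[, c("chrom", "pos", "ref", "alt", "class", "nominal_vaf")],
                     tsv_path)
  }
  if (!is.null(vcf_path)) {
    header <- c(
      "##fileformat=VCFv4.2",
      sprintf("##source=duplexlb-%s", duplexlb_version()),
      if (!is.null(ref)) sprintf("##contig=<ID=%s,length=%d>", ref$contig, nchar(ref$seq)),
      "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
      "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Nominal VAF percent\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    body <- sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=%s;NVAF=%s",
      truth$chrom, truth$pos,
      if ("variant_id" %in% names(truth)) truth$variant_id else ".",
      truth$ref, truth$alt, truth$class, format(truth$nominal_vaf, trim = TRUE)
    )
    readr::write_lines(c(header, body), vcf_path)
  }
  invisible(truth)
}

#' @rdname write_truth
#' @param path Truth TSV path.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", pos = "i", ref = "c", alt = "c",
                    class = "c", nominal_vaf = "d"
                  ))
}

#' Read a run configuration YAML
#'
#' Recognized blocks: `simulator` ([sim_config()] fields), `caller`
#' ([caller_config()] fields), `levels`, `replicates`, `seed`.
#'
#' @param path YAML file.
#' @return List with `sim`, `caller`, `levels`, `replicates`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$simulator %||% list())
  if (!is.null(y$seed)) sim$seed <- as.integer(y$seed)
  caller <- do.call(caller_config, y$caller %||% list())
  list(
    sim = sim,
    caller = caller,
    levels = as.numeric(unlist(y$levels %||% c(0.05, 0.1, 0.5, 1, 5))),
    replicates = y$replicates %||% 2L,
    seed = sim$seed
  )
}
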