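# Internal helpers shared across the simulator, consensus and calling layers.
#
# Coordinate conventions (stated wherever coordinates appear):
#   * fragment/panel intervals are 0-based half-open (BED convention);
#   * pileups, variants and VCF records are 1-based.
#
# Aligned-read representation: each read (or consensus read) stores
#   seq : a string over the reference window [start, end) with one character
#         per reference base, alphabet {A,C,G,T,N,-} ('-' = deleted base);
#   ins : "" or ";"-separated "POS:SEQ" entries, POS the 1-based reference
#         coordinate of the anchor base after which SEQ is inserted.
# This keeps reads within a family co-aligned column by column, which is what
# the per-base consensus vote operates on.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
encode_tag <- function(i, salt = 0L, width = 10L, salt_width = 7L) {
  enc <- function(x, w) {
    out <- matrix("A", nrow = w, ncol = length(x))
    for (j in seq_len(w)) {
      out[j, ] <- DNA_BASES[(x %% 4L) + 1L]
      x <- x %/% 4L
    }
    do.call(paste0, asplit(out, 1))
  }
  paste0(enc(rep.int(as.integer(salt), length(i)), salt_width), enc(as.integer(i), width))
}

# the three substitution choices per reference base, column-indexed by
# match(base, DNA_BASES)
OTHER_BASES <- matrix(
  c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
  nrow = 3
)

#' @noRd
random_other_base <- function(base) {
  OTHER_BASES[cbind(sample.int(3L, length(base), replace = TRUE),
                    match(base, DNA_BASES))]
}

# Parsed insertion annotations as a plain list (hot path: called per read
# family): $row (index into `ins`), $pos (1-based anchor), $seq.
#' @noRd
parse_ins <- function(ins) {
  has <- which(!is.na(ins) & nzchar(ins))
  if (length(has) == 0) {
    return(list(row = integer(), pos = integer(), seq = character()))
  }
  parts <- strsplit(ins[has], ";", fixed = TRUE)
  lens <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  list(
    row = rep.int(has, lens),
    pos = as.integer(sub(":.*$", "", flat)),
    seq = sub("^[0-9]+:", "", flat)
  )
}

#' @noRd
unparse_ins <- function(pos, seq) {
  if (length(pos) == 0) return("")
  ord <- order(pos)
  paste(sprintf("%d:%s", pos[ord], seq[ord]), collapse = ";")
}

# Convert one aligned-representation read to SAM CIGAR + SEQ.
#' @noRd
aligned_to_sam_one <- function(seq, ins, start) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_del <- chars == "-"
  ins_tb <- parse_ins(ins)
  n_ins <- length(ins_tb$pos)
  # split M/D runs at insertion anchors so I ops land between them
  r <- rle(is_del)
  ends <- cumsum(r$lengths)
  starts_ <- c(1L, utils::head(ends, -1) + 1L)
  segs <- data.frame(start = starts_, end = ends, del = r$values)
  anchors <- sort(ins_tb$pos - start) # offset (1-based within window) of anchor
  cig <- character(0)
  sam_seq <- character(0)
  emit_seg <- function(s, e, del) {
    if (e < s) return()
    if (del) {
      cig <<- c(cig, sprintf("%dD", e - s + 1L))
    } else {
      cig <<- c(cig, sprintf("%dM", e - s + 1L))
      sam_seq <<- c(sam_seq, chars[s:e])
    }
  }
  if (n_ins == 0) {
    for (k in seq_len(nrow(segs))) emit_seg(segs$start[k], segs$end[k], segs$del[k])
  } else {
    ord <- order(ins_tb$pos)
    ipos <- ins_tb$pos[ord]
    iseq <- ins_tb$seq[ord]
    off <- ipos - start # insertion goes after window offset `off`
    ii <- 1L
    for (k in seq_len(nrow(segs))) {
      s <- segs$start[k]; e <- segs$end[k]
      while (ii <= length(off) && off[ii] >= s && off[ii] <= e) {
        emit_seg(s, off[ii], segs$del[k])
        cig <- c(cig, sprintf("%dI", nchar(iseq[ii])))
        sam_seq <- c(sam_seq, iseq[ii])
        s <- off[ii] + 1L
        ii <- ii + 1L
      }
      emit_seg(s, e, segs$del[k])
    }
  }
  # merge adjacent same-op runs (can arise around insertion anchors)
  ops <- sub("^[0-9]+", "", cig)
  n_op <- as.integer(sub("[MDI]$", "", cig))
  keep <- character(0)
  if (length(ops) > 0) {
    j <- 1L
    while (j <= length(ops)) {
      k <- j
      while (k < length(ops) && ops[k + 1L] == ops[j]) k <- k + 1L
      keep <- c(keep, sprintf("%d%s", sum(n_op[j:k]), ops[j]))
      j <- k + 1L
    }
  }
  list(cigar = paste(keep, collapse = ""), seq = paste(sam_seq, collapse = ""))
}

# Rebuild the aligned representation from SAM POS/CIGAR/SEQ.
#' @noRd
sam_to_aligned_one <- function(pos, cigar, seq) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDSH=X]", cigar))[[1]]
  n_op <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  aligned <- character(0)
  ins_pos <- integer(0)
  ins_seq <- character(0)
  ref_cursor <- pos - 1L # 0-based
  q <- 1L
  for (k in seq_along(op)) {
    len <- n_op[k]
    if (op[k] %in% c("M", "=", "X")) {
      aligned <- c(aligned, substr(seq, q, q + len - 1L))
      q <- q + len
      ref_cursor <- ref_cursor + len
    } else if (op[k] == "D") {
      aligned <- c(aligned, strrep("-", len))
      ref_cursor <- ref_cursor + len
    } else if (op[k] == "I") {
      ins_pos <- c(ins_pos, ref_cursor) # anchor = last consumed ref base (1-based)
      ins_seq <- c(ins_seq, substr(seq, q, q + len - 1L))
      q <- q + len
    } else if (op[k] %in% c("S", "H")) {
      if (op[k] == "S") q <- q + len
    }
  }
  list(
    start = pos - 1L,
    end = ref_cursor,
    seq = paste(aligned, collapse = ""),
    ins = unparse_ins(ins_pos, ins_seq)
  )
}

# Left-align and trim one variant record against the reference sequence
# (minimal representation; standard parsimony/left-shift rules).
#' @noRd
normalize_one <- function(pos, ref, alt, refseq) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 && (nr > 1 || na > 1) &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr == 1 || na == 1) {
        if (pos <= 1) break
        prev <- substr(refseq, pos - 1, pos - 1)
        ref <- paste0(prev, substr(ref, 1, nr - 1))
        alt <- paste0(prev, substr(alt, 1, na - 1))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1, nr - 1)
        alt <- substr(alt, 1, na - 1)
      }
    } else {
      break
    }
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize variant records (left-align and trim)
#'
#' Reduces each `(pos, ref, alt)` record to its minimal, left-most
#' representation against the reference sequence, the usual prerequisite for
#' exact truth-set comparison. Positions are 1-based.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param ref A [sim_reference()] object, or a plain reference sequence
#'   string for single-contig data.
#' @return A tibble with the same rows, normalized in place, with a `class`
#'   column (`"SNV"` or `"InDel"`) recomputed from the normalized alleles.
#' @export
normalize_variants <- function(variants, ref) {
  refseq <- if (is.character(ref)) ref else ref$seq
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, class = character(0)))
  }
  out <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(p, r, a) normalize_one(p, r, a, refseq)
  )
  variants$pos <- vapply(out, `[[`, integer(1), "pos")
  variants$ref <- vapply(out, `[[`, character(1), "ref")
  variants$alt <- vapply(out, `[[`, character(1), "alt")
  mutate(variants,
    class = if_else(nchar(.data$ref) == nchar(.data$alt), "SNV", "InDel")
  )
}

#' @noRd
config_hash <- function(x) {
  rlang::hash(x)
}

#' @noRd
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  invisible(x)
}
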