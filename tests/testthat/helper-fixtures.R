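# Small fixtures built in code; everything is generated at test time.

tiny_ref <- function(seed = 7L) sim_reference(seed = seed)

# one-region reference for cheap single-locus tests
one_region_ref <- function(seed = 7L, len = 400L) {
  sim_reference(
    seed = seed, length = 1000L,
    panel = tibble::tibble(chrom = "chrS", start = 200L, end = 200L + len,
                           label = "hotspot_1", is_hotspot = TRUE)
  )
}

fast_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_molecules = 300L, family_size_mean = 4, seed = 5L,
                   seq_error_rate = 0, pcr_error_rate = 0)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hand-built co-aligned reads for consensus unit tests
mk_reads <- function(seqs, orient, tag_a = "TTAA", tag_b = "GGCC",
                     chrom = "chrS", start = 100L, ins = "") {
  n <- length(seqs)
  tibble::tibble(
    read_id = sprintf("r%02d", seq_len(n)),
    tag_a = rep_len(tag_a, n),
    tag_b = rep_len(tag_b, n),
    orient = rep_len(orient, n),
    chrom = chrom,
    start = start,
    end = start + nchar(seqs[1]),
    seq = seqs,
    ins = rep_len(ins, n)
  )
}

# reads tibble with d identical reference-matching fragments per molecule,
# used to build exact-depth pileup fixtures
mk_ref_reads <- function(ref, n, region = 1L, mutate_at = NULL, alt = NULL,
                         n_alt = 0L) {
  s <- ref$panel$start[region]
  e <- ref$panel$end[region]
  win <- substr(ref$seq, s + 1L, e)
  seqs <- rep(win, n)
  if (n_alt > 0) {
    off <- mutate_at - s
    for (i in seq_len(n_alt)) {
      x <- seqs[i]
      substr(x, off, off) <- alt
      seqs[i] <- x
    }
  }
  tibble::tibble(
    read_id = sprintf("x%04d", seq_len(n)),
    tag_a = sprintf("TAG%04dA", seq_len(n)),
    tag_b = sprintf("TAG%04dB", seq_len(n)),
    orient = "ab",
    chrom = ref$contig,
    start = s,
    end = e,
    seq = seqs,
    ins = ""
  )
}

# molecule id prefix of a simulator read id ("m0000123_ab_r01" -> "m0000123")
mol_of <- function(read_id) sub("_.*$", "", read_id)
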