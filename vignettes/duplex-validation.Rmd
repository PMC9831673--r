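---
title: "Duplex consensus calling and analytical validation with duplexlb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling and analytical validation with duplexlb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexlb)
library(dplyr)
```

## The problem

Liquid biopsy assays detect tumor- or mosaic-derived variants in circulating
free DNA (cfDNA) at variant allele frequencies (VAFs) well below what raw
short-read sequencing can resolve: at 0.5% VAF a true variant is
indistinguishable from the ~0.1–1% per-base error floor of sequencing and
late PCR artifacts. Duplex sequencing solves this by tagging *both strands*
of each original DNA molecule before amplification. All PCR copies of one
strand form a strand family (the αβ family for the forward strand, βα for
its complement); a true variant is present in both families of a molecule,
while a sequencing error lives in single reads and a PCR artifact in at most
one strand family.

duplexlb implements this error model end to end: a duplex read simulator, a
strand-aware consensus caller, a dual-mode low-VAF variant caller, and the
analytical-validation statistics (limit of blank, detection and
quantification; sensitivity and positive predictive value; trueness,
repeatability, total error) that turn a validation run into reporting
cutoffs.

## Consensus model

Reads are grouped into families by the canonical key
`(min(tag_a, tag_b), max(tag_a, tag_b), chrom, fragment_start, fragment_end)`;
lexicographic canonicalization makes the αβ read and its βα mate collide
onto one key deterministically while the per-read orientation keeps the two
strand families apart inside it.

* **SSCS** (single-strand consensus): per strand family with at least
  `min_reads = 2` reads, the call at each base is the allele — A/C/G/T, a
  deletion gap, or an insertion at an anchor — supported by *strictly more
  than* `majority_frac = 0.5` of the family's reads; anything else,
  including a 1–1 tie, is N. Voting is count-based, not quality-weighted:
  the assay's guidelines give no quality model, and count voting is exactly
  testable. Sides with a single read yield no consensus.
* **DCS** (duplex consensus): a base is emitted only where the two SSCS
  mates agree on a non-N call; disagreement becomes N, and a family lacking
  either SSCS contributes nothing (pure duplex mode — no single-strand
  rescue). Every DCS read is therefore backed by at least two raw reads on
  *each* strand.

Reads within a family are co-aligned by construction (they share fragment
coordinates and the simulator places variants at the molecule level), so
per-column voting operates directly on aligned alleles including gap
symbols; insertion alleles are voted at their anchor base against the
no-insertion alternative, and an unresolvable anchor is masked to N.

## Calling model

Pileups are taken over every panel base (1-based positions; panel intervals
are 0-based half-open BED). N consensus bases carry no allele information
and are excluded from both the allele counts and the VAF denominator; they
are tallied separately. InDel alleles are anchored at the base preceding
the event and left-aligned.

Two modes share one filter rule, `PASS ⇔ VAF > LOB AND alt_reads ≥
min_alt_reads`, with "above the LOB" read as a *strict* inequality:

| mode   | substrate            | LOB (VAF) | min. supporting reads |
|--------|----------------------|-----------|-----------------------|
| lb     | duplex consensus     | 0.25%     | 8 consensus reads     |
| tissue | raw reads            | 5%        | 0                     |

So 8 alternate reads at depth 3200 (exactly 0.25%) is *not* called, 9/3200
is, and 7 reads at 0.7% VAF fails the support rule. The 8-read rule applies
to the alternate-supporting consensus read count, not the total depth, and
only in liquid-biopsy mode — it is defined in terms of consensus reads,
which the tissue workflow does not build (tissue reads are also not
deduplicated). A call failing the LOB is labelled `below_LOB` even when it
also lacks support; `low_support` marks calls above the LOB with fewer than
the required reads.

## Validation statistics

* **LOB** — nonparametric 95th percentile (order statistic at rank
  ⌈0.95 n⌉) of per-position non-reference allele fractions at wild-type
  positions, pooled over blanks, rounded *up* to the nearest 0.05% VAF
  step; at least 60 wild-type positions are required. A Gaussian
  alternative (mean + 1.645 SD) is available; the percentile is the default
  because it makes no distributional assumption about a noise floor that is
  strongly zero-inflated after duplex collapsing.
* **LOD** — the lowest nominal level whose hit rate reaches the confidence
  goal; the achieved confidence is the hit rate itself (27/30 at 0.5% VAF
  gives an LOD of 0.5% at 90% confidence).
* **Sensitivity / PPV** — truth comparison is *exact* after normalization
  (left-alignment and trimming) within trusted regions, per class (SNV,
  InDel) and per region set (full panel, hotspot subset). This is a
  deliberate simplification of haplotype-aware comparison engines: at
  single-event, well-separated variants the two coincide, and exactness
  keeps the comparison auditable.
* **Quantification** — for duplicate measurements of each variant at
  nominal level `v`: mean relative bias `B = mean(100·(mean(measured)−v)/v)`,
  trueness `100 − |B|`; pooled duplicate SD `sqrt(Σ dᵢ²/(2n))`, CV
  `100·SD/v`, repeatability `100 − CV`; total error `|B| + 2·CV`
  (Westgard-style). The LOQ is the lowest level with trueness > 90 and
  repeatability > 80. The trueness/repeatability definitions are
  reconstructions of a computation the reference assay does not fully
  specify; they are configurable and documented here as the package's
  definitions.

```{r loq}
determine_loq(tibble::tibble(
  nominal_vaf = c(0.5, 1, 5),
  trueness = c(85.0, 92.5, 99.9),
  repeatability = c(34.4, 65.2, 91.9)
))
```

## What the simulator emulates

`simulate_sample()` draws, per panel region, `n_molecules` double-stranded
fragments spanning the region. Each molecule independently carries each
variant allele with probability `nominal_vaf/100`; each of its two strands
yields Poisson(`family_size_mean`) reads and drops out entirely with
probability `strand_dropout_prob`. A PCR error hits a molecule-strand with
probability `pcr_error_rate` and propagates to *all* reads of that strand
family — exactly the artifact class the duplex consensus exists to remove —
while sequencing errors are i.i.d. per read base at `seq_error_rate`.
Duplex tags are collision-free synthetic barcodes (no tag sequencing
errors); fragment endpoints are fixed per molecule and reads span the whole
fragment, which keeps pileup bookkeeping exact.

Defaults (the study conditions of the bundled validation series):

| parameter             | default | rationale |
|-----------------------|---------|-----------|
| `n_molecules`         | 10000   | ~33 ng cfDNA in genome equivalents; see below |
| `family_size_mean`    | 4       | typical duplex library PCR copy number per strand |
| `strand_dropout_prob` | 0.05    | occasional loss of one strand's amplicons |
| `seq_error_rate`      | 1e-3    | Illumina-class per-base substitution floor |
| `pcr_error_rate`      | 1e-3    | rare early-PCR artifacts, molecule-strand level |

The molecule budget deserves a note. With these family sizes, a molecule
survives to a duplex consensus read with probability ≈ 0.75, so 10,000
input molecules yield ≈ 7,400-fold duplex depth. At 0.5% VAF that is an
expectation of ~37 alternate consensus reads against a PASS threshold of
max(8, 0.25%·depth ≈ 19) — comfortably detectable, which is what the
validation series requires (a validated assay of this class detects every
SNV at 0.5%). A few thousand molecules would leave the expectation at or below
the threshold and make 0.5% undetectable by construction; quoting a smaller
input would misstate the study conditions rather than stress the method.

The simulator does **not** emulate realistic fragment-size distributions or
nucleosome footprints, GC bias, tag cross-contamination, mapping or
alignment ambiguity (reads arrive placed), quality-score structure
(qualities are uniform and the voter ignores them), or sequencing errors
inside inserted bases. Passing tests therefore demonstrate the logic of
consensus building and validation statistics under the stated error model —
not performance on real libraries, where alignment artifacts dominate InDel
error modes. That is also why the simulated InDel detection at 0.5% VAF is
higher than the ~79% such assays report: real InDel misses are
alignment-driven, a mechanism outside this generative model.

## The bundled validation series

`make_validation_series()` reproduces the standard validation design: one
wild-type control plus duplicates at 0.05, 0.1, 0.5, 1 and 5% VAF; 8 SNV +
7 InDel spike-ins confined to the hotspot regions; 59 SNV + 1 InDel
germline background variants at 50%/100% VAF present in every sample. The
bookkeeping reproduces the reference composition: 660 germline-variant
observations (649 SNV, 11 InDel) across the 11 samples and 90 spike-in
observations above the 0.25% LOB (48 SNV, 42 InDel). `dilute_in_silico()`
thins two read sets Bernoulli-wise to emulate the in silico dilutions used
for the tissue workflow (a 10–20% dilution of an 80% VAF source lands at
8–16% expected VAF).

Problem sizes: the bundled synthetic panel is a 2 kb contig with a 400 bp
hotspot region and a 990 bp background region — large enough to host all
spike-ins, the germline background and >1300 wild-type positions for the
LOB (60 are required), small enough that the full 11-sample series at
default depth runs in about two minutes on one core. A production-scale
102 kb panel enters the package only as interval arithmetic (`read_bed()` reports
it); per-position statistics are independent of panel width.

## Numerical and degenerate-input choices

* Ties at any consensus base (and unresolved insertion anchors) are N,
  never a coin flip; all voting is deterministic and order-independent.
* Reads missing tags are routed to a counted reject list, never dropped.
* `vaf` uses the non-N depth at the anchor position; a zero-depth column
  yields no call.
* Variant matching normalizes both sides (right-trim with left extension,
  then left-trim), so padded or shifted representations of the same event
  compare equal.
* Fixed seeds make every layer byte-reproducible: per-sample seeds are
  derived from the series seed, and report rendering has a deterministic
  field order.
* `estimate_lob()` refuses fewer than 60 wild-type positions;
  `performance()` refuses undefined denominators rather than returning
  `NaN`; a `detection_rate()` cell with no observations is an error, and an
  unestablished LOD/LOQ is reported as such rather than extrapolated.

## Known limitations

* Pure duplex mode only: families with one usable strand are discarded
  (an `--sscs-rescue` mode is a possible extension, off by design).
* Exact post-normalization matching will undercount truth agreement for
  complex or adjacent events that a haplotype-aware comparator would
  reconcile; the simulator keeps variants well-separated so this does not
  bite in the bundled series.
* The simulated wild-type noise after duplex collapsing is essentially
  zero at these depths, so the simulated LOB sits at 0% VAF — real cfDNA
  background (oxidative damage, low-level contamination) is what pushes an
  assay to 0.25%, and the assay default is used wherever an empirical blank
  set is unavailable.
* Tissue mode inherits whatever duplicates are in the raw reads; no
  deduplication is attempted.
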