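#include <Rcpp.h>
using namespace Rcpp;

// Symbols voted on: A, C, G, T and the deletion gap '-'. 'N' never wins a
// vote (it carries no allele information) but still counts in the
// denominator, so a family of two reads voting A vs N yields N, not A.
static inline int sym_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  case '-': return 4;
  default:  return -1; // N or anything else: non-candidate
  }
}

static const char SYMS[5] = {'A', 'C', 'G', 'T', '-'};

// Per-base strict-majority consensus over groups of co-aligned reads.
//
// seqs must be ordered so that each group's reads are contiguous;
// group_sizes gives the number of reads per group. All reads in a group
// must have identical length (they share fragment coordinates). The call
// at a base is the symbol supported by strictly more than majority_frac
// of the group's reads, else 'N'.
// [[Rcpp::export]]
List cpp_sscs_vote(CharacterVector seqs, IntegerVector group_sizes,
                   double majority_frac, bool keep_support) {
  int n_groups = group_sizes.size();
  CharacterVector calls(n_groups);
  List support(keep_support ? n_groups : 0);
  R_xlen_t offset = 0;

  for (int g = 0; g < n_groups; ++g) {
    int k = group_sizes[g];
    if (k <= 0) stop("group sizes must be positive");
    const char *first = CHAR(STRING_ELT(seqs, offset));
    int len = LENGTH(STRING_ELT(seqs, offset));

    // Fast path: a single read string held by > majority_frac of the
    // group forces the per-base majority everywhere.
    bool shortcut = false;
    if (k == 1) {
      shortcut = true;
    } else {
      int same = 0;
      for (int i = 0; i < k; ++i) {
        SEXP s = STRING_ELT(seqs, offset + i);
        if (LENGTH(s) != len) stop("reads within a family differ in length");
        if (strcmp(CHAR(s), first) == 0) ++same;
      }
      if (same > majority_frac * k) shortcut = true;
    }

    if (shortcut && !keep_support) {
      calls[g] = seqs[offset];
    } else {
      std::vector<const char *> ptr(k);
      for (int i = 0; i < k; ++i) ptr[i] = CHAR(STRING_ELT(seqs, offset + i));
      std::string out(len, 'N');
      IntegerVector supp(keep_support ? len : 0);
      std::vector<int> counts(5);
      for (int j = 0; j < len; ++j) {
        std::fill(counts.begin(), counts.end(), 0);
        for (int i = 0; i < k; ++i) {
          int idx = sym_index(ptr[i][j]);
          if (idx >= 0) ++counts[idx];
        }
        int best = 0;
        for (int s = 1; s < 5; ++s) if (counts[s] > counts[best]) best = s;
        if (counts[best] > majority_frac * k) {
          out[j] = SYMS[best];
          if (keep_support) supp[j] = counts[best];
        } else if (keep_support) {
          supp[j] = 0;
        }
      }
      calls[g] = out;
      if (keep_support) support[g] = supp;
    }
    offset += k;
  }

  return List::create(_["call"] = calls, _["support"] = support);
}

// Pair alpha-beta and beta-alpha single-strand consensuses: a duplex base
// is emitted only where both strands call the same non-N symbol.
// [[Rcpp::export]]
CharacterVector cpp_dcs_pair(CharacterVector ab, CharacterVector ba) {
  R_xlen_t n = ab.size();
  if (ba.size() != n) stop("strand consensus vectors differ in length");
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(ab, i));
    const char *b = CHAR(STRING_ELT(ba, i));
    int la = LENGTH(STRING_ELT(ab, i));
    if (LENGTH(STRING_ELT(ba, i)) != la)
      stop("paired strand consensuses differ in length");
    std::string d(la, 'N');
    for (int j = 0; j < la; ++j) {
      if (a[j] == b[j] && a[j] != 'N') d[j] = a[j];
    }
    out[i] = d;
  }
  return out;
}
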