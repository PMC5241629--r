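#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, U/T=3, other=-1
static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline bool wc_pair(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}

static inline bool gu_pair(int a, int b) {
  return (a == 2 && b == 3) || (a == 3 && b == 2);
}

static inline bool can_pair(int a, int b) {
  return wc_pair(a, b) || gu_pair(a, b);
}

// Pair-type index into the 6x6 stack table: CG GC GU UG AU UA; -1 if not a pair.
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 0; // CG
  if (a == 2 && b == 1) return 1; // GC
  if (a == 2 && b == 3) return 2; // GU
  if (a == 3 && b == 2) return 3; // UG
  if (a == 0 && b == 3) return 4; // AU
  if (a == 3 && b == 0) return 5; // UA
  return -1;
}

// Nussinov-style maximum base pairing with minimum hairpin loop size.
// Traceback prefers pairing position i with the smallest admissible partner.
// [[Rcpp::export]]
std::string cpp_nussinov(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_idx(seq[i]);
    if (s[i] < 0) stop("invalid base '%s' at position %d", std::string(1, seq[i]), i + 1);
  }
  if (n == 0) return "";
  std::vector<int> N((size_t)n * n, 0);
#define NN(i, j) N[(size_t)(i) * n + (j)]
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = NN(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int inner = (k - 1 >= i + 1) ? NN(i + 1, k - 1) : 0;
        int outer = (k + 1 <= j) ? NN(k + 1, j) : 0;
        int cand = inner + outer + 1;
        if (cand > best) best = cand;
      }
      NN(i, j) = best;
    }
  }
  std::string db(n, '.');
  // iterative traceback over a stack of intervals
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = NN(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(s[i], s[k])) continue;
      int inner = (k - 1 >= i + 1) ? NN(i + 1, k - 1) : 0;
      int outer = (k + 1 <= j) ? NN(k + 1, j) : 0;
      if (inner + outer + 1 == target) {
        db[i] = '(';
        db[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
#undef NN
  return db;
}

// Intermolecular miRNA:target duplex minimum free energy.
//
// m is the miRNA 5'->3'; u is the target window 5'->3'. Pairing is
// antiparallel; internally the target is reversed so pair indices increase
// in both strands. Energy = sum of nearest-neighbor stacking terms over
// contiguous paired columns plus an affine penalty (loop_open +
// loop_ext per unpaired nt) for each internal loop/bulge. Dangling ends
// are free. stack_table is 6x6 over pair types CG GC GU UG AU UA with
// entry [p1][p2] = dG37 of 5'-ac-3'/3'-bd-5' where p1 = type(a,b) and
// p2 = type(d,c).
// [[Rcpp::export]]
List cpp_duplex(std::string m, std::string u, NumericMatrix stack_table,
                double loop_open = 3.5, double loop_ext = 0.5,
                int max_loop = 10) {
  int M = m.size(), N = u.size();
  std::vector<int> ms(M), ws(N);
  for (int i = 0; i < M; ++i) {
    ms[i] = base_idx(m[i]);
    if (ms[i] < 0) stop("invalid base in miRNA at position %d", i + 1);
  }
  // w = reversed target
  for (int r = 0; r < N; ++r) {
    ws[r] = base_idx(u[N - 1 - r]);
    if (ws[r] < 0) stop("invalid base in target window at position %d", N - r);
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E((size_t)M * N, INF);
  std::vector<int> pred((size_t)M * N, -1);
#define EE(i, r) E[(size_t)(i) * N + (r)]
#define PP(i, r) pred[(size_t)(i) * N + (r)]
  for (int i = 0; i < M; ++i) {
    for (int r = 0; r < N; ++r) {
      if (!can_pair(ms[i], ws[r])) continue;
      double best = 0.0; // open a new duplex at this pair
      int bp = -1;
      // stacked continuation (preferred on ties)
      if (i > 0 && r > 0 && EE(i - 1, r - 1) < INF) {
        int p1 = pair_type(ms[i - 1], ws[r - 1]);
        int p2 = pair_type(ws[r], ms[i]);
        double cand = EE(i - 1, r - 1) + stack_table(p1, p2);
        if (cand < best) { best = cand; bp = (i - 1) * N + (r - 1); }
      }
      // interior loop / bulge continuations, smallest total gap first
      for (int tot = 1; tot <= 2 * max_loop; ++tot) {
        for (int gi = 0; gi <= tot && gi <= max_loop; ++gi) {
          int gr = tot - gi;
          if (gr > max_loop) continue;
          int pi = i - 1 - gi, pr = r - 1 - gr;
          if (pi < 0 || pr < 0) continue;
          if (EE(pi, pr) >= INF) continue;
          double cand = EE(pi, pr) + loop_open + loop_ext * tot;
          if (cand < best) { best = cand; bp = pi * N + pr; }
        }
      }
      EE(i, r) = best;
      PP(i, r) = bp;
    }
  }
  // global minimum (0 = no duplex formed)
  double dg = 0.0;
  int besti = -1, bestr = -1;
  for (int i = 0; i < M; ++i)
    for (int r = 0; r < N; ++r)
      if (EE(i, r) < dg) { dg = EE(i, r); besti = i; bestr = r; }
  std::string pairing(M, ' ');
  int site_start = NA_INTEGER, site_end = NA_INTEGER;
  int npairs = 0;
  if (besti >= 0) {
    int jmin = N, jmax = -1;
    int i = besti, r = bestr;
    while (i >= 0 && r >= 0) {
      int j = N - 1 - r; // position on the original target
      pairing[i] = wc_pair(ms[i], ws[r]) ? '|' : ':';
      if (j < jmin) jmin = j;
      if (j > jmax) jmax = j;
      ++npairs;
      int p = PP(i, r);
      if (p < 0) break;
      i = p / N;
      r = p % N;
    }
    site_start = jmin;
    site_end = jmax + 1;
  }
  if (besti < 0) dg = 0.0;
#undef EE
#undef PP
  return List::create(_["delta_g"] = dg, _["pairing"] = pairing,
                      _["site_start"] = site_start, _["site_end"] = site_end,
                      _["n_pairs"] = npairs);
}

// All-offsets Hamming-distance mapping of reads to precursor sequences
// (forward strand). Returns one row per hit with distance <= max_mismatch.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector precursors,
                        int max_mismatch = 1) {
  int nr = reads.size(), np = precursors.size();
  std::vector<std::string> ps(np);
  for (int p = 0; p < np; ++p) ps[p] = as<std::string>(precursors[p]);
  std::vector<int> out_read, out_prec, out_start, out_mm;
  for (int q = 0; q < nr; ++q) {
    std::string rd = as<std::string>(reads[q]);
    int L = rd.size();
    for (int p = 0; p < np; ++p) {
      const std::string &pr = ps[p];
      int PL = pr.size();
      for (int s = 0; s + L <= PL; ++s) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (rd[k] != pr[s + k] && ++mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) {
          out_read.push_back(q + 1);
          out_prec.push_back(p + 1);
          out_start.push_back(s);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["precursor"] = out_prec,
                           _["start"] = out_start, _["mismatches"] = out_mm);
}

// Leftmost 3' adapter occurrence per read. Returns the 0-based position at
// which the adapter starts (trim point), or -1 if no hit. A prefix of the
// adapter must match with at most floor(rate * overlap) mismatches; overlaps
// shorter than min_overlap are admissible only when they reach the read's
// 3' terminus.
// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector reads, std::string adapter,
                                 int min_overlap = 8,
                                 double max_mismatch_rate = 0.1) {
  int nr = reads.size();
  int alen = adapter.size();
  IntegerVector out(nr);
  for (int q = 0; q < nr; ++q) {
    std::string rd = as<std::string>(reads[q]);
    int L = rd.size();
    int hit = -1;
    for (int s = 0; s < L; ++s) {
      int ov = std::min(alen, L - s);
      if (ov < min_overlap && s + ov < L) continue; // short overlap only at terminus
      int allowed = (int)std::floor(max_mismatch_rate * ov);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (rd[s + k] != adapter[k] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { hit = s; break; }
    }
    out[q] = hit;
  }
  return out;
}
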