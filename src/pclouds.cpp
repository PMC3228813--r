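#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3; case-insensitive; -1 for anything else.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Codes are returned to R as doubles: 4^k fits exactly in a double for k <= 26.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, uint32_t> tab;
  double total = 0.0;
  const uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    size_t n = strlen(p);
    uint64_t code = 0;
    int run = 0;  // length of current all-ACGT suffix
    for (size_t i = 0; i < n; ++i) {
      int b = base2bits(p[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | uint64_t(b)) & mask;
      if (++run >= k) { ++tab[code]; total += 1.0; }
    }
  }
  R_xlen_t m = tab.size();
  NumericVector codes(m);
  IntegerVector counts(m);
  R_xlen_t i = 0;
  for (auto &kv : tab) {
    codes[i] = static_cast<double>(kv.first);
    counts[i] = static_cast<int>(kv.second);
    ++i;
  }
  return List::create(_["code"] = codes, _["count"] = counts,
                      _["total_positions"] = total);
}

// [[Rcpp::export]]
NumericVector cpp_encode_oligos(CharacterVector oligos) {
  R_xlen_t n = oligos.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *p = CHAR(STRING_ELT(oligos, i));
    uint64_t code = 0;
    for (size_t j = 0; p[j]; ++j) {
      int b = base2bits(p[j]);
      if (b < 0) stop("non-ACGT symbol in oligo '%s'", p);
      code = (code << 2) | uint64_t(b);
    }
    out[i] = static_cast<double>(code);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_oligos(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = static_cast<uint64_t>(codes[i]);
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[code & 3];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_revcomp_codes(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = static_cast<uint64_t>(codes[i]);
    uint64_t rc = 0;
    for (int j = 0; j < k; ++j) {
      rc = (rc << 2) | (3 - (code & 3));  // complement, reversed order
      code >>= 2;
    }
    out[i] = static_cast<double>(rc);
  }
  return out;
}

// Greedy cloud construction.  Oligos with count >= core_cutoff are processed in
// non-increasing count order (ties by code, i.e. lexicographic on the oligo);
// each unassigned core seeds a cloud whose Hamming radius is set by the seed's
// own count against the three extension cutoffs; growth is breadth-first
// through distance-1 steps between admitted members, admitting unassigned
// oligos with count >= lower_cutoff.
// [[Rcpp::export]]
List cpp_build_clouds(NumericVector codes, IntegerVector counts, int k,
                      int lower_cutoff, int core_cutoff,
                      int ext1, int ext2, int ext3) {
  R_xlen_t n = codes.size();
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(n * 2);
  for (R_xlen_t i = 0; i < n; ++i)
    idx[static_cast<uint64_t>(codes[i])] = static_cast<int>(i);

  std::vector<int> order;
  order.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i)
    if (counts[i] >= core_cutoff) order.push_back(static_cast<int>(i));
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (counts[a] != counts[b]) return counts[a] > counts[b];
    return codes[a] < codes[b];
  });

  IntegerVector cloud(n, 0);        // 0 = unassigned
  LogicalVector is_seed(n, false);
  std::vector<int> cloud_radius;
  std::vector<double> seed_code;
  int next_cloud = 0;

  std::vector<int> frontier, nxt;
  for (int s : order) {
    if (cloud[s] != 0) continue;
    int c = counts[s];
    int radius = (c >= ext3) ? 3 : (c >= ext2) ? 2 : (c >= ext1) ? 1 : 0;
    ++next_cloud;
    cloud[s] = next_cloud;
    is_seed[s] = true;
    cloud_radius.push_back(radius);
    seed_code.push_back(codes[s]);

    frontier.clear();
    frontier.push_back(s);
    for (int depth = 1; depth <= radius && !frontier.empty(); ++depth) {
      nxt.clear();
      for (int m : frontier) {
        uint64_t code = static_cast<uint64_t>(codes[m]);
        for (int pos = 0; pos < k; ++pos) {
          uint64_t shift = uint64_t(2) * pos;
          uint64_t cur = (code >> shift) & 3;
          for (uint64_t b = 0; b < 4; ++b) {
            if (b == cur) continue;
            uint64_t nb = (code & ~(uint64_t(3) << shift)) | (b << shift);
            auto it = idx.find(nb);
            if (it == idx.end()) continue;
            int j = it->second;
            if (cloud[j] != 0 || counts[j] < lower_cutoff) continue;
            cloud[j] = next_cloud;
            nxt.push_back(j);
          }
        }
      }
      frontier.swap(nxt);
    }
  }

  return List::create(_["cloud"] = cloud, _["is_seed"] = is_seed,
                      _["radius"] = wrap(cloud_radius),
                      _["seed_code"] = wrap(seed_code));
}

// Per oligo start position: 1 if the oligo or its reverse complement is a
// cloud member, 0 if not, NA if the window contains a non-ACGT symbol.
// [[Rcpp::export]]
IntegerVector cpp_member_scan(std::string seq, int k, NumericVector member_codes) {
  std::unordered_set<uint64_t> members;
  members.reserve(member_codes.size() * 2);
  for (R_xlen_t i = 0; i < member_codes.size(); ++i)
    members.insert(static_cast<uint64_t>(member_codes[i]));

  R_xlen_t n = static_cast<R_xlen_t>(seq.size());
  R_xlen_t npos = n - k + 1;
  if (npos < 1) return IntegerVector(0);
  IntegerVector out(npos, NA_INTEGER);
  const uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  const int shift_hi = 2 * (k - 1);
  uint64_t code = 0, rc = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; code = 0; rc = 0; continue; }
    code = ((code << 2) | uint64_t(b)) & mask;
    rc = (rc >> 2) | (uint64_t(3 - b) << shift_hi);
    if (++run >= k) {
      R_xlen_t start = i - k + 1;
      out[start] = (members.count(code) || members.count(rc)) ? 1 : 0;
    }
  }
  return out;
}

// Dinucleotide (first-order) transition counts over ACGT, plus mononucleotide
// counts; pairs straddling a non-ACGT symbol are not counted.
// [[Rcpp::export]]
List cpp_dinuc_counts(std::string seq) {
  NumericMatrix trans(4, 4);
  NumericVector mono(4);
  int prev = -1;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b >= 0) {
      mono[b] += 1.0;
      if (prev >= 0) trans(prev, b) += 1.0;
    }
    prev = b;
  }
  return List::create(_["trans"] = trans, _["mono"] = mono);
}

// Simulate a first-order Markov chain over the ACGT positions of `templ`,
// copying non-ACGT symbols through verbatim; the chain restarts from `init`
// at the start and after every non-ACGT run.  Uses the R RNG.
// [[Rcpp::export]]
std::string cpp_simulate_markov(std::string templ, NumericMatrix trans,
                                NumericVector init) {
  // cumulative rows; rows that sum to ~0 fall back to init
  double cinit[4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  if (acc <= 0.0) { cinit[0] = 0.25; cinit[1] = 0.5; cinit[2] = 0.75; cinit[3] = 1.0; }
  else for (int j = 0; j < 4; ++j) cinit[j] /= acc;

  double ctrans[4][4];
  bool row_ok[4];
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); ctrans[i][j] = acc; }
    row_ok[i] = acc > 0.0;
    if (row_ok[i]) for (int j = 0; j < 4; ++j) ctrans[i][j] /= acc;
  }

  std::string out = templ;
  int prev = -1;
  for (size_t i = 0; i < out.size(); ++i) {
    if (base2bits(out[i]) < 0) { prev = -1; continue; }
    double u = unif_rand();
    const double *row = (prev >= 0 && row_ok[prev]) ? ctrans[prev] : cinit;
    int b = 0;
    while (b < 3 && u > row[b]) ++b;
    out[i] = BITS2BASE[b];
    prev = b;
  }
  return out;
}
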