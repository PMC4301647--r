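#include <Rcpp.h>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Suffix array by direct suffix sort. Genomes here are small (<= a few Mb)
// and near-random, so plain strcmp-based sorting is fast enough and simple.
// [[Rcpp::export(name = ".sa_build")]]
IntegerVector sa_build(std::string text) {
  const int n = (int) text.size();
  const char *s = text.c_str();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return std::strcmp(s + a, s + b) < 0; });
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = idx[i];
  return out;
}

static int cmp_at(const std::string &text, int pos, const std::string &q) {
  // compare text[pos..pos+|q|) with q; suffix shorter than q compares short
  return text.compare(pos, q.size(), q);
}

// all start positions (0-based, unsorted) where q occurs exactly in text
static void sa_hits(const std::string &text, const IntegerVector &sa,
                    const std::string &q, std::vector<int> &out) {
  const int n = sa.size();
  int lo = 0, hi = n;
  while (lo < hi) {  // lower bound
    int mid = (lo + hi) / 2;
    if (cmp_at(text, sa[mid], q) < 0) lo = mid + 1; else hi = mid;
  }
  int first = lo;
  hi = n;
  while (lo < hi) {  // upper bound
    int mid = (lo + hi) / 2;
    if (cmp_at(text, sa[mid], q) <= 0) lo = mid + 1; else hi = mid;
  }
  for (int i = first; i < lo; ++i) out.push_back(sa[i]);
}

// [[Rcpp::export(name = ".sa_find")]]
IntegerVector sa_find(std::string text, IntegerVector sa, std::string query) {
  std::vector<int> hits;
  sa_hits(text, sa, query, hits);
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

struct Placement {
  int gpos;    // 0-based leftmost genome coordinate
  char strand;
};

// translate a text start position into genome coordinate + strand.
// Text layout: fwd_ext [ '#' rc_ext ] where fwd_ext = genome (+ circular pad)
// and rc_ext = reverse complement of fwd_ext.
static Placement place(int p, int fwd_len, int genome_len, int m) {
  Placement pl;
  if (p < fwd_len) {
    pl.gpos = p % genome_len;
    pl.strand = '+';
  } else {
    int q = p - fwd_len - 1;                  // position within rc_ext
    pl.gpos = (fwd_len - q - m) % genome_len; // leftmost fwd coordinate
    if (pl.gpos < 0) pl.gpos += genome_len;
    pl.strand = '-';
  }
  return pl;
}

static bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Map reads with the unique-hit policy:
//   exactly one exact hit -> unique_exact (1)
//   >=2 exact hits        -> ambiguous   (3)
//   0 exact, one 1-mismatch hit  -> unique_one_mismatch (2)
//   0 exact, >=2 1-mismatch hits -> ambiguous (3)
//   otherwise unmapped (0)
// One-mismatch search enumerates the 3 alternative bases at every read
// position (all 4 at an N, which matches no base) and does exact suffix-array
// lookups of each variant; distinct variants cannot share a hit position, so
// every 1-mismatch placement is found exactly once.
// [[Rcpp::export(name = ".sa_map_reads")]]
List sa_map_reads(std::string text, IntegerVector sa, CharacterVector reads,
                  int fwd_len, int genome_len) {
  const int nr = reads.size();
  IntegerVector status(nr), pos(nr), mm(nr);
  CharacterVector strand(nr);
  const char *bases = "ACGT";
  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int m = (int) read.size();
    int nN = 0;
    for (int i = 0; i < m; ++i) {
      if (!is_acgt(read[i])) { read[i] = 'N'; ++nN; }
    }
    std::vector<int> hits;
    int st = 0, mmv = NA_INTEGER, gp = NA_INTEGER;
    std::string sd = "";
    if (nN == 0) {
      sa_hits(text, sa, read, hits);
      if (hits.size() == 1) { st = 1; mmv = 0; }
      else if (hits.size() >= 2) st = 3;
    }
    if (st == 0 && nN <= 1) {
      hits.clear();
      for (int i = 0; i < m; ++i) {
        if (nN == 1 && read[i] != 'N') continue;  // mismatch budget spent at N
        const char orig = read[i];
        std::string var = read;
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == orig) continue;
          var[i] = bases[b];
          sa_hits(text, sa, var, hits);
          if (hits.size() > 1) break;  // already ambiguous
        }
        if (hits.size() > 1) break;
      }
      if (hits.size() == 1) { st = 2; mmv = 1; }
      else if (hits.size() >= 2) st = 3;
    }
    if (st == 1 || st == 2) {
      Placement pl = place(hits[0], fwd_len, genome_len, m);
      gp = pl.gpos + 1;  // 1-based
      sd = pl.strand;
    }
    status[r] = st;
    pos[r] = gp;
    mm[r] = mmv;
    strand[r] = (st == 1 || st == 2) ? String(sd) : NA_STRING;
  }
  return List::create(_["status"] = status, _["position"] = pos,
                      _["strand"] = strand, _["mismatches"] = mm);
}
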