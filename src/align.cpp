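#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Ungapped alignment kernels. Reads are short (15-150 nt), references are
// viral/organellar scale (kb), so a 7-mer positional index plus pigeonhole
// seeding (max_mm + 1 disjoint blocks; one must be clean) is enough.

static const int KSEED = 7;

static inline int base2code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1; // N or other
  }
}

static bool hash_kmer(const std::string& s, size_t off, uint32_t& h) {
  h = 0;
  for (int i = 0; i < KSEED; ++i) {
    int c = base2code(s[off + i]);
    if (c < 0) return false;
    h = (h << 2) | (uint32_t)c;
  }
  return true;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// mismatches of read placed at ref[start..start+len), early exit beyond cap
static int count_mm(const std::string& ref, const std::string& read,
                    int start, int cap) {
  int mm = 0;
  const int len = (int)read.size();
  for (int i = 0; i < len; ++i) {
    if (ref[start + i] != read[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Placement {
  int start = -1, mm = 0, strand = 0; // strand 0 = '+', 1 = '-'
  bool set = false;
  // ordering: fewer mm, then lower start, then '+' before '-'
  bool better_than(const Placement& o) const {
    if (!o.set) return true;
    if (mm != o.mm) return mm < o.mm;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
};

// [[Rcpp::export]]
DataFrame cpp_map_reads(std::string ref, CharacterVector reads, int max_mm) {
  const int rl = (int)ref.size();
  // positional 7-mer index of the reference
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(rl * 2);
  for (int p = 0; p + KSEED <= rl; ++p) {
    uint32_t h;
    if (hash_kmer(ref, p, h)) index[h].push_back(p);
  }
  std::vector<int> out_read, out_start, out_len, out_mm;
  std::vector<int> out_strand;
  std::vector<char> tried(rl, 0);

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len == 0 || len > rl) continue;
    std::string rev = revcomp_str(fwd);
    Placement best;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = (ori == 0) ? fwd : rev;
      std::vector<int> cand;
      int block = len / (max_mm + 1);
      if (block >= KSEED) {
        for (int b = 0; b <= max_mm; ++b) {
          int off = b * block;
          uint32_t h;
          if (!hash_kmer(rd, off, h)) continue;
          auto it = index.find(h);
          if (it == index.end()) continue;
          for (int p : it->second) {
            int st = p - off;
            if (st >= 0 && st + len <= rl) cand.push_back(st);
          }
        }
      } else {
        for (int st = 0; st + len <= rl; ++st) cand.push_back(st);
      }
      // dedupe candidates cheaply
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int st : cand) {
        int mm = count_mm(ref, rd, st, max_mm);
        if (mm <= max_mm) {
          Placement pl; pl.start = st; pl.mm = mm; pl.strand = ori; pl.set = true;
          if (pl.better_than(best)) best = pl;
        }
      }
    }
    if (best.set) {
      out_read.push_back(r + 1);
      out_start.push_back(best.start);
      out_len.push_back(len);
      out_strand.push_back(best.strand);
      out_mm.push_back(best.mm);
    }
  }
  CharacterVector strand(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand[i] = out_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["read"] = out_read, _["start"] = out_start, _["length"] = out_len,
    _["strand"] = strand, _["mismatches"] = out_mm,
    _["stringsAsFactors"] = false);
}

// Glocal scan for assembly: allow the read to hang off either contig end as
// long as the overlapping region is >= min_overlap with <= max_mm
// substitutions. pos may be negative (left overhang). Best placement per
// read: fewest mm, then longest overlap, then lowest pos, '+' before '-'.
// [[Rcpp::export]]
DataFrame cpp_overlap_scan(std::string contig, CharacterVector reads,
                           int min_overlap, int max_mm) {
  const int cl = (int)contig.size();
  std::vector<int> out_read, out_pos, out_mm, out_ov;
  std::vector<int> out_strand;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len < min_overlap) continue;
    std::string rev = revcomp_str(fwd);
    bool set = false;
    int b_pos = 0, b_mm = 0, b_ov = 0, b_strand = 0;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = (ori == 0) ? fwd : rev;
      for (int p = -(len - min_overlap); p <= cl - min_overlap; ++p) {
        int a = std::max(0, -p);             // first read index in overlap
        int b = std::min(len, cl - p);       // one past last read index
        int ov = b - a;
        if (ov < min_overlap) continue;
        int mm = 0; bool ok = true;
        for (int i = a; i < b; ++i) {
          if (contig[p + i] != rd[i]) {
            if (++mm > max_mm) { ok = false; break; }
          }
        }
        if (!ok) continue;
        bool better = !set;
        if (set) {
          if (mm != b_mm) better = mm < b_mm;
          else if (ov != b_ov) better = ov > b_ov;
          else if (p != b_pos) better = p < b_pos;
          else better = ori < b_strand;
        }
        if (better) {
          set = true; b_pos = p; b_mm = mm; b_ov = ov; b_strand = ori;
        }
      }
    }
    if (set) {
      out_read.push_back(r + 1);
      out_pos.push_back(b_pos);
      out_mm.push_back(b_mm);
      out_ov.push_back(b_ov);
      out_strand.push_back(b_strand);
    }
  }
  CharacterVector strand(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand[i] = out_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["read"] = out_read, _["pos"] = out_pos, _["strand"] = strand,
    _["mismatches"] = out_mm, _["overlap"] = out_ov,
    _["stringsAsFactors"] = false);
}
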