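// Seed-and-extend ungapped read matching (exact k-mer seed, mismatch-bounded
// verification), mirroring a megablast-style word search for near-identical
// sequences. Two entry points: probe containment counting, and best ungapped
// placement of reads on a region with clipping at region edges.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static std::string revcomp(const std::string& s) {
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

// count of reads containing each probe (full probe within read,
// <= max_mm mismatches over the probe; each read counted once per probe)
// [[Rcpp::export]]
IntegerVector count_hits_cpp(CharacterVector probes, CharacterVector reads,
                             int max_mm, int seed_len, bool both_strands) {
  int np = probes.size(), nr = reads.size();
  std::vector<std::string> pr(np);
  for (int p = 0; p < np; ++p) pr[p] = as<std::string>(probes[p]);

  // seed index: disjoint k-mers of each probe -> (probe, offset)
  std::unordered_map<std::string, std::vector<std::pair<int,int> > > idx;
  for (int p = 0; p < np; ++p) {
    int plen = (int) pr[p].size();
    for (int off = 0; off + seed_len <= plen; off += seed_len)
      idx[pr[p].substr(off, seed_len)].push_back(std::make_pair(p, off));
    if (plen % seed_len != 0 && plen >= seed_len)
      idx[pr[p].substr(plen - seed_len, seed_len)]
        .push_back(std::make_pair(p, plen - seed_len));
  }

  IntegerVector counts(np);
  std::vector<int> seen(np, -1);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string s = (strand == 0) ? rd : revcomp(rd);
      int rlen = (int) s.size();
      for (int q = 0; q + seed_len <= rlen; ++q) {
        auto it = idx.find(s.substr(q, seed_len));
        if (it == idx.end()) continue;
        for (auto& cand : it->second) {
          int p = cand.first, off = cand.second;
          if (seen[p] == r) continue;
          int start = q - off;
          int plen = (int) pr[p].size();
          if (start < 0 || start + plen > rlen) continue;
          int mm = 0;
          for (int k = 0; k < plen && mm <= max_mm; ++k)
            if (pr[p][k] != s[start + k]) ++mm;
          if (mm <= max_mm) { seen[p] = r; counts[p]++; }
        }
      }
    }
  }
  return counts;
}

// best ungapped placement of each read on a region. The placement offset is
// fixed by an exact seed; the overlap is the full intersection of read and
// region under that offset (clipped at region edges) and must carry
// <= max_mm mismatches and >= min_overlap columns. Returns one row per
// matched read: region start/end, read start/end (on the matched strand),
// mismatches, strand.
// [[Rcpp::export]]
DataFrame match_reads_cpp(CharacterVector reads, std::string region,
                          int max_mm, int seed_len, int min_overlap,
                          bool both_strands) {
  int glen = (int) region.size();
  std::unordered_map<std::string, std::vector<int> > idx;
  for (int j = 0; j + seed_len <= glen; ++j)
    idx[region.substr(j, seed_len)].push_back(j);

  std::vector<int> o_read, o_rs, o_re, o_gs, o_ge, o_mm;
  std::vector<std::string> o_strand;

  int nr = reads.size();
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    bool found = false;
    int b_gs = 0, b_ge = 0, b_rs = 0, b_re = 0, b_mm = 0;
    double b_score = -1e18;
    std::string b_strand = "+";

    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string s = (strand == 0) ? rd : revcomp(rd);
      int rlen = (int) s.size();
      std::vector<int> tried; // candidate offsets d = gpos - q
      for (int q = 0; q + seed_len <= rlen; ++q) {
        auto it = idx.find(s.substr(q, seed_len));
        if (it == idx.end()) continue;
        for (int gpos : it->second) {
          int d = gpos - q;
          bool dup = false;
          for (int t : tried) if (t == d) { dup = true; break; }
          if (dup) continue;
          tried.push_back(d);
          int i0 = std::max(0, -d);           // read coords of overlap
          int i1 = std::min(rlen, glen - d);  // exclusive
          int ov = i1 - i0;
          if (ov < min_overlap) continue;
          int mm = 0;
          for (int k = i0; k < i1 && mm <= max_mm; ++k)
            if (s[k] != region[k + d]) ++mm;
          if (mm > max_mm) continue;
          // trim edge mismatches
          int s0 = i0, s1 = i1;
          while (s0 < s1 && s[s0] != region[s0 + d]) { ++s0; --mm; }
          while (s1 > s0 && s[s1 - 1] != region[s1 - 1 + d]) { --s1; --mm; }
          if (s1 - s0 < min_overlap) continue;
          double score = (s1 - s0) - 4.0 * mm;
          if (score > b_score ||
              (score == b_score && (s0 + d) < b_gs - 1)) {
            b_score = score; found = true;
            b_gs = s0 + d + 1; b_ge = s1 + d; // 1-based region coords
            b_rs = s0 + 1; b_re = s1;         // 1-based read coords (strand s)
            b_mm = mm; b_strand = (strand == 0) ? "+" : "-";
          }
        }
      }
    }
    if (found) {
      o_read.push_back(r + 1);
      o_gs.push_back(b_gs); o_ge.push_back(b_ge);
      o_rs.push_back(b_rs); o_re.push_back(b_re);
      o_mm.push_back(b_mm); o_strand.push_back(b_strand);
    }
  }
  return DataFrame::create(_["read"] = o_read,
                           _["start"] = o_gs, _["end"] = o_ge,
                           _["read_start"] = o_rs, _["read_end"] = o_re,
                           _["mismatches"] = o_mm, _["strand"] = o_strand,
                           _["stringsAsFactors"] = false);
}
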