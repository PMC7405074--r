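#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Offline most-compressive-motif heuristic over an integer symbol sequence.
// Symbol 0 is a reserved break sentinel (mask / window boundary): candidate
// motifs never span it and it is never replaced.
//
// Savings for a motif of length W occurring N times (non-overlapping):
//   W*N - (W + 1 + N)
// Each iteration replaces every greedily counted (left-to-right,
// non-overlapping) occurrence of the argmax-savings motif with a fresh
// symbol; ties prefer larger savings, then longer W, then the
// lexicographically smallest definition. Stops when no motif saves > 0.

namespace {

inline uint64_t mix(uint64_t h, int x) {
  h ^= static_cast<uint64_t>(static_cast<uint32_t>(x)) + 0x9e3779b97f4a7c15ULL;
  h *= 0x100000001b3ULL;
  return h;
}

struct Entry {
  int first_pos;   // position of first occurrence (defines the gram)
  int last_end;    // end index of last counted occurrence
  long long n;     // greedy non-overlapping count
};

bool gram_equal(const std::vector<int> &s, int a, int b, int W) {
  for (int j = 0; j < W; ++j)
    if (s[a + j] != s[b + j]) return false;
  return true;
}

bool gram_lex_less(const std::vector<int> &s, int a, int b, int W) {
  for (int j = 0; j < W; ++j) {
    if (s[a + j] < s[b + j]) return true;
    if (s[a + j] > s[b + j]) return false;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
List compress_cpp(IntegerVector seq, int max_len, int first_new_symbol) {
  std::vector<int> cur(seq.begin(), seq.end());
  long long orig_len = 0;
  for (int x : cur)
    if (x != 0) ++orig_len;

  std::vector<std::vector<int>> rule_defs;
  std::vector<int> rule_syms, rule_sav, rule_cnt;
  int next_sym = first_new_symbol;
  long long total_sav = 0;

  std::unordered_map<uint64_t, Entry> tab;
  // rare true-collision fallback keyed by explicit grams
  std::vector<std::pair<std::vector<int>, Entry>> spill;

  while (true) {
    const int n = static_cast<int>(cur.size());
    if (n < 2) break;

    long long best_sav = 0;
    int best_W = 0, best_pos = -1;

    const int maxW = std::min(max_len, n);
    for (int W = 2; W <= maxW; ++W) {
      tab.clear();
      spill.clear();
      for (int i = 0; i + W <= n; ++i) {
        bool ok = true;
        for (int j = i; j < i + W; ++j)
          if (cur[j] == 0) { ok = false; break; }
        if (!ok) continue;

        uint64_t h = 1469598103934665603ULL;
        for (int j = i; j < i + W; ++j) h = mix(h, cur[j]);

        auto it = tab.find(h);
        if (it == tab.end()) {
          tab.emplace(h, Entry{i, i + W - 1, 1});
        } else if (gram_equal(cur, it->second.first_pos, i, W)) {
          if (i > it->second.last_end) {
            ++it->second.n;
            it->second.last_end = i + W - 1;
          }
        } else {
          // hash collision: search / extend spill list
          bool found = false;
          for (auto &sp : spill) {
            if (static_cast<int>(sp.first.size()) == W &&
                std::equal(sp.first.begin(), sp.first.end(),
                           cur.begin() + i)) {
              if (i > sp.second.last_end) {
                ++sp.second.n;
                sp.second.last_end = i + W - 1;
              }
              found = true;
              break;
            }
          }
          if (!found)
            spill.emplace_back(
                std::vector<int>(cur.begin() + i, cur.begin() + i + W),
                Entry{i, i + W - 1, 1});
        }
      }

      auto consider = [&](const Entry &e) {
        if (e.n < 2) return;
        long long sav =
            static_cast<long long>(W) * e.n - (W + 1 + e.n);
        if (sav <= 0) return;
        bool better = false;
        if (sav > best_sav) better = true;
        else if (sav == best_sav) {
          if (W > best_W) better = true;
          else if (W == best_W && best_pos >= 0 &&
                   gram_lex_less(cur, e.first_pos, best_pos, W))
            better = true;
        }
        if (better) {
          best_sav = sav;
          best_W = W;
          best_pos = e.first_pos;
        }
      };
      for (auto &kv : tab) consider(kv.second);
      for (auto &sp : spill) consider(sp.second);
    }

    if (best_sav <= 0) break;

    std::vector<int> def(cur.begin() + best_pos,
                         cur.begin() + best_pos + best_W);
    std::vector<int> out;
    out.reserve(n);
    int cnt = 0, i = 0;
    while (i < n) {
      bool m = (i + best_W <= n);
      if (m)
        for (int j = 0; j < best_W; ++j)
          if (cur[i + j] != def[j]) { m = false; break; }
      if (m) {
        out.push_back(next_sym);
        i += best_W;
        ++cnt;
      } else {
        out.push_back(cur[i]);
        ++i;
      }
    }

    rule_defs.push_back(def);
    rule_syms.push_back(next_sym);
    rule_sav.push_back(static_cast<int>(best_sav));
    rule_cnt.push_back(cnt);
    total_sav += best_sav;
    ++next_sym;
    cur.swap(out);
  }

  List defs(rule_defs.size());
  for (size_t r = 0; r < rule_defs.size(); ++r)
    defs[r] = IntegerVector(rule_defs[r].begin(), rule_defs[r].end());

  return List::create(
      _["rule_symbols"] = IntegerVector(rule_syms.begin(), rule_syms.end()),
      _["rule_defs"] = defs,
      _["savings"] = IntegerVector(rule_sav.begin(), rule_sav.end()),
      _["counts"] = IntegerVector(rule_cnt.begin(), rule_cnt.end()),
      _["compressed"] = IntegerVector(cur.begin(), cur.end()),
      _["original_length"] = static_cast<double>(orig_len),
      _["total_savings"] = static_cast<double>(total_sav));
}

// Count occurrences of each motif (list of integer vectors, no sentinels)
// in seq. overlap = true counts every sliding-window match; overlap = false
// counts greedily left-to-right per motif. Matches never span the sentinel 0.

// [[Rcpp::export]]
IntegerVector count_motifs_cpp(IntegerVector seq, List motifs, bool overlap) {
  const int m = motifs.size();
  IntegerVector counts(m);
  if (m == 0) return counts;

  std::vector<std::vector<int>> defs(m);
  int max_w = 0;
  for (int k = 0; k < m; ++k) {
    IntegerVector v = motifs[k];
    defs[k].assign(v.begin(), v.end());
    max_w = std::max(max_w, static_cast<int>(v.size()));
  }

  // per-length hash -> candidate motif indices
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(m * 2);
  for (int k = 0; k < m; ++k) {
    uint64_t h = 1469598103934665603ULL;
    for (int x : defs[k]) h = mix(h, x);
    h = mix(h, static_cast<int>(defs[k].size())); // length-salted
    idx[h].push_back(k);
  }

  const int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> next_ok(m, 0); // for non-overlapping counting

  for (int i = 0; i < n; ++i) {
    if (s[i] == 0) continue;
    uint64_t h = 1469598103934665603ULL;
    for (int W = 1; W <= max_w && i + W <= n; ++W) {
      if (s[i + W - 1] == 0) break;
      h = mix(h, s[i + W - 1]);
      if (W < 2) continue;
      uint64_t hk = mix(h, W);
      auto it = idx.find(hk);
      if (it == idx.end()) continue;
      for (int k : it->second) {
        if (static_cast<int>(defs[k].size()) != W) continue;
        bool match = true;
        for (int j = 0; j < W; ++j)
          if (defs[k][j] != s[i + j]) { match = false; break; }
        if (!match) continue;
        if (overlap) {
          ++counts[k];
        } else if (i >= next_ok[k]) {
          ++counts[k];
          next_ok[k] = i + W;
        }
      }
    }
  }
  return counts;
}
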