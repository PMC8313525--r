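#include <Rcpp.h>
#include <vector>
#include <map>

// Lempel-Ziv match lengths via an online suffix automaton.
//
// For position j (0-based) the value is m + 1, where m is the length of the
// longest prefix of s[j..n-1] occurring as a contiguous substring of the
// prefix s[0..j-1]. This covers the end-of-sequence boundary convention
// (whole suffix found in prefix -> n - j + 2, counting 1-based) uniformly.
//
// The automaton of s[0..j-1] recognises exactly its substrings, so the match
// is read off by walking transitions; the automaton is then extended by
// s[j]. Total cost is O(n log sigma + sum of match lengths).

namespace {

struct SuffixAutomaton {
  std::vector<int> len, link;
  std::vector<std::map<int, int> > next;
  int last;

  explicit SuffixAutomaton(int reserve_n) {
    len.reserve(2 * reserve_n + 4);
    link.reserve(2 * reserve_n + 4);
    next.reserve(2 * reserve_n + 4);
    len.push_back(0);
    link.push_back(-1);
    next.push_back(std::map<int, int>());
    last = 0;
  }

  int new_state(int l, int lk) {
    len.push_back(l);
    link.push_back(lk);
    next.push_back(std::map<int, int>());
    return (int)len.size() - 1;
  }

  void extend(int c) {
    int cur = new_state(len[last] + 1, -1);
    int p = last;
    while (p != -1 && next[p].find(c) == next[p].end()) {
      next[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = next[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q]);
        next[clone] = next[q];
        link[q] = clone;
        link[cur] = clone;
        while (p != -1 && next[p][c] == q) {
          next[p][c] = clone;
          p = link[p];
        }
      }
    }
    last = cur;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector lz_lambda_cpp(Rcpp::IntegerVector s) {
  int n = s.size();
  Rcpp::IntegerVector lambda(n);
  SuffixAutomaton sam(n);
  for (int j = 0; j < n; ++j) {
    int cur = 0;
    int m = 0;
    for (int k = j; k < n; ++k) {
      std::map<int, int>::const_iterator it = sam.next[cur].find(s[k]);
      if (it == sam.next[cur].end()) break;
      cur = it->second;
      ++m;
    }
    lambda[j] = m + 1;
    sam.extend(s[j]);
  }
  return lambda;
}
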