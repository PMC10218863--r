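#include <Rcpp.h>
#include <set>
#include <stack>
#include <vector>
using namespace Rcpp;

// Watson-Crick + GU wobble; T treated as U; IUPAC ambiguity codes unpairable.
static inline bool can_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization over nested structures with a minimum hairpin size
// (at least min_hairpin unpaired positions between any paired i < j) and an
// optional set of forbidden pairs (1-based positions).  Traceback is
// deterministic: leave i unpaired whenever that attains the optimum, else
// pair i with the smallest admissible k.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
std::string nussinov_fold_cpp(std::string seq, int min_hairpin,
                              IntegerVector forbid_i, IntegerVector forbid_j) {
  int n = (int)seq.size();
  std::string db(n, '.');
  if (n == 0) return db;

  std::set<std::pair<int, int> > forb;
  for (int k = 0; k < forbid_i.size(); ++k)
    forb.insert(std::make_pair(forbid_i[k] - 1, forbid_j[k] - 1));

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        if (forb.count(std::make_pair(i, k))) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
        int cand = inner + 1 + outer;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j) continue;
    if (M[i][j] == ((i + 1 <= j) ? M[i + 1][j] : 0)) {
      todo.push(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_hairpin + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      if (forb.count(std::make_pair(i, k))) continue;
      int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
      int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (inner + 1 + outer == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        todo.push(std::make_pair(i + 1, k - 1));
        todo.push(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return db;
}
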