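#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <queue>
#include <string>
#include <vector>
using namespace Rcpp;

// FNV-1a 32-bit: fixed, platform-independent string hash.
static inline uint32_t fnv1a(const std::string &s) {
  uint32_t h = 2166136261u;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint32_t)(unsigned char)s[i];
    h *= 16777619u;
  }
  return h;
}

// Neighborhood-subgraph pair features on a vertex-labeled graph: for every
// vertex pair (u, v) with shortest-path distance d <= max_distance and every
// radius r <= max_radius, the canonical strings of the radius-r neighborhoods
// rooted at u and v (sorted labels per BFS layer) are combined with d and
// hashed to [0, 2^hash_bits).  Returns the accumulated weight per index.
// Edges are given 1-based; the graph is undirected.
// [[Rcpp::export(name = ".nspdk_features_cpp")]]
List nspdk_features_cpp(CharacterVector labels, IntegerVector from,
                        IntegerVector to, int max_radius, int max_distance,
                        int hash_bits) {
  int n = labels.size();
  std::vector<std::string> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = as<std::string>(labels[i]);

  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < from.size(); ++e) {
    int a = from[e] - 1, b = to[e] - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }

  int depth = std::max(max_radius, max_distance);
  // BFS distances (capped at depth) from every vertex.
  std::vector<std::vector<int> > dist(n, std::vector<int>(n, -1));
  for (int s = 0; s < n; ++s) {
    std::queue<int> q;
    dist[s][s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      if (dist[s][u] >= depth) continue;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int w = adj[u][k];
        if (dist[s][w] < 0) {
          dist[s][w] = dist[s][u] + 1;
          q.push(w);
        }
      }
    }
  }

  // Canonical neighborhood signature per (vertex, radius).
  std::vector<std::vector<std::string> > sig(
      n, std::vector<std::string>(max_radius + 1));
  for (int v = 0; v < n; ++v) {
    for (int r = 0; r <= max_radius; ++r) {
      std::string s;
      for (int d = 0; d <= r; ++d) {
        std::vector<std::string> layer;
        for (int u = 0; u < n; ++u)
          if (dist[v][u] == d) layer.push_back(lab[u]);
        std::sort(layer.begin(), layer.end());
        if (d > 0) s += ";";
        for (size_t k = 0; k < layer.size(); ++k) {
          if (k > 0) s += ",";
          s += layer[k];
        }
      }
      sig[v][r] = s;
    }
  }

  uint32_t mask = (hash_bits >= 32) ? 0xffffffffu
                                    : ((uint32_t(1) << hash_bits) - 1u);
  std::map<uint32_t, double> acc;
  for (int u = 0; u < n; ++u) {
    for (int v = u; v < n; ++v) {
      int d = dist[u][v];
      if (d < 0 || d > max_distance) continue;
      for (int r = 0; r <= max_radius; ++r) {
        const std::string &a = sig[u][r];
        const std::string &b = sig[v][r];
        std::string feat = (a <= b) ? (a + "|" + b) : (b + "|" + a);
        feat += "#";
        feat += std::to_string(d);
        feat += "@";
        feat += std::to_string(r);
        acc[fnv1a(feat) & mask] += 1.0;
      }
    }
  }

  IntegerVector idx(acc.size());
  NumericVector w(acc.size());
  int k = 0;
  for (std::map<uint32_t, double>::const_iterator it = acc.begin();
       it != acc.end(); ++it, ++k) {
    idx[k] = (int)it->first;  // 0-based
    w[k] = it->second;
  }
  return List::create(_["index"] = idx, _["weight"] = w);
}
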