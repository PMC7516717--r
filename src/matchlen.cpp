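#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Online suffix automaton over the reference stream's past. States recognize
// exactly the set of substrings of the text appended so far; longest_match
// walks a pattern greedily from the initial state, so the walk length is the
// longest prefix of the pattern occurring as a substring of the past.
struct SuffixAutomaton {
  std::vector<std::map<int, int>> nxt;
  std::vector<int> link, len;
  int last;

  SuffixAutomaton() {
    nxt.emplace_back();
    link.push_back(-1);
    len.push_back(0);
    last = 0;
  }

  int new_state(int l, int lk, const std::map<int, int>& tr) {
    nxt.push_back(tr);
    link.push_back(lk);
    len.push_back(l);
    return (int)nxt.size() - 1;
  }

  void extend(int c) {
    int cur = new_state(len[last] + 1, -1, std::map<int, int>());
    int p = last;
    while (p != -1 && nxt[p].find(c) == nxt[p].end()) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q], nxt[q]);
        while (p != -1) {
          std::map<int, int>::iterator it = nxt[p].find(c);
          if (it == nxt[p].end() || it->second != q) break;
          it->second = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }

  int longest_match(const int* pat, int from, int n) const {
    int s = 0, L = 0;
    for (int p = from; p < n; ++p) {
      std::map<int, int>::const_iterator it = nxt[s].find(pat[p]);
      if (it == nxt[s].end()) break;
      s = it->second;
      ++L;
    }
    return L;
  }
};

// Match lengths Lambda_t of `a` against the past of `b` under strict temporal
// precedence: position t of `a` may only match substrings of the b-words with
// time(b) < time(a_t). Lambda_t = (longest seen prefix) + 1, which also
// implements the end-of-sequence convention (remaining + 1 when a is
// exhausted while still matching).
// [[Rcpp::export]]
IntegerVector cross_match_lengths_cpp(IntegerVector a_words, IntegerVector a_times,
                                      IntegerVector b_words, IntegerVector b_times) {
  int ta = a_words.size(), tb = b_words.size();
  IntegerVector lambdas(ta);
  SuffixAutomaton sam;
  const int* aw = INTEGER(a_words);
  int j = 0;
  for (int t = 0; t < ta; ++t) {
    while (j < tb && b_times[j] < a_times[t]) sam.extend(b_words[j++]);
    lambdas[t] = sam.longest_match(aw, t, ta) + 1;
  }
  return lambdas;
}

// Self match lengths for the entropy-rate estimator: the past of position t
// is the stream's first t-1 words (matches fully contained in the past).
// [[Rcpp::export]]
IntegerVector self_match_lengths_cpp(IntegerVector words) {
  int n = words.size();
  IntegerVector lambdas(n);
  SuffixAutomaton sam;
  const int* w = INTEGER(words);
  for (int t = 0; t < n; ++t) {
    lambdas[t] = sam.longest_match(w, t, n) + 1;
    sam.extend(w[t]);
  }
  return lambdas;
}

static bool connected_after(const std::vector<std::vector<int>>& adj, int n) {
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.push_back(0);
  seen[0] = 1;
  int count = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int u = adj[v][i];
      if (!seen[u]) {
        seen[u] = 1;
        ++count;
        stack.push_back(u);
      }
    }
  }
  return count == n;
}

static bool has_edge(const std::vector<std::vector<int>>& adj, int a, int b) {
  const std::vector<int>& na = adj[a];
  for (size_t i = 0; i < na.size(); ++i)
    if (na[i] == b) return true;
  return false;
}

static void drop_edge(std::vector<std::vector<int>>& adj, int a, int b) {
  std::vector<int>& na = adj[a];
  for (size_t i = 0; i < na.size(); ++i)
    if (na[i] == b) {
      na[i] = na.back();
      na.pop_back();
      break;
    }
}

// Degree-preserving x-swap randomization with connectivity preservation.
// `el` is a 1-based edge list (m x 2). Attempts `n_swaps` double edge swaps;
// a swap is admissible if it creates no self-loop or parallel edge, and the
// batch of swaps since the last check is reverted if the graph disconnects.
// [[Rcpp::export]]
IntegerMatrix xswap_cpp(IntegerMatrix el, int n, int n_swaps, int check_every) {
  int m = el.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<std::pair<int, int>> edges(m);
  for (int e = 0; e < m; ++e) {
    int a = el(e, 0) - 1, b = el(e, 1) - 1;
    edges[e] = std::make_pair(a, b);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  if (check_every < 1) check_every = 1;

  // batch journal for reverts: (edge index, old pair, new pair)
  struct Rec { int e; std::pair<int, int> oldp, newp; };
  std::vector<Rec> journal;
  int accepted_in_batch = 0;

  GetRNGstate();
  for (int it = 0; it < n_swaps; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    int na1, nb1, na2, nb2; // proposed edges (na1,nb1), (na2,nb2)
    if (unif_rand() < 0.5) {
      na1 = a; nb1 = d; na2 = c; nb2 = b;
    } else {
      na1 = a; nb1 = c; na2 = b; nb2 = d;
    }
    if (na1 == nb1 || na2 == nb2) continue;                    // self-loop
    if ((na1 == na2 && nb1 == nb2) || (na1 == nb2 && nb1 == na2)) continue;
    if (has_edge(adj, na1, nb1) || has_edge(adj, na2, nb2)) continue;
    // apply
    drop_edge(adj, a, b); drop_edge(adj, b, a);
    drop_edge(adj, c, d); drop_edge(adj, d, c);
    adj[na1].push_back(nb1); adj[nb1].push_back(na1);
    adj[na2].push_back(nb2); adj[nb2].push_back(na2);
    Rec r1 = {e1, edges[e1], std::make_pair(na1, nb1)};
    Rec r2 = {e2, edges[e2], std::make_pair(na2, nb2)};
    journal.push_back(r1);
    journal.push_back(r2);
    edges[e1] = std::make_pair(na1, nb1);
    edges[e2] = std::make_pair(na2, nb2);
    if (++accepted_in_batch >= check_every) {
      if (!connected_after(adj, n)) {
        for (int k = (int)journal.size() - 1; k >= 0; --k) {
          const Rec& r = journal[k];
          drop_edge(adj, r.newp.first, r.newp.second);
          drop_edge(adj, r.newp.second, r.newp.first);
          adj[r.oldp.first].push_back(r.oldp.second);
          adj[r.oldp.second].push_back(r.oldp.first);
          edges[r.e] = r.oldp;
        }
      }
      journal.clear();
      accepted_in_batch = 0;
    }
  }
  // leftover partial batch
  if (!journal.empty() && !connected_after(adj, n)) {
    for (int k = (int)journal.size() - 1; k >= 0; --k) {
      const Rec& r = journal[k];
      drop_edge(adj, r.newp.first, r.newp.second);
      drop_edge(adj, r.newp.second, r.newp.first);
      adj[r.oldp.first].push_back(r.oldp.second);
      adj[r.oldp.second].push_back(r.oldp.first);
      edges[r.e] = r.oldp;
    }
  }
  PutRNGstate();

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = edges[e].first + 1;
    out(e, 1) = edges[e].second + 1;
  }
  return out;
}
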