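// Connected-subgraph fingerprint core.
//
// Enumerates all connected induced subgraphs with between min_atoms and
// max_atoms vertices (ESU / Wernicke enumeration: each vertex set visited
// exactly once) and aggregates them by an exact canonical signature obtained
// by minimizing a label string over all vertex permutations (feature sizes
// are small, so brute force is cheap and collision-free).

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Rec {
  int count = 0;        // distinct atom sets with this signature
  int marked = 0;       // instances whose atoms are all real and all marked
  int nreal = 0;        // real (non-wildcard) atoms per instance
};

std::string canon_sig(const std::vector<int>& verts,
                      const std::vector<std::string>& labels,
                      const std::vector<std::vector<char> >& bmat) {
  const int m = (int)verts.size();
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end());
  std::string best;
  bool have = false;
  std::string cand;
  do {
    cand.clear();
    for (int i = 0; i < m; ++i) {
      cand += labels[verts[idx[i]]];
      cand += ',';
    }
    cand += ';';
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) {
        char c = bmat[verts[idx[i]]][verts[idx[j]]];
        cand += (c == 0 ? '.' : c);
      }
    if (!have || cand < best) {
      best = cand;
      have = true;
    }
  } while (std::next_permutation(idx.begin(), idx.end()));
  return best;
}

struct EsuCtx {
  int n, min_sz, max_sz, root;
  const std::vector<std::vector<int> >* adj;
  const std::vector<std::string>* labels;
  const std::vector<std::vector<char> >* bmat;
  const std::vector<bool>* real;
  const std::vector<bool>* marked;
  std::vector<bool> nbrflag;
  std::vector<int> sub;
  std::map<std::string, Rec>* out;

  void record() {
    std::string sig = canon_sig(sub, *labels, *bmat);
    Rec& r = (*out)[sig];
    r.count += 1;
    int nreal = 0;
    bool all_marked = true;
    for (int v : sub) {
      if ((*real)[v]) {
        ++nreal;
        if (!(*marked)[v]) all_marked = false;
      } else {
        all_marked = false;
      }
    }
    r.nreal = nreal;
    if (all_marked) r.marked += 1;
  }

  void extend(std::vector<int> ext) {
    if ((int)sub.size() >= min_sz) record();
    if ((int)sub.size() == max_sz) return;
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> newly;
      for (int u : (*adj)[w]) {
        if (u > root && !nbrflag[u]) {
          newly.push_back(u);
          nbrflag[u] = true;
        }
      }
      std::vector<int> next_ext = ext;
      next_ext.insert(next_ext.end(), newly.begin(), newly.end());
      sub.push_back(w);
      extend(next_ext);
      sub.pop_back();
      for (int u : newly) nbrflag[u] = false;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_csfp(CharacterVector labels, LogicalVector is_real,
              LogicalVector is_marked, IntegerVector bond_a,
              IntegerVector bond_b, CharacterVector bond_char,
              int min_atoms, int max_atoms) {
  const int n = labels.size();
  if (max_atoms > 7) stop("max_atoms > 7 not supported (factorial signature)");
  if (min_atoms < 1 || min_atoms > max_atoms) stop("invalid size range");
  std::vector<std::string> labs(n);
  std::vector<bool> real(n), marked(n);
  for (int i = 0; i < n; ++i) {
    labs[i] = as<std::string>(labels[i]);
    real[i] = is_real[i];
    marked[i] = is_marked[i];
  }
  std::vector<std::vector<int> > adj(n);
  std::vector<std::vector<char> > bmat(n, std::vector<char>(n, 0));
  for (int k = 0; k < bond_a.size(); ++k) {
    int a = bond_a[k] - 1, b = bond_b[k] - 1;
    char c = as<std::string>(bond_char[k])[0];
    adj[a].push_back(b);
    adj[b].push_back(a);
    bmat[a][b] = c;
    bmat[b][a] = c;
  }
  std::map<std::string, Rec> out;
  EsuCtx ctx;
  ctx.n = n;
  ctx.min_sz = min_atoms;
  ctx.max_sz = max_atoms;
  ctx.adj = &adj;
  ctx.labels = &labs;
  ctx.bmat = &bmat;
  ctx.real = &real;
  ctx.marked = &marked;
  ctx.out = &out;
  ctx.nbrflag.assign(n, false);
  for (int v = 0; v < n; ++v) {
    ctx.root = v;
    std::fill(ctx.nbrflag.begin(), ctx.nbrflag.end(), false);
    ctx.nbrflag[v] = true;
    std::vector<int> ext;
    for (int u : adj[v])
      if (u > v) {
        ext.push_back(u);
        ctx.nbrflag[u] = true;
      }
    ctx.sub.assign(1, v);
    ctx.extend(ext);
  }
  const int m = (int)out.size();
  CharacterVector sig(m);
  IntegerVector count(m), marked_n(m), nreal(m);
  int i = 0;
  for (std::map<std::string, Rec>::const_iterator it = out.begin();
       it != out.end(); ++it, ++i) {
    sig[i] = it->first;
    count[i] = it->second.count;
    marked_n[i] = it->second.marked;
    nreal[i] = it->second.nreal;
  }
  return List::create(_["sig"] = sig, _["count"] = count,
                      _["marked"] = marked_n, _["heavy"] = nreal);
}
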