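// Core engine for threshold Boolean network analysis: synchronous successor
// table, attractor extraction from the functional graph of the state space,
// flip-transition chain among attractors, terminal-SCC Ergodic Sets,
// stationary distributions, and the edge-deletion sensitivity report.
//
// States are encoded as unsigned integers with gene 1 in the least
// significant bit. Attractors are canonical state sequences rotated so the
// smallest code comes first, and are globally ordered by that code, so that
// indices are deterministic and attractors of different networks can be
// matched by their state sequence alone.

#include <RcppArmadillo.h>
#include <map>
#include <set>
#include <vector>
#include <algorithm>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

typedef std::vector<uint32_t> Key;

// Largest number of attractors for which the flip chain is built; beyond
// this the dense attractor-by-attractor matrices get unreasonable.
const int MAX_CHAIN_ATTRACTORS = 4096;

inline uint32_t successor_state(const std::vector<int>& A, int n, uint32_t s) {
  uint32_t out = 0;
  for (int i = 0; i < n; ++i) {
    int h = 0;
    for (int j = 0; j < n; ++j)
      if ((s >> j) & 1u) h += A[(size_t)i * n + j];
    int b;
    if (h > 0) b = 1;
    else if (h < 0) b = 0;
    else b = (s >> i) & 1u;
    out |= ((uint32_t)b << i);
  }
  return out;
}

struct Core {
  int n;
  std::vector<std::vector<uint32_t>> attractors;  // canonical, sorted
  std::vector<int> attr_of;                       // state -> attractor index
};

void find_attractors(const std::vector<int>& A, int n, Core& core) {
  const uint32_t S = 1u << n;
  core.n = n;
  std::vector<uint32_t> succ(S);
  for (uint32_t s = 0; s < S; ++s) succ[s] = successor_state(A, n, s);

  std::vector<int> attr(S, -1), stamp(S, -1), pos(S, 0);
  std::vector<std::vector<uint32_t>> found;
  std::vector<uint32_t> path;
  for (uint32_t s0 = 0; s0 < S; ++s0) {
    if (attr[s0] >= 0) continue;
    path.clear();
    uint32_t s = s0;
    while (attr[s] < 0 && stamp[s] != (int)s0) {
      stamp[s] = (int)s0;
      pos[s] = (int)path.size();
      path.push_back(s);
      s = succ[s];
    }
    int aid;
    if (attr[s] >= 0) {
      aid = attr[s];
    } else {
      // hit the current path again: states from pos[s] onward form a cycle
      std::vector<uint32_t> cyc(path.begin() + pos[s], path.end());
      size_t mi = 0;
      for (size_t k = 1; k < cyc.size(); ++k)
        if (cyc[k] < cyc[mi]) mi = k;
      std::rotate(cyc.begin(), cyc.begin() + mi, cyc.end());
      aid = (int)found.size();
      found.push_back(cyc);
    }
    for (uint32_t t : path) attr[t] = aid;
  }

  // deterministic ordering: by the smallest state code on the cycle
  int nA = (int)found.size();
  std::vector<int> ord(nA);
  for (int i = 0; i < nA; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return found[a][0] < found[b][0];
  });
  std::vector<int> rank(nA);
  for (int i = 0; i < nA; ++i) rank[ord[i]] = i;
  core.attractors.resize(nA);
  for (int i = 0; i < nA; ++i) core.attractors[i] = found[ord[i]];
  core.attr_of.resize(S);
  for (uint32_t s = 0; s < S; ++s) core.attr_of[s] = rank[attr[s]];
}

struct Chain {
  arma::mat W;                        // penalty-weighted flip mass
  arma::mat C;                        // raw flip counts (graph topology)
  std::vector<std::vector<int>> es;   // terminal SCCs, members sorted
  std::vector<arma::vec> pi;          // stationary distribution per ES
};

void build_chain(const std::vector<int>& A, int n, const Core& core,
                 double lambda, bool use_penalty, Chain& ch) {
  int nA = (int)core.attractors.size();
  if (nA > MAX_CHAIN_ATTRACTORS)
    stop("too many attractors (%d) for Ergodic Set analysis", nA);
  ch.W.zeros(nA, nA);
  ch.C.zeros(nA, nA);
  for (int a = 0; a < nA; ++a) {
    for (uint32_t s : core.attractors[a]) {
      for (int g = 0; g < n; ++g) {
        int h = 0;
        for (int j = 0; j < n; ++j)
          if ((s >> j) & 1u) h += A[(size_t)g * n + j];
        bool flip_on = ((s >> g) & 1u) == 0;
        bool pen = use_penalty && ((flip_on && h < 0) || (!flip_on && h > 0));
        uint32_t t = s ^ (1u << g);
        int b = core.attr_of[t];
        ch.W(a, b) += pen ? lambda : 1.0;
        ch.C(a, b) += 1.0;
      }
    }
  }

  // Kosaraju SCC on the attractor graph (edges where C > 0)
  std::vector<std::vector<int>> out(nA), in(nA);
  for (int a = 0; a < nA; ++a)
    for (int b = 0; b < nA; ++b)
      if (ch.C(a, b) > 0) { out[a].push_back(b); in[b].push_back(a); }

  std::vector<int> order;
  order.reserve(nA);
  std::vector<char> seen(nA, 0);
  for (int s0 = 0; s0 < nA; ++s0) {
    if (seen[s0]) continue;
    // iterative DFS with explicit finish events
    std::vector<std::pair<int, size_t>> st;
    st.push_back({s0, 0});
    seen[s0] = 1;
    while (!st.empty()) {
      auto& top = st.back();
      if (top.second < out[top.first].size()) {
        int nb = out[top.first][top.second++];
        if (!seen[nb]) { seen[nb] = 1; st.push_back({nb, 0}); }
      } else {
        order.push_back(top.first);
        st.pop_back();
      }
    }
  }
  std::vector<int> comp(nA, -1);
  int nc = 0;
  for (int k = nA - 1; k >= 0; --k) {
    int s0 = order[k];
    if (comp[s0] >= 0) continue;
    std::vector<int> st2 = {s0};
    comp[s0] = nc;
    while (!st2.empty()) {
      int u = st2.back(); st2.pop_back();
      for (int v : in[u])
        if (comp[v] < 0) { comp[v] = nc; st2.push_back(v); }
    }
    ++nc;
  }
  std::vector<char> terminal(nc, 1);
  for (int a = 0; a < nA; ++a)
    for (int b : out[a])
      if (comp[b] != comp[a]) terminal[comp[a]] = 0;

  std::vector<std::vector<int>> members(nc);
  for (int a = 0; a < nA; ++a) members[comp[a]].push_back(a);
  for (int c = 0; c < nc; ++c) {
    if (!terminal[c]) continue;
    std::sort(members[c].begin(), members[c].end());
    ch.es.push_back(members[c]);
  }
  std::sort(ch.es.begin(), ch.es.end(),
            [](const std::vector<int>& a, const std::vector<int>& b) {
              return a[0] < b[0];
            });

  // stationary distribution of each terminal component: solve pi P = pi
  for (const std::vector<int>& m : ch.es) {
    int nm = (int)m.size();
    arma::vec pi(nm);
    if (nm == 1) {
      pi(0) = 1.0;
    } else {
      arma::mat P(nm, nm);
      for (int r = 0; r < nm; ++r) {
        double tot = arma::accu(ch.W.row(m[r]));
        for (int c = 0; c < nm; ++c) P(r, c) = ch.W(m[r], m[c]) / tot;
      }
      arma::mat M = P.t() - arma::eye(nm, nm);
      M.row(nm - 1).ones();
      arma::vec b(nm, arma::fill::zeros);
      b(nm - 1) = 1.0;
      if (!arma::solve(pi, M, b, arma::solve_opts::no_approx))
        stop("stationary distribution solve failed (reducible chain?)");
    }
    ch.pi.push_back(pi);
  }
}

std::vector<int> as_vec(const IntegerMatrix& Am) {
  int n = Am.nrow();
  std::vector<int> A((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A[(size_t)i * n + j] = Am(i, j);
  return A;
}

double mean_len(const Core& core, const std::vector<int>& members) {
  double s = 0;
  for (int m : members) s += (double)core.attractors[m].size();
  return s / (double)members.size();
}

}  // namespace

// [[Rcpp::export]]
List cpp_analyze(IntegerMatrix Am, double lambda, bool use_penalty) {
  int n = Am.nrow();
  std::vector<int> A = as_vec(Am);
  Core core;
  find_attractors(A, n, core);
  Chain ch;
  build_chain(A, n, core, lambda, use_penalty, ch);

  int nA = (int)core.attractors.size();
  List attrs(nA);
  for (int i = 0; i < nA; ++i) {
    const std::vector<uint32_t>& c = core.attractors[i];
    IntegerVector v(c.size());
    for (size_t k = 0; k < c.size(); ++k) v[k] = (int)c[k];
    attrs[i] = v;
  }
  IntegerVector attr_of(core.attr_of.size());
  for (size_t s = 0; s < core.attr_of.size(); ++s)
    attr_of[s] = core.attr_of[s] + 1;

  int nes = (int)ch.es.size();
  List es(nes), pis(nes);
  for (int e = 0; e < nes; ++e) {
    IntegerVector m(ch.es[e].size());
    for (size_t k = 0; k < ch.es[e].size(); ++k) m[k] = ch.es[e][k] + 1;
    es[e] = m;
    pis[e] = NumericVector(ch.pi[e].begin(), ch.pi[e].end());
  }
  return List::create(
      _["n"] = n,
      _["attractors"] = attrs,
      _["attr_of_state"] = attr_of,
      _["weights"] = wrap(ch.W),
      _["counts"] = wrap(ch.C),
      _["es"] = es,
      _["stationary"] = pis);
}

// [[Rcpp::export]]
int cpp_count_es(IntegerMatrix Am) {
  int n = Am.nrow();
  std::vector<int> A = as_vec(Am);
  Core core;
  find_attractors(A, n, core);
  Chain ch;
  build_chain(A, n, core, 1.0, false, ch);
  return (int)ch.es.size();
}

// Full edge-deletion sensitivity analysis. Returns n_es of the wild type;
// when the wild type has exactly one Ergodic Set, also the mean
// total-variation distance S over evaluated deletion mutants, the wild-type
// ES summary, and (optionally) per-mutant detail with the four-way
// displacement decomposition.
// [[Rcpp::export]]
List cpp_sensitivity(IntegerMatrix Am, double lambda, bool use_penalty,
                     bool detail) {
  int n = Am.nrow();
  std::vector<int> A = as_vec(Am);
  Core core;
  find_attractors(A, n, core);
  Chain ch;
  build_chain(A, n, core, lambda, use_penalty, ch);
  int n_es = (int)ch.es.size();
  if (n_es != 1) {
    return List::create(_["n_es"] = n_es, _["S"] = NA_REAL);
  }
  const std::vector<int>& wt_members = ch.es[0];
  double wt_mlen = mean_len(core, wt_members);
  std::map<Key, double> piA;
  for (size_t k = 0; k < wt_members.size(); ++k)
    piA[core.attractors[wt_members[k]]] = ch.pi[0](k);

  std::vector<int> mi, mj, ski, skj;
  std::vector<double> md, m1v, m2v, m3v, m4v, msize, mmlen;
  double Ssum = 0;
  int n_eval = 0, n_edges = 0;

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (A[(size_t)i * n + j] == 0) continue;
      ++n_edges;
      std::vector<int> B = A;
      B[(size_t)i * n + j] = 0;
      Core bc;
      find_attractors(B, n, bc);
      Chain bch;
      build_chain(B, n, bc, lambda, use_penalty, bch);
      if (bch.es.size() != 1) {
        ski.push_back(i + 1);
        skj.push_back(j + 1);
        continue;
      }
      std::set<Key> attrsB(bc.attractors.begin(), bc.attractors.end());
      std::map<Key, double> piB;
      for (size_t k = 0; k < bch.es[0].size(); ++k)
        piB[bc.attractors[bch.es[0][k]]] = bch.pi[0](k);

      double d1 = 0, d2 = 0, d3 = 0, d4 = 0;
      for (const auto& kv : piA) {
        if (!attrsB.count(kv.first)) d1 += kv.second;
        else {
          auto it = piB.find(kv.first);
          if (it == piB.end()) d3 += kv.second;
          else d4 += std::fabs(kv.second - it->second);
        }
      }
      for (const auto& kv : piB)
        if (!piA.count(kv.first)) d2 += kv.second;
      double d = (d1 + d2 + d3 + d4) / 2.0;

      Ssum += d;
      ++n_eval;
      if (detail) {
        mi.push_back(i + 1); mj.push_back(j + 1);
        md.push_back(d);
        m1v.push_back(d1); m2v.push_back(d2);
        m3v.push_back(d3); m4v.push_back(d4);
        msize.push_back((double)bch.es[0].size());
        mmlen.push_back(mean_len(bc, bch.es[0]));
      }
    }
  }
  double S = n_eval > 0 ? Ssum / n_eval : NA_REAL;
  List out = List::create(
      _["n_es"] = 1,
      _["S"] = S,
      _["n_edges"] = n_edges,
      _["n_evaluated"] = n_eval,
      _["wt_es_size"] = (int)wt_members.size(),
      _["wt_mean_length"] = wt_mlen,
      _["skipped_i"] = ski,
      _["skipped_j"] = skj);
  if (detail) {
    out["mutant_i"] = mi;
    out["mutant_j"] = mj;
    out["d"] = md;
    out["m1"] = m1v;
    out["m2"] = m2v;
    out["m3"] = m3v;
    out["m4"] = m4v;
    out["mutant_es_size"] = msize;
    out["mutant_mean_length"] = mmlen;
  }
  return out;
}
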