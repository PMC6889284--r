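// Two-level map-equation minimization on an undirected weighted graph.
// Greedy two-phase search (local node moves, then community aggregation,
// repeated to convergence), restarted n_trials times with shuffled node
// orders drawn from R's RNG so results are reproducible via set.seed().
//
// Codelength identity used throughout (log base 2, plogp(0) := 0):
//   L = plogp(q) - 2*sum_c plogp(q_c) + sum_c plogp(q_c + P_c)
//       - sum_alpha plogp(p_alpha)
// with q_c the community's relative exit weight cut_c / (2W), q = sum q_c,
// P_c the summed node visit rates, p_alpha = strength_alpha / (2W).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double plogp(double x) {
  return x > 0.0 ? x * std::log2(x) : 0.0;
}

struct Level {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj; // no self loops here
  std::vector<double> selfw;  // self-loop weight (internal weight of supernode)
  std::vector<double> p;      // visit rate of (super)node
  std::vector<double> deg;    // sum of non-self incident edge weights
};

class MapEq {
public:
  double two_w;          // 2 * total edge weight of the original graph
  double const_term;     // sum_alpha plogp(p_alpha) over original nodes
  // community state for the current level
  std::vector<int> comm;
  std::vector<double> cut;   // absolute cut weight of each community
  std::vector<double> sum_p; // summed visit rates
  double sum_cut;            // sum of cuts

  double codelength() const {
    double t1 = 0.0, t2 = 0.0, t3 = 0.0;
    for (size_t c = 0; c < cut.size(); ++c) {
      if (sum_p[c] <= 0.0 && cut[c] <= 0.0) continue;
      double qc = cut[c] / two_w;
      t2 += plogp(qc);
      t3 += plogp(qc + sum_p[c]);
    }
    t1 = plogp(sum_cut / two_w);
    return t1 - 2.0 * t2 + t3 - const_term;
  }

  // contribution of one community to (-2*t2 + t3)
  inline double comm_term(double cutc, double pc) const {
    double qc = cutc / two_w;
    return -2.0 * plogp(qc) + plogp(qc + pc);
  }
};

// Fisher-Yates with R's RNG
static void shuffle_order(std::vector<int>& ord) {
  int n = ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One local-moving phase; returns true if any move was made.
static bool local_move_phase(const Level& lv, MapEq& st, double tol) {
  int n = lv.n;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  bool any_move = false;
  bool improved = true;
  std::vector<double> w_to(n, 0.0);
  std::vector<int> touched;
  while (improved) {
    improved = false;
    shuffle_order(ord);
    for (int oi = 0; oi < n; ++oi) {
      int u = ord[oi];
      int cu = st.comm[u];
      touched.clear();
      double w_self_comm = 0.0;
      for (auto& e : lv.adj[u]) {
        int cv = st.comm[e.first];
        if (w_to[cv] == 0.0 && cv != cu) touched.push_back(cv);
        if (cv == cu) w_self_comm += e.second; else w_to[cv] += e.second;
      }
      if (touched.empty()) continue;
      // terms with u removed from cu
      double cut_cu_without = st.cut[cu] + 2.0 * w_self_comm - lv.deg[u];
      double p_cu_without = st.sum_p[cu] - lv.p[u];
      double base_old = st.comm_term(st.cut[cu], st.sum_p[cu]);
      double base_without = (p_cu_without > 1e-15 || cut_cu_without > 1e-15)
        ? st.comm_term(cut_cu_without, p_cu_without) : 0.0;
      double best_delta = 0.0;
      int best_c = cu;
      double best_cut_to_new = 0.0;
      double sum_cut_old = st.sum_cut;
      for (int cv : touched) {
        double cut_cv_with = st.cut[cv] + lv.deg[u] - 2.0 * w_to[cv];
        double sum_cut_new = sum_cut_old
          + (cut_cu_without - st.cut[cu]) + (cut_cv_with - st.cut[cv]);
        double delta =
          plogp(sum_cut_new / st.two_w) - plogp(sum_cut_old / st.two_w)
          + base_without - base_old
          + st.comm_term(cut_cv_with, st.sum_p[cv] + lv.p[u])
          - st.comm_term(st.cut[cv], st.sum_p[cv]);
        if (delta < best_delta - tol) {
          best_delta = delta;
          best_c = cv;
          best_cut_to_new = cut_cv_with;
        }
      }
      if (best_c != cu) {
        st.sum_cut += (cut_cu_without - st.cut[cu])
          + (best_cut_to_new - st.cut[best_c]);
        st.cut[cu] = cut_cu_without;
        st.sum_p[cu] = p_cu_without;
        st.cut[best_c] = best_cut_to_new;
        st.sum_p[best_c] += lv.p[u];
        st.comm[u] = best_c;
        improved = true;
        any_move = true;
      }
      for (int cv : touched) w_to[cv] = 0.0;
    }
  }
  return any_move;
}

static void init_state(const Level& lv, MapEq& st) {
  int n = lv.n;
  st.comm.assign(n, 0);
  st.cut.assign(n, 0.0);
  st.sum_p.assign(n, 0.0);
  st.sum_cut = 0.0;
  for (int i = 0; i < n; ++i) {
    st.comm[i] = i;
    st.cut[i] = lv.deg[i];
    st.sum_p[i] = lv.p[i];
    st.sum_cut += lv.deg[i];
  }
}

// Aggregate current communities into a coarser level; fills mapping old->new comm.
static Level aggregate(const Level& lv, const MapEq& st, std::vector<int>& relabel) {
  int n = lv.n;
  relabel.assign(st.cut.size(), -1);
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    int c = st.comm[i];
    if (relabel[c] < 0) relabel[c] = nc++;
  }
  Level out;
  out.n = nc;
  out.adj.assign(nc, {});
  out.selfw.assign(nc, 0.0);
  out.p.assign(nc, 0.0);
  out.deg.assign(nc, 0.0);
  std::vector<std::map<int, double>> acc(nc);
  for (int i = 0; i < n; ++i) {
    int ci = relabel[st.comm[i]];
    out.p[ci] += lv.p[i];
    out.selfw[ci] += lv.selfw[i];
    for (auto& e : lv.adj[i]) {
      int cj = relabel[st.comm[e.first]];
      if (cj == ci) {
        out.selfw[ci] += e.second / 2.0; // each internal edge seen twice
      } else {
        acc[ci][cj] += e.second;
      }
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (auto& kv : acc[c]) {
      out.adj[c].push_back({kv.first, kv.second});
      out.deg[c] += kv.second;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".mapeq_detect")]]
List mapeq_detect(int n_nodes, IntegerVector ei, IntegerVector ej,
                  NumericVector ew, int n_trials, double tol) {
  Level base;
  base.n = n_nodes;
  base.adj.assign(n_nodes, {});
  base.selfw.assign(n_nodes, 0.0);
  base.p.assign(n_nodes, 0.0);
  base.deg.assign(n_nodes, 0.0);
  double total_w = 0.0;
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k], b = ej[k];
    double w = ew[k];
    if (a == b) { base.selfw[a] += w; }
    else {
      base.adj[a].push_back({b, w});
      base.adj[b].push_back({a, w});
      base.deg[a] += w;
      base.deg[b] += w;
    }
    total_w += w;
  }
  double two_w = 2.0 * total_w;
  double const_term = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    base.p[i] = (base.deg[i] + 2.0 * base.selfw[i]) / two_w;
    const_term += plogp(base.p[i]);
  }

  std::vector<int> best_assign(n_nodes, 0);
  double best_L = R_PosInf;
  GetRNGstate();
  for (int trial = 0; trial < n_trials; ++trial) {
    // assignment of original nodes through the level hierarchy
    std::vector<int> node_comm(n_nodes);
    for (int i = 0; i < n_nodes; ++i) node_comm[i] = i;
    Level lv = base;
    MapEq st;
    st.two_w = two_w;
    st.const_term = const_term;
    init_state(lv, st);
    while (true) {
      bool moved = local_move_phase(lv, st, tol);
      std::vector<int> relabel;
      Level coarse = aggregate(lv, st, relabel);
      // update original-node assignment: node -> comm -> relabel
      for (int i = 0; i < n_nodes; ++i) {
        node_comm[i] = relabel[st.comm[node_comm[i]]];
      }
      if (!moved || coarse.n == lv.n) break;
      lv = std::move(coarse);
      init_state(lv, st);
      // rebuild state cut/sum_p consistent with singleton supernodes
    }
    // final codelength at the coarsest state
    MapEq fin;
    fin.two_w = two_w;
    fin.const_term = const_term;
    int nc = 0;
    for (int i = 0; i < n_nodes; ++i) nc = std::max(nc, node_comm[i] + 1);
    fin.comm = node_comm;
    fin.cut.assign(nc, 0.0);
    fin.sum_p.assign(nc, 0.0);
    fin.sum_cut = 0.0;
    for (int i = 0; i < n_nodes; ++i) {
      fin.sum_p[node_comm[i]] += base.p[i];
      for (auto& e : base.adj[i]) {
        if (node_comm[e.first] != node_comm[i]) fin.cut[node_comm[i]] += e.second;
      }
    }
    for (int c = 0; c < nc; ++c) fin.sum_cut += fin.cut[c];
    double L = fin.codelength();
    if (L < best_L - 1e-13) {
      best_L = L;
      best_assign = node_comm;
    }
  }
  PutRNGstate();
  return List::create(_["assign"] = wrap(best_assign), _["L"] = best_L);
}
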