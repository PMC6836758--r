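#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent without migration on a rooted population tree.
//
// Lineage groups are indexed 0..P-1; merge events (backward in time) move
// every active lineage of `src` into `dst`, after which `src` is dead.
// Within a group of effective size N, each lineage pair coalesces at rate
// 1 / (inheritance * 2N) per generation. Times are in generations.
//
// Mutations are Poisson on branches at rate mu_locus per generation and
// each creates one new segregating site (infinite-sites); column = site,
// row = sampled copy, entry = 1 if the copy carries the derived state.

namespace {

struct Genealogy {
  std::vector<int> parent;      // -1 for root
  std::vector<double> time;
  int n_leaves;
};

Genealogy simulate_genealogy(const IntegerVector& n_copies,
                             const NumericVector& pop_sizes,
                             const NumericVector& event_times,
                             const IntegerVector& event_src,
                             const IntegerVector& event_dst,
                             double inheritance) {
  const int P = n_copies.size();
  int n = 0;
  for (int i = 0; i < P; ++i) n += n_copies[i];
  if (n < 1) stop("no sampled copies");

  Genealogy g;
  g.n_leaves = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<std::vector<int>> active(P);
  int id = 0;
  for (int p = 0; p < P; ++p)
    for (int j = 0; j < n_copies[p]; ++j) active[p].push_back(id++);

  int next_node = n;
  double t = 0.0;
  int e = 0;
  const int E = event_times.size();
  int remaining = n;

  while (remaining > 1) {
    double total_rate = 0.0;
    std::vector<double> rate(P, 0.0);
    for (int p = 0; p < P; ++p) {
      const double k = (double)active[p].size();
      if (k >= 2.0) {
        rate[p] = k * (k - 1.0) / 2.0 / (inheritance * 2.0 * pop_sizes[p]);
        total_rate += rate[p];
      }
    }
    double t_next = R_PosInf;
    if (total_rate > 0.0) t_next = t + exp_rand() / total_rate;

    if (e < E && event_times[e] <= t_next) {
      t = event_times[e];
      std::vector<int>& s = active[event_src[e]];
      std::vector<int>& d = active[event_dst[e]];
      d.insert(d.end(), s.begin(), s.end());
      s.clear();
      ++e;
      continue;
    }
    if (!R_FINITE(t_next))
      stop("coalescent stalled: multiple lineage groups with no remaining merge events");

    t = t_next;
    double u = unif_rand() * total_rate;
    int p = 0;
    for (; p < P - 1; ++p) {
      u -= rate[p];
      if (u <= 0.0) break;
    }
    std::vector<int>& a = active[p];
    int k = (int)a.size();
    int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
    int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
    if (i2 >= i1) ++i2;
    int c1 = a[i1], c2 = a[i2];
    int anc = next_node++;
    g.parent[c1] = anc;
    g.parent[c2] = anc;
    g.time[anc] = t;
    if (i1 > i2) std::swap(i1, i2);
    a.erase(a.begin() + i2);
    a[i1] = anc;
    --remaining;
  }
  return g;
}

// leaves under each node, as a list of leaf-index vectors (computed lazily
// only for mutated branches via upward propagation).
IntegerMatrix mutations_to_matrix(const Genealogy& g,
                                  const std::vector<int>& mut_node) {
  const int n = g.n_leaves;
  const int M = (int)mut_node.size();
  IntegerMatrix X(n, M);
  if (M == 0) return X;

  // children lists
  const int V = (int)g.parent.size();
  std::vector<std::vector<int>> children(V);
  for (int v = 0; v < V; ++v)
    if (g.parent[v] >= 0) children[g.parent[v]].push_back(v);

  for (int m = 0; m < M; ++m) {
    // DFS from mut_node collecting leaves
    std::vector<int> stack{mut_node[m]};
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < n) X(v, m) = 1;
      else for (int c : children[v]) stack.push_back(c);
    }
  }
  return X;
}

} // namespace

// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector n_copies, NumericVector pop_sizes,
                   NumericVector event_times, IntegerVector event_src,
                   IntegerVector event_dst, double inheritance,
                   double mu_locus) {
  RNGScope scope;
  Genealogy g = simulate_genealogy(n_copies, pop_sizes, event_times,
                                   event_src, event_dst, inheritance);
  const int V = (int)g.parent.size();
  std::vector<int> mut_node;
  double tmrca = 0.0;
  for (int v = 0; v < V; ++v) {
    if (g.parent[v] < 0) { tmrca = g.time[v]; continue; }
    double blen = g.time[g.parent[v]] - g.time[v];
    int nm = (int)R::rpois(mu_locus * blen);
    for (int m = 0; m < nm; ++m) mut_node.push_back(v);
  }
  IntegerMatrix X = mutations_to_matrix(g, mut_node);
  return List::create(_["haps"] = X, _["tmrca"] = tmrca);
}

// Single-population Kingman genealogy with exactly S mutations placed
// multinomially on branches proportional to branch length; time units are
// irrelevant to the resulting site patterns. Used for null distributions
// of neutrality statistics conditioned on the observed S.
// [[Rcpp::export]]
IntegerMatrix sim_conditional_cpp(int n, int S) {
  RNGScope scope;
  IntegerVector nc(1, n);
  NumericVector ps(1, 0.5); // coalescent units: rate k(k-1)/2
  Genealogy g = simulate_genealogy(nc, ps, NumericVector(0), IntegerVector(0),
                                   IntegerVector(0), 1.0);
  const int V = (int)g.parent.size();
  std::vector<double> cum(V, 0.0);
  double tot = 0.0;
  for (int v = 0; v < V; ++v) {
    if (g.parent[v] >= 0) tot += g.time[g.parent[v]] - g.time[v];
    cum[v] = tot;
  }
  std::vector<int> mut_node(S);
  for (int m = 0; m < S; ++m) {
    double u = unif_rand() * tot;
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    mut_node[m] = lo;
  }
  return mutations_to_matrix(g, mut_node);
}

// Pairwise coalescence time of 2 copies in one population (calibration).
// [[Rcpp::export]]
NumericVector sim_t2_cpp(int reps, double N, double inheritance) {
  RNGScope scope;
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r)
    out[r] = exp_rand() * inheritance * 2.0 * N;
  return out;
}
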