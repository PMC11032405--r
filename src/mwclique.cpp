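#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weights are integer-valued but carried as double: sums stay exact well past
// the n * 2e6 range the weight model produces (doubles are exact to 2^53).

namespace {

struct Graph {
  int n;
  std::vector<std::vector<char> > adj; // dense symmetric adjacency
  std::vector<double> w;
};

Graph build_graph(const List& adjlist, const NumericVector& weights) {
  Graph g;
  g.n = weights.size();
  g.adj.assign(g.n, std::vector<char>(g.n, 0));
  g.w.assign(weights.begin(), weights.end());
  for (int v = 0; v < g.n; ++v) {
    IntegerVector nb = adjlist[v]; // 0-based neighbor ids
    for (int i = 0; i < nb.size(); ++i) g.adj[v][nb[i]] = 1;
  }
  return g;
}

struct ColorOut {
  std::vector<int> order;      // reordered candidate set
  std::vector<double> wcolor;  // cumulative weight bound per position
  std::vector<int> color_of;   // color class per position (1-based)
  int min_k_w;                 // first class admitted to the colored region
  int maxno;                   // number of classes used
  std::vector<std::vector<int> > classes;
  std::vector<double> class_w; // max vertex weight per class
  std::vector<double> ub;      // prefix sums of class_w
};

// Greedy weighted coloring of R in its incoming order, then reorder:
// vertices whose class prefix bound cannot beat the incumbent gap keep their
// incoming relative order at the front with bound 0; the rest follow class by
// class carrying the prefix-sum bound of their class.
ColorOut color_sort(const Graph& g, const std::vector<int>& R,
                    double wQ, double wQmax) {
  ColorOut out;
  const int m = (int)R.size();
  std::vector<int> color(m, 0);
  for (int i = 0; i < m; ++i) {
    int p = R[i];
    int k = 0;
    while (k < (int)out.classes.size()) {
      bool conflict = false;
      const std::vector<int>& cls = out.classes[k];
      for (size_t j = 0; j < cls.size(); ++j)
        if (g.adj[p][cls[j]]) { conflict = true; break; }
      if (!conflict) break;
      ++k;
    }
    if (k == (int)out.classes.size()) {
      out.classes.push_back(std::vector<int>());
      out.class_w.push_back(0.0);
    }
    out.classes[k].push_back(p);
    if (g.w[p] > out.class_w[k]) out.class_w[k] = g.w[p];
    color[i] = k + 1;
  }
  out.maxno = (int)out.classes.size();
  out.ub.resize(out.maxno);
  double cum = 0.0;
  for (int k = 0; k < out.maxno; ++k) { cum += out.class_w[k]; out.ub[k] = cum; }

  const double gap = wQmax - wQ;
  out.min_k_w = out.maxno + 1;
  for (int k = 0; k < out.maxno; ++k)
    if (out.ub[k] > gap) { out.min_k_w = k + 1; break; }

  out.order.reserve(m); out.wcolor.reserve(m); out.color_of.reserve(m);
  for (int i = 0; i < m; ++i)
    if (color[i] < out.min_k_w) {
      out.order.push_back(R[i]);
      out.wcolor.push_back(0.0);
      out.color_of.push_back(color[i]);
    }
  for (int k = out.min_k_w - 1; k < out.maxno; ++k)
    for (size_t j = 0; j < out.classes[k].size(); ++j) {
      out.order.push_back(out.classes[k][j]);
      out.wcolor.push_back(out.ub[k]);
      out.color_of.push_back(k + 1);
    }
  return out;
}

struct Search {
  const Graph* g;
  bool dyn;
  double tlimit;
  std::vector<double> steps; // steps[level], level >= 1
  double steps_all;
  std::vector<int> Q;
  double wQ;
  std::vector<int> Qmax;
  double wQmax;
  std::vector<double> history;

  Search(const Graph* gr, bool d, double tl)
      : g(gr), dyn(d), tlimit(tl), steps(2, 0.0), steps_all(0.0),
        wQ(0.0), wQmax(0.0) {}

  void expand(std::vector<int> R, std::vector<double> wcolor, int level) {
    if ((int)steps.size() <= level) steps.resize(level + 1, 0.0);
    while (!R.empty()) {
      steps[level] += 1.0;
      steps_all += 1.0;
      int p = R.back();
      double wc = wcolor.back();
      R.pop_back();
      wcolor.pop_back();
      if (!(wQ + wc > wQmax))
        break; // bounds are nondecreasing along R: the whole level is done
      Q.push_back(p);
      wQ += g->w[p];
      std::vector<int> Rp;
      Rp.reserve(R.size());
      for (size_t i = 0; i < R.size(); ++i)
        if (g->adj[p][R[i]]) Rp.push_back(R[i]);
      if (!Rp.empty()) {
        if (dyn) {
          double upto = 0.0;
          for (int l = 1; l <= level && l < (int)steps.size(); ++l)
            upto += steps[l];
          double T = steps_all > 0.0 ? upto / steps_all : 0.0;
          if (T < tlimit) {
            // recompute degrees within the induced subgraph G(Rp) and
            // re-sort by decreasing induced degree, stably
            const int m = (int)Rp.size();
            std::vector<int> deg(m, 0), idx(m);
            for (int i = 0; i < m; ++i) idx[i] = i;
            for (int i = 0; i < m; ++i)
              for (int j = i + 1; j < m; ++j)
                if (g->adj[Rp[i]][Rp[j]]) { ++deg[i]; ++deg[j]; }
            std::stable_sort(idx.begin(), idx.end(),
                             [&](int a, int b) { return deg[a] > deg[b]; });
            std::vector<int> sorted;
            sorted.reserve(m);
            for (int i = 0; i < m; ++i) sorted.push_back(Rp[idx[i]]);
            Rp.swap(sorted);
          }
        }
        ColorOut c = color_sort(*g, Rp, wQ, wQmax);
        expand(c.order, c.wcolor, level + 1);
      } else if (wQ > wQmax) {
        Qmax = Q;
        wQmax = wQ;
        history.push_back(wQmax);
      }
      Q.pop_back();
      wQ -= g->w[p];
    }
  }
};

List color_out_to_list(const ColorOut& c) {
  IntegerVector order(c.order.size()), color_of(c.color_of.size());
  for (size_t i = 0; i < c.order.size(); ++i) {
    order[i] = c.order[i] + 1;
    color_of[i] = c.color_of[i];
  }
  List classes(c.maxno);
  for (int k = 0; k < c.maxno; ++k) {
    IntegerVector cls(c.classes[k].size());
    for (size_t j = 0; j < c.classes[k].size(); ++j) cls[j] = c.classes[k][j] + 1;
    classes[k] = cls;
  }
  return List::create(
      _["order"] = order,
      _["wcolor"] = NumericVector(c.wcolor.begin(), c.wcolor.end()),
      _["color"] = color_of,
      _["min_k_w"] = c.min_k_w,
      _["n_classes"] = c.maxno,
      _["classes"] = classes,
      _["class_weights"] = NumericVector(c.class_w.begin(), c.class_w.end()),
      _["class_bounds"] = NumericVector(c.ub.begin(), c.ub.end()));
}

} // namespace

// [[Rcpp::export]]
List csw_cpp(List adjlist, NumericVector weights, IntegerVector cand0,
             double weight_q, double weight_qmax) {
  Graph g = build_graph(adjlist, weights);
  std::vector<int> R(cand0.begin(), cand0.end());
  return color_out_to_list(color_sort(g, R, weight_q, weight_qmax));
}

// [[Rcpp::export]]
List mwc_cpp(List adjlist, NumericVector weights, IntegerVector root0,
             bool dyn, double tlimit) {
  Graph g = build_graph(adjlist, weights);
  std::vector<int> R(root0.begin(), root0.end());
  ColorOut c = color_sort(g, R, 0.0, 0.0);
  Search s(&g, dyn, tlimit);
  s.expand(c.order, c.wcolor, 1);
  IntegerVector clique(s.Qmax.size());
  for (size_t i = 0; i < s.Qmax.size(); ++i) clique[i] = s.Qmax[i] + 1;
  int max_level = 0;
  for (int l = (int)s.steps.size() - 1; l >= 1; --l)
    if (s.steps[l] > 0.0) { max_level = l; break; }
  NumericVector spl(max_level);
  for (int l = 1; l <= max_level; ++l) spl[l - 1] = s.steps[l];
  return List::create(
      _["clique"] = clique,
      _["weight"] = s.wQmax,
      _["steps_total"] = s.steps_all,
      _["steps_per_level"] = spl,
      _["incumbent_history"] =
          NumericVector(s.history.begin(), s.history.end()));
}
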