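// Core numerics for neural grammar networks.
//
// A per-molecule network ("plan") is a flattened parse tree: node layers in
// child-before-parent order (the single output unit last), and one edge per
// weight-layer instantiation.  Edge types: 0 = internal child layer,
// 1 = one-hot token leaf (child = token index), 2 = dense input leaf
// (child = index into the plan's dense-vector list).  Edges are sorted by
// parent, so a single ascending sweep is a breadth-first-equivalent forward
// pass and the reverse sweep backpropagates (every node has exactly one
// parent edge).  The learning rate is folded into the per-instantiation
// deltas; shared layers receive the *sum* of their instantiation deltas
// plus the momentum carry-over, and layers unused by an exemplar are left
// untouched (weights, biases and momentum buffers alike).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lib {
  int K;
  std::vector<int> pr, pc;                  // parent and child sizes
  std::vector<std::vector<double> > w, b, dw, db;  // w column-major
};

Lib lib_in(const List& layers) {
  Lib L;
  L.K = layers.size();
  L.pr.resize(L.K); L.pc.resize(L.K);
  L.w.resize(L.K); L.b.resize(L.K); L.dw.resize(L.K); L.db.resize(L.K);
  for (int k = 0; k < L.K; ++k) {
    List lay = layers[k];
    NumericMatrix w = lay["w"], dw = lay["dw"];
    NumericVector b = lay["b"], db = lay["db"];
    L.pr[k] = w.nrow(); L.pc[k] = w.ncol();
    L.w[k].assign(w.begin(), w.end());
    L.b[k].assign(b.begin(), b.end());
    L.dw[k].assign(dw.begin(), dw.end());
    L.db[k].assign(db.begin(), db.end());
  }
  return L;
}

List lib_out(const Lib& L, const List& tmpl) {
  List out(L.K);
  for (int k = 0; k < L.K; ++k) {
    List lay = clone(as<List>(tmpl[k]));
    NumericMatrix w(L.pr[k], L.pc[k]), dw(L.pr[k], L.pc[k]);
    NumericVector b(L.pr[k]), db(L.pr[k]);
    std::copy(L.w[k].begin(), L.w[k].end(), w.begin());
    std::copy(L.dw[k].begin(), L.dw[k].end(), dw.begin());
    std::copy(L.b[k].begin(), L.b[k].end(), b.begin());
    std::copy(L.db[k].begin(), L.db[k].end(), db.begin());
    lay["w"] = w; lay["b"] = b; lay["dw"] = dw; lay["db"] = db;
    out[k] = lay;
  }
  out.attr("names") = tmpl.attr("names");
  return out;
}

struct Plan {
  std::vector<int> nsize;
  std::vector<int> eparent, ekey, etype, echild;  // 0-based parent/key
  std::vector<std::vector<double> > dense;
};

Plan plan_in(const List& plan) {
  Plan P;
  IntegerVector ns = plan["node_sizes"];
  IntegerVector ep = plan["edge_parent"], ek = plan["edge_key"],
                et = plan["edge_type"], ec = plan["edge_child"];
  P.nsize.assign(ns.begin(), ns.end());
  P.eparent.resize(ep.size()); P.ekey.resize(ep.size());
  P.etype.assign(et.begin(), et.end());
  P.echild.assign(ec.begin(), ec.end());
  for (int e = 0; e < ep.size(); ++e) {
    P.eparent[e] = ep[e] - 1;
    P.ekey[e] = ek[e] - 1;
    if (P.etype[e] == 0) P.echild[e] = ec[e] - 1;  // node refs to 0-based
  }
  if (plan.containsElementNamed("dense") && !Rf_isNull(plan["dense"])) {
    List d = plan["dense"];
    P.dense.resize(d.size());
    for (int i = 0; i < d.size(); ++i) {
      NumericVector v = d[i];
      P.dense[i].assign(v.begin(), v.end());
    }
  }
  return P;
}

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Forward pass; fills act (per node) and returns the output activation.
double forward(const Lib& L, const Plan& P,
               std::vector<std::vector<double> >& act) {
  int n = P.nsize.size();
  act.resize(n);
  int E = P.eparent.size();
  int e = 0;
  for (int u = 0; u < n; ++u) {
    int su = P.nsize[u];
    std::vector<double>& a = act[u];
    a.assign(su, 0.0);
    for (; e < E && P.eparent[e] == u; ++e) {
      int k = P.ekey[e];
      const std::vector<double>& w = L.w[k];
      const std::vector<double>& b = L.b[k];
      int pr = L.pr[k];
      if (P.etype[e] == 0) {
        const std::vector<double>& av = act[P.echild[e]];
        for (int j = 0; j < (int)av.size(); ++j) {
          double aj = av[j];
          const double* col = &w[(size_t)j * pr];
          for (int i = 0; i < pr; ++i) a[i] += col[i] * aj;
        }
      } else if (P.etype[e] == 1) {
        int j = P.echild[e] - 1;  // one-hot: activation 1.0 at token index
        const double* col = &w[(size_t)j * pr];
        for (int i = 0; i < pr; ++i) a[i] += col[i];
      } else {
        const std::vector<double>& x = P.dense[P.echild[e] - 1];
        for (int j = 0; j < (int)x.size(); ++j) {
          double xj = x[j];
          const double* col = &w[(size_t)j * pr];
          for (int i = 0; i < pr; ++i) a[i] += col[i] * xj;
        }
      }
      for (int i = 0; i < pr; ++i) a[i] += b[i];
    }
    for (int i = 0; i < su; ++i) a[i] = logistic(a[i]);
  }
  return act[n - 1][0];
}

// Backward pass.  Fills per-edge instantiation deltas (scaled by eta) via
// the callback; delta[u] holds the error gradient at each node layer.
template <class F>
double backward(const Lib& L, const Plan& P, double target, double eta,
                std::vector<std::vector<double> >& act, F&& emit) {
  double out = forward(L, P, act);
  int n = P.nsize.size();
  std::vector<std::vector<double> > delta(n);
  for (int u = 0; u < n; ++u) delta[u].assign(P.nsize[u], 0.0);
  delta[n - 1][0] = (target - out) * out * (1.0 - out);
  int E = P.eparent.size();
  for (int e = E - 1; e >= 0; --e) {
    int u = P.eparent[e], k = P.ekey[e];
    int pr = L.pr[k], pc = L.pc[k];
    const std::vector<double>& du = delta[u];
    std::vector<double> dwk((size_t)pr * pc, 0.0), dbk(pr);
    for (int i = 0; i < pr; ++i) dbk[i] = eta * du[i];
    if (P.etype[e] == 0) {
      int v = P.echild[e];
      const std::vector<double>& av = act[v];
      const std::vector<double>& w = L.w[k];
      std::vector<double>& dv = delta[v];
      for (int j = 0; j < pc; ++j) {
        const double* col = &w[(size_t)j * pr];
        double s = 0.0, aj = av[j];
        double* dcol = &dwk[(size_t)j * pr];
        for (int i = 0; i < pr; ++i) {
          s += col[i] * du[i];
          dcol[i] = eta * du[i] * aj;
        }
        dv[j] = aj * (1.0 - aj) * s;
      }
    } else if (P.etype[e] == 1) {
      int j = P.echild[e] - 1;
      double* dcol = &dwk[(size_t)j * pr];
      for (int i = 0; i < pr; ++i) dcol[i] = eta * du[i];  // leaf activation 1.0
    } else {
      const std::vector<double>& x = P.dense[P.echild[e] - 1];
      for (int j = 0; j < pc; ++j) {
        double xj = x[j];
        double* dcol = &dwk[(size_t)j * pr];
        for (int i = 0; i < pr; ++i) dcol[i] = eta * du[i] * xj;
      }
    }
    emit(e, k, dwk, dbk);
  }
  return out;
}

// Accumulators for one online update (sum of instantiation deltas per key).
struct Accum {
  std::vector<std::vector<double> > sw, sb;
  std::vector<char> used;
  std::vector<int> used_list;
  void init(const Lib& L) {
    sw.resize(L.K); sb.resize(L.K);
    used.assign(L.K, 0);
    for (int k = 0; k < L.K; ++k) {
      sw[k].assign((size_t)L.pr[k] * L.pc[k], 0.0);
      sb[k].assign(L.pr[k], 0.0);
    }
  }
  void add(int k, const std::vector<double>& dwk,
           const std::vector<double>& dbk) {
    if (!used[k]) { used[k] = 1; used_list.push_back(k); }
    for (size_t i = 0; i < dwk.size(); ++i) sw[k][i] += dwk[i];
    for (size_t i = 0; i < dbk.size(); ++i) sb[k][i] += dbk[i];
  }
  void apply(Lib& L, double momentum) {
    for (size_t m = 0; m < used_list.size(); ++m) {
      int k = used_list[m];
      for (size_t i = 0; i < sw[k].size(); ++i) {
        double tot = sw[k][i] + momentum * L.dw[k][i];
        L.w[k][i] += tot;
        L.dw[k][i] = tot;
        sw[k][i] = 0.0;
      }
      for (size_t i = 0; i < sb[k].size(); ++i) {
        double tot = sb[k][i] + momentum * L.db[k][i];
        L.b[k][i] += tot;
        L.db[k][i] = tot;
        sb[k][i] = 0.0;
      }
      used[k] = 0;
    }
    used_list.clear();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_forward(List layers, List plan) {
  Lib L = lib_in(layers);
  Plan P = plan_in(plan);
  std::vector<std::vector<double> > act;
  double out = forward(L, P, act);
  List acts(act.size());
  for (size_t u = 0; u < act.size(); ++u) acts[u] = wrap(act[u]);
  return List::create(_["output"] = out, _["activations"] = acts);
}

// [[Rcpp::export]]
List cpp_backprop(List layers, List plan, double target, double eta) {
  Lib L = lib_in(layers);
  Plan P = plan_in(plan);
  std::vector<std::vector<double> > act;
  int E = P.eparent.size();
  List dws(E), dbs(E);
  IntegerVector keys(E);
  double out = backward(L, P, target, eta, act,
    [&](int e, int k, const std::vector<double>& dwk,
        const std::vector<double>& dbk) {
      NumericMatrix m(L.pr[k], L.pc[k]);
      std::copy(dwk.begin(), dwk.end(), m.begin());
      dws[e] = m;
      dbs[e] = wrap(dbk);
      keys[e] = k + 1;
    });
  return List::create(_["output"] = out, _["keys"] = keys,
                      _["dw"] = dws, _["db"] = dbs);
}

// [[Rcpp::export]]
List cpp_step(List layers, List plan, double target, double eta,
              double momentum) {
  Lib L = lib_in(layers);
  Plan P = plan_in(plan);
  Accum A; A.init(L);
  std::vector<std::vector<double> > act;
  double out = backward(L, P, target, eta, act,
    [&](int, int k, const std::vector<double>& dwk,
        const std::vector<double>& dbk) { A.add(k, dwk, dbk); });
  A.apply(L, momentum);
  return List::create(_["output"] = out, _["layers"] = lib_out(L, layers));
}

// Online (per-exemplar) training with momentum.  Exemplar order is
// reshuffled every epoch with R's RNG, so results are reproducible from
// set.seed().  Epoch RMSE uses each exemplar's output as computed just
// before its own update; training stops when RMSE < threshold.
// [[Rcpp::export]]
List cpp_train(List layers, List plans, NumericVector targets, double eta,
               double momentum, double rmse_threshold, int max_epochs) {
  Lib L = lib_in(layers);
  int n = plans.size();
  std::vector<Plan> P(n);
  for (int i = 0; i < n; ++i) P[i] = plan_in(plans[i]);
  Accum A; A.init(L);
  std::vector<std::vector<double> > act;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  NumericVector history(max_epochs);
  bool converged = false;
  int epoch = 0;
  double rmse = NA_REAL;
  RNGScope rng;
  while (epoch < max_epochs) {
    ++epoch;
    // Fisher-Yates reshuffle from R's RNG stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double sse = 0.0;
    for (int m = 0; m < n; ++m) {
      int i = ord[m];
      double out = backward(L, P[i], targets[i], eta, act,
        [&](int, int k, const std::vector<double>& dwk,
            const std::vector<double>& dbk) { A.add(k, dwk, dbk); });
      A.apply(L, momentum);
      double err = targets[i] - out;
      sse += err * err;
    }
    rmse = std::sqrt(sse / n);
    history[epoch - 1] = rmse;
    if (rmse < rmse_threshold) { converged = true; break; }
    if (epoch % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["layers"] = lib_out(L, layers),
                      _["converged"] = converged,
                      _["epochs"] = epoch,
                      _["final_rmse"] = rmse,
                      _["rmse_history"] = history[Range(0, epoch - 1)]);
}
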