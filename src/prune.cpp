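// Felsenstein pruning over the 61-state codon alphabet for the
// branch-site mixture: builds the per-edge transition matrices from the
// cached eigendecompositions and prunes every site class in one call.
// Rate matrices, eigendecompositions, class mixing and optimization
// stay in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// edge_child / edge_parent: 1-based node indices, ordered so that every
// edge below a node comes before the edge above it (deepest child
// first). states: n_tip x S, 0 = missing, else 1..61. decs: one
// eigendecomposition (left, values, right) per distinct omega; widx:
// n_class x n_edge 1-based index into decs. Branch lengths are divided
// by `scale` (the mixture mean rate). Returns n_class x S per-site
// log-likelihoods.
// [[Rcpp::export(name = ".bs_class_logliks")]]
arma::mat bs_class_logliks(const IntegerVector& edge_child,
                           const IntegerVector& edge_parent,
                           int n_tip, int n_node,
                           const IntegerMatrix& states,
                           const List& decs,
                           const arma::vec& edge_len,
                           double scale,
                           const IntegerMatrix& widx,
                           const arma::vec& pi,
                           int root) {
  const int E = edge_child.size();
  const int S = states.ncol();
  const int n_class = widx.nrow();
  const int n_w = decs.size();

  // lazily built transition matrices per (omega, edge)
  std::vector<arma::mat> P(static_cast<size_t>(n_w) * E);
  std::vector<bool> built(static_cast<size_t>(n_w) * E, false);
  std::vector<arma::mat> left(n_w), right(n_w);
  std::vector<arma::vec> values(n_w);
  for (int w = 0; w < n_w; ++w) {
    List d = decs[w];
    left[w] = as<arma::mat>(d["left"]);
    values[w] = as<arma::vec>(d["values"]);
    right[w] = as<arma::mat>(d["right"]);
  }
  arma::mat out(n_class, S);

  for (int cl = 0; cl < n_class; ++cl) {
    std::vector<arma::mat> cond(n_node + 1);
    std::vector<bool> started(n_node + 1, false);
    arma::rowvec logscale(S, arma::fill::zeros);
    for (int k = 0; k < E; ++k) {
      const int child = edge_child[k];
      const int parent = edge_parent[k];
      const int w = widx(cl, k) - 1;
      const size_t pk = static_cast<size_t>(w) * E + k;
      if (!built[pk]) {
        arma::vec ev = arma::exp(values[w] * (edge_len[k] / scale));
        P[pk] = left[w] * arma::diagmat(ev) * right[w];
        P[pk].transform([](double x) { return x < 0 ? 0.0 : x; });
        built[pk] = true;
      }
      const arma::mat& Pk = P[pk];
      arma::mat msg(61, S);
      if (child <= n_tip) {
        for (int s = 0; s < S; ++s) {
          int st = states(child - 1, s);
          if (st == 0) msg.col(s).ones();
          else msg.col(s) = Pk.col(st - 1);
        }
      } else {
        msg = Pk * cond[child];
        cond[child].reset();
        // scale internal messages to guard against underflow
        arma::rowvec cs = arma::sum(msg, 0);
        cs.elem(arma::find(cs == 0)).ones();
        msg.each_row() /= cs;
        logscale += arma::log(cs);
      }
      if (!started[parent]) {
        cond[parent] = msg;
        started[parent] = true;
      } else {
        cond[parent] %= msg;
      }
    }
    arma::rowvec site = pi.t() * cond[root];
    out.row(cl) = arma::log(site) + logscale;
  }
  return out;
}
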