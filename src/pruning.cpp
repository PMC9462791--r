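// Felsenstein pruning for k-state continuous-time Markov chains on a fixed
// rooted tree, with an optional discrete rate mixture (gamma categories).
// Shared by the amino-acid ancestral reconstruction machinery (k = 20) and
// the compound binary-pair chain used for correlated evolution (k = 4).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// P(t) = exp(Q * t) via eigendecomposition when Q is cleanly diagonalizable,
// falling back to arma::expmat. Small negative entries from roundoff are
// clamped to zero and rows renormalized.
static arma::mat clean_pmat(arma::mat P) {
  P.elem(arma::find(P < 0.0)).zeros();
  arma::colvec rs = arma::sum(P, 1);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    if (rs(i) > 0) P.row(i) /= rs(i);
  }
  return P;
}

struct EigQ {
  bool ok;
  arma::cx_mat V;
  arma::cx_mat Vinv;
  arma::cx_vec lambda;
};

static EigQ eig_setup(const arma::mat& Q) {
  EigQ e;
  e.ok = false;
  arma::cx_vec lambda;
  arma::cx_mat V;
  if (!arma::eig_gen(lambda, V, Q)) return e;
  arma::cx_mat Vinv;
  if (!arma::inv(Vinv, V)) return e;
  // guard against near-defective decompositions
  double c = arma::norm(V, 2) * arma::norm(Vinv, 2);
  if (!std::isfinite(c) || c > 1e8) return e;
  e.ok = true;
  e.V = V;
  e.Vinv = Vinv;
  e.lambda = lambda;
  return e;
}

static arma::mat pmat(const EigQ& e, const arma::mat& Q, double t) {
  if (t <= 0.0) return arma::eye(Q.n_rows, Q.n_cols);
  if (e.ok) {
    arma::cx_mat D = arma::diagmat(arma::exp(e.lambda * t));
    arma::mat P = arma::real(e.V * D * e.Vinv);
    return clean_pmat(P);
  }
  return clean_pmat(arma::expmat(Q * t));
}

// Pruning over a postorder edge list.
//
// edge: (n_edge x 2) integer matrix, 1-based ape node ids, postorder
//       (children appear before their parents).
// tip_partials: cube (k x n_sites x n_tip).
// Returns per-site log-likelihood (mixed over categories) and, optionally,
// per-category scaled up-pass partials, per-node cumulative log scalers and
// the per-edge transition matrices (needed by the marginal down pass in R).
// [[Rcpp::export]]
List cpp_pruning(const arma::mat& Q,
                 const arma::imat& edge,
                 const arma::vec& edge_len,
                 const int n_tip,
                 const int n_node,
                 const int root,
                 const arma::cube& tip_partials,
                 const arma::vec& root_prior,
                 const arma::vec& rates,
                 const arma::vec& weights,
                 const bool want_partials) {
  const arma::uword k = Q.n_rows;
  const arma::uword n_sites = tip_partials.n_cols;
  const arma::uword n_edge = edge.n_rows;
  const arma::uword n_cat = rates.n_elem;

  EigQ eq = eig_setup(Q);

  arma::mat site_ll(n_sites, n_cat);   // per-category log-likelihood
  List up_list(n_cat), scale_list(n_cat), P_list(n_cat);

  for (arma::uword c = 0; c < n_cat; ++c) {
    // transition matrices for this category
    arma::cube P(k, k, n_edge);
    for (arma::uword e = 0; e < n_edge; ++e) {
      P.slice(e) = pmat(eq, Q, rates(c) * edge_len(e));
    }

    arma::cube up(k, n_sites, n_node, arma::fill::none);
    arma::mat lsc(n_node, n_sites, arma::fill::zeros); // cumulative log scalers
    for (int v = 0; v < n_tip; ++v) up.slice(v) = tip_partials.slice(v);
    for (int v = n_tip; v < n_node; ++v) up.slice(v).ones();

    for (arma::uword e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0) - 1;
      const int chi = edge(e, 1) - 1;
      arma::mat msg = P.slice(e) * up.slice(chi);  // k x n_sites
      up.slice(par) %= msg;
      lsc.row(par) += lsc.row(chi);
      // rescale parent columns to avoid underflow
      arma::rowvec m = arma::max(up.slice(par), 0);
      for (arma::uword s = 0; s < n_sites; ++s) {
        if (m(s) > 0 && (m(s) < 1e-100 || m(s) > 1e100)) {
          up.slice(par).col(s) /= m(s);
          lsc(par, s) += std::log(m(s));
        }
      }
    }

    arma::rowvec root_like = root_prior.t() * up.slice(root - 1);
    for (arma::uword s = 0; s < n_sites; ++s) {
      double l = root_like(s);
      site_ll(s, c) = (l > 0 ? std::log(l) : -arma::datum::inf) + lsc(root - 1, s);
    }

    if (want_partials) {
      up_list[c] = up;
      scale_list[c] = lsc;
      P_list[c] = P;
    }
  }

  // mix categories: log sum_c w_c exp(ll_c)
  arma::vec ll(n_sites);
  arma::vec lw = arma::log(weights);
  for (arma::uword s = 0; s < n_sites; ++s) {
    arma::vec v = site_ll.row(s).t() + lw;
    double m = v.max();
    ll(s) = std::isfinite(m) ? m + std::log(arma::sum(arma::exp(v - m))) : m;
  }

  if (!want_partials) {
    return List::create(_["site_loglik"] = ll, _["cat_loglik"] = site_ll);
  }
  return List::create(_["site_loglik"] = ll,
                      _["cat_loglik"] = site_ll,
                      _["up"] = up_list,
                      _["scalers"] = scale_list,
                      _["P"] = P_list);
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::mat& Q, const double t) {
  EigQ eq = eig_setup(Q);
  return pmat(eq, Q, t);
}
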