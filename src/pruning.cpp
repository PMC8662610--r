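// Felsenstein pruning over the 61 sense-codon states with per-node scaling.
// The mixture layer (site classes, class proportions) lives in R; this file
// evaluates the per-pattern log-likelihood for one fully specified set of
// per-edge transition matrices, supplied as spectral decompositions so that
// P(t) = U diag(exp(lambda * t)) Uinv can be formed cheaply per edge.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// edge:       (nedge x 2) 1-based postorder edge matrix (parent, child)
// tlen:       branch length per edge, in expected substitutions per codon
// mat_id:     1-based index into the decomposition cube, per edge
// U, Uinv:    (ns x ns x nmat) cubes; lambda: (ns x nmat)
// tip_states: (ntip x npat) 1-based sense-codon index, 0 = missing/gap
// pi:         root (equilibrium) frequencies, length ns
// returns per-pattern log-likelihood (length npat)
// [[Rcpp::export]]
arma::vec pruning_loglik_cpp(const arma::imat& edge,
                             const arma::vec& tlen,
                             const arma::ivec& mat_id,
                             const arma::cube& U,
                             const arma::cube& Uinv,
                             const arma::mat& lambda,
                             const arma::imat& tip_states,
                             const arma::vec& pi,
                             const int n_node) {
  const arma::uword ns = pi.n_elem;
  const arma::uword npat = tip_states.n_cols;
  const arma::uword ntip = tip_states.n_rows;
  const arma::uword nedge = edge.n_rows;

  arma::cube part(ns, npat, n_node);
  std::vector<bool> used(n_node, false);
  arma::vec logscale(npat, arma::fill::zeros);

  for (arma::uword e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const arma::uword m = static_cast<arma::uword>(mat_id(e) - 1);

    arma::mat P = U.slice(m) * arma::diagmat(arma::exp(lambda.col(m) * tlen(e))) *
      Uinv.slice(m);
    // clamp tiny negative entries from the spectral reconstruction
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });

    arma::mat down(ns, npat);
    if (static_cast<arma::uword>(child) < ntip) {
      // tip: P %*% indicator; missing state -> row sums of P (all ones)
      arma::vec rs = arma::sum(P, 1);
      for (arma::uword p = 0; p < npat; ++p) {
        const int s = tip_states(child, p);
        if (s == 0) {
          down.col(p) = rs;
        } else {
          down.col(p) = P.col(s - 1);
        }
      }
    } else {
      down = P * part.slice(child);
    }

    if (!used[parent]) {
      part.slice(parent) = down;
      used[parent] = true;
    } else {
      part.slice(parent) %= down;
      // rescale to avoid underflow on deep trees
      arma::rowvec mx = arma::max(part.slice(parent), 0);
      for (arma::uword p = 0; p < npat; ++p) {
        if (mx(p) > 0 && mx(p) < 1e-200) {
          part.slice(parent).col(p) /= mx(p);
          logscale(p) += std::log(mx(p));
        }
      }
    }
  }

  const int root = edge(nedge - 1, 0) - 1;
  arma::vec out(npat);
  for (arma::uword p = 0; p < npat; ++p) {
    double L = arma::dot(pi, part.slice(root).col(p));
    out(p) = (L > 0 ? std::log(L) : -1e300) + logscale(p);
  }
  return out;
}

// Pruning for branch-site random-effects models: each edge's transition
// kernel is the weight-mixture of per-category matrices,
// P_e = sum_c wts(e,c) * U_c exp(lambda_c tmat(e,c)) Uinv_c
// (tmat carries the per-category rate-scaled branch length).
// [[Rcpp::export]]
arma::vec pruning_loglik_mix_cpp(const arma::imat& edge,
                                 const arma::mat& tmat,
                                 const arma::imat& mat_ids,
                                 const arma::mat& wts,
                                 const arma::cube& U,
                                 const arma::cube& Uinv,
                                 const arma::mat& lambda,
                                 const arma::imat& tip_states,
                                 const arma::vec& pi,
                                 const int n_node) {
  const arma::uword ns = pi.n_elem;
  const arma::uword npat = tip_states.n_cols;
  const arma::uword ntip = tip_states.n_rows;
  const arma::uword nedge = edge.n_rows;
  const arma::uword ncomp = mat_ids.n_cols;

  arma::cube part(ns, npat, n_node);
  std::vector<bool> used(n_node, false);
  arma::vec logscale(npat, arma::fill::zeros);

  for (arma::uword e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    arma::mat Pe(ns, ns, arma::fill::zeros);
    for (arma::uword c = 0; c < ncomp; ++c) {
      const double w = wts(e, c);
      if (w <= 0) continue;
      const arma::uword m = static_cast<arma::uword>(mat_ids(e, c) - 1);
      Pe += w * (U.slice(m) *
                 arma::diagmat(arma::exp(lambda.col(m) * tmat(e, c))) *
                 Uinv.slice(m));
    }
    Pe.transform([](double x) { return x < 0.0 ? 0.0 : x; });

    arma::mat down(ns, npat);
    if (static_cast<arma::uword>(child) < ntip) {
      arma::vec rs = arma::sum(Pe, 1);
      for (arma::uword p = 0; p < npat; ++p) {
        const int s = tip_states(child, p);
        down.col(p) = (s == 0) ? rs : arma::vec(Pe.col(s - 1));
      }
    } else {
      down = Pe * part.slice(child);
    }
    if (!used[parent]) {
      part.slice(parent) = down;
      used[parent] = true;
    } else {
      part.slice(parent) %= down;
      arma::rowvec mx = arma::max(part.slice(parent), 0);
      for (arma::uword p = 0; p < npat; ++p) {
        if (mx(p) > 0 && mx(p) < 1e-200) {
          part.slice(parent).col(p) /= mx(p);
          logscale(p) += std::log(mx(p));
        }
      }
    }
  }
  const int root = edge(nedge - 1, 0) - 1;
  arma::vec out(npat);
  for (arma::uword p = 0; p < npat; ++p) {
    double L = arma::dot(pi, part.slice(root).col(p));
    out(p) = (L > 0 ? std::log(L) : -1e300) + logscale(p);
  }
  return out;
}

// Simulate one edge: given parent states (1-based, length nsite) and the edge's
// P matrix rows as cumulative sums, draw child states. Kept in C++ for speed of
// long simulated alignments.
// [[Rcpp::export]]
IntegerVector evolve_states_cpp(const IntegerVector& parent_states,
                                const arma::mat& P,
                                const NumericVector& unif) {
  const int n = parent_states.size();
  const arma::uword ns = P.n_cols;
  IntegerVector child(n);
  for (int i = 0; i < n; ++i) {
    const arma::uword s = parent_states[i] - 1;
    double acc = 0.0;
    const double u = unif[i];
    arma::uword j = 0;
    for (; j < ns; ++j) {
      acc += P(s, j);
      if (u <= acc) break;
    }
    if (j >= ns) j = ns - 1;
    child[i] = static_cast<int>(j) + 1;
  }
  return child;
}
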