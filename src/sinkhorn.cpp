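#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Stabilized Sinkhorn iterations for entropy-regularized optimal transport
// (scaling form with log-domain absorption, Schmitzer-style).
//
// Solves min <M, G> + eps * KL(G | p q^T) over couplings with marginals
// p and q. Dual potentials f, g are warm-startable across calls; the
// coupling is G_ij = exp((f_i + g_j - M_ij) / eps). Iterations run as
// cheap matrix-vector scalings u = p / (E v), v = q / (E^T u) on the
// kernel E = exp((f + g - M)/eps); whenever a scaling factor grows past
// the absorption threshold it is folded back into the potentials and the
// kernel is rebuilt, which keeps everything inside double range for
// arbitrarily small eps.
//
// [[Rcpp::export(name = ".sinkhorn_log_cpp")]]
Rcpp::List sinkhorn_log_cpp(const arma::mat& M,
                            const arma::vec& p,
                            const arma::vec& q,
                            double eps,
                            arma::vec f,
                            arma::vec g,
                            int max_iter,
                            double tol) {
  const uword n = M.n_rows, m = M.n_cols;
  const double absorb = 1e100;
  const vec lp = log(p), lq = log(q);
  const mat Mt = M.t();

  mat E(n, m);
  auto rebuild = [&]() {
    for (uword j = 0; j < m; ++j) {
      E.col(j) = exp((f + g(j) - M.col(j)) / eps);
    }
  };
  auto lse = [](const vec& a) {
    double mx = a.max();
    if (!std::isfinite(mx)) return mx;
    return mx + std::log(accu(exp(a - mx)));
  };
  // full log-domain half-iterations; used when the scaling kernel
  // underflows to zero rows (cold starts with small eps)
  auto log_step = [&]() {
    for (uword i = 0; i < n; ++i) {
      f(i) = eps * (lp(i) - lse((g - Mt.col(i)) / eps));
    }
    for (uword j = 0; j < m; ++j) {
      g(j) = eps * (lq(j) - lse((f - M.col(j)) / eps));
    }
    rebuild();
  };
  rebuild();

  vec u(n, fill::ones), v(m, fill::ones);
  double err = datum::inf;
  int it = 0;
  while (it < max_iter) {
    ++it;
    vec Ev = E * v;
    if (Ev.min() <= 0 || !Ev.is_finite()) {
      log_step();
      u.ones();
      v.ones();
      continue;
    }
    u = p / Ev;
    vec Etu = E.t() * u;
    if (Etu.min() <= 0 || !Etu.is_finite()) {
      log_step();
      u.ones();
      v.ones();
      continue;
    }
    v = q / Etu;
    if (u.max() > absorb || v.max() > absorb ||
        u.min() < 1.0 / absorb || v.min() < 1.0 / absorb) {
      f += eps * log(u);
      g += eps * log(v);
      rebuild();
      u.ones();
      v.ones();
    }
    if (it % 5 == 0 || it == max_iter) {
      // row marginals of the current coupling diag(u) E diag(v)
      vec rs = u % (E * v);
      err = abs(rs - p).max();
      if (err < tol) break;
    }
  }

  f += eps * log(u);
  g += eps * log(v);
  rebuild();  // E now holds the coupling itself

  return Rcpp::List::create(Rcpp::Named("gamma") = E,
                            Rcpp::Named("f") = f,
                            Rcpp::Named("g") = g,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("marginal_error") = err);
}
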