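#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Matrix exponential of a dense generator (scaling-and-squaring Pade).
// [[Rcpp::export(name = ".cpp_expm")]]
arma::mat cpp_expm(const arma::mat& M) {
  arma::mat E;
  bool ok = arma::expmat(E, M);
  if (!ok || !E.is_finite()) {
    Rcpp::stop("matrix exponential failed (overflow or non-finite input)");
  }
  return E;
}

// Matrix exponential of t * Q for a *reversible* generator via
// symmetrization: A = D^-1 Q D with D = diag(sqrt(pi)) has off-diagonals
// sqrt(Q(i,j) * Q(j,i)) and is symmetric, so expm(tQ) =
// D U exp(t Lambda) U' D^-1 from the orthogonal eigendecomposition of A.
// This stays accurate where Pade scaling-and-squaring breaks down
// (||tQ|| >> 1e9). The exact null mode (eigenvector sqrt(pi)) is deflated
// and re-added exactly. Returns an empty matrix when Q is not numerically
// reversible (caller falls back to Pade).
// [[Rcpp::export(name = ".cpp_expm_reversible")]]
arma::mat cpp_expm_reversible(const arma::mat& Q, const double t) {
  const arma::uword n = Q.n_rows;
  // log stationary potentials by BFS over the rate-ratio graph
  arma::vec phi(n);
  phi.fill(arma::datum::nan);
  phi(0) = 0.0;
  std::vector<arma::uword> queue{0};
  while (!queue.empty()) {
    const arma::uword i = queue.back();
    queue.pop_back();
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i || Q(j, i) <= 0.0) continue;
      if (Q(i, j) <= 0.0) return arma::mat();  // one-way edge
      const double lr = std::log(Q(j, i)) - std::log(Q(i, j));
      if (std::isnan(phi(j))) {
        phi(j) = phi(i) + lr;
        queue.push_back(j);
      } else if (std::abs(phi(j) - phi(i) - lr) >
                 1e-6 * std::max(1.0, std::abs(phi(j)))) {
        return arma::mat();  // cycle inconsistency: not reversible
      }
    }
  }
  if (phi.has_nan()) return arma::mat();  // disconnected
  arma::vec d = arma::exp((phi - arma::mean(phi)) / 2.0);
  if (!d.is_finite()) return arma::mat();
  arma::mat A = arma::sqrt(Q % Q.t());
  A.diag() = Q.diag();
  arma::vec lam;
  arma::mat U;
  if (!arma::eig_sym(lam, U, A)) return arma::mat();
  arma::vec w = d / arma::norm(d);
  arma::vec proj = arma::abs(U.t() * w);
  const arma::uword k0 = proj.index_max();
  lam = arma::clamp(lam, -arma::datum::inf, 0.0);
  arma::vec elam = arma::exp(t * lam);
  elam(k0) = 0.0;  // deflated; stationary term re-added exactly below
  arma::mat E = U * arma::diagmat(elam) * U.t() + w * w.t();
  arma::mat H = E % (d * (1.0 / d).t());
  if (!H.is_finite()) return arma::mat();
  return H;
}

// Largest-magnitude eigenvalue of a dense generator.
// [[Rcpp::export(name = ".cpp_spectral_radius")]]
double cpp_spectral_radius(const arma::mat& M) {
  arma::cx_vec ev;
  bool ok = arma::eig_gen(ev, M);
  if (!ok) Rcpp::stop("eigenvalue computation failed");
  return arma::abs(ev).max();
}

// Occupancy sampled on a fixed grid: y[i] = H * y[i-1] with H = expm(dt * Q)
// precomputed by the caller ("powering up" the exponential). Returns an
// (n_steps + 1) x n matrix whose first row is x0.
// [[Rcpp::export(name = ".cpp_power_trace")]]
arma::mat cpp_power_trace(const arma::mat& H, const arma::vec& x0,
                          const int n_steps) {
  const arma::uword n = x0.n_elem;
  arma::mat out(n_steps + 1, n);
  arma::vec x = x0;
  out.row(0) = x.t();
  for (int i = 1; i <= n_steps; ++i) {
    x = H * x;
    out.row(i) = x.t();
  }
  if (!out.is_finite()) {
    Rcpp::stop("trace propagation produced non-finite occupancies");
  }
  return out;
}
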