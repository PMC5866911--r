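// Gibbs sampler for Bayes-C / Bayes-Cpi whole-genome regression:
//   y = X beta + Z u + e,
// beta flat prior; u_j = delta_j * a_j with delta_j ~ Bern(1 - pi) and
// a_j ~ N(0, var_u) (one effect variance common to all included markers);
// var_u and var_e have scaled-inverse-chi-square priors; pi optionally
// sampled from its Beta full conditional under a uniform prior.
// Uses R's RNG so chains are reproducible via set.seed() and resumable
// across calls within a session.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fisher-Yates permutation using R's RNG.
static void permute(std::vector<int>& idx) {
  const int n = static_cast<int>(idx.size());
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix X, NumericMatrix Z,
                  int n_iter, int burnin, int thin,
                  double pi0, bool estimate_pi,
                  double var_u0, double var_e0,
                  double nu_u, double scale_u,
                  double nu_e, double scale_e,
                  bool fix_variances, bool pi_linked_scale,
                  Nullable<List> state_ = R_NilValue,
                  int iter_offset = 0) {
  const int n = y.size();
  const int p = X.ncol();
  const int m = Z.ncol();

  std::vector<double> beta(p, 0.0), u(m, 0.0);
  std::vector<int> delta(m, 0);
  double var_u = var_u0, var_e = var_e0, pi = pi0;
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  // Resume from a previous block if a state is supplied.
  if (state_.isNotNull()) {
    List st(state_);
    NumericVector b = st["beta"], uu = st["u"], ee = st["e"];
    IntegerVector dd = st["delta"];
    for (int k = 0; k < p; ++k) beta[k] = b[k];
    for (int j = 0; j < m; ++j) { u[j] = uu[j]; delta[j] = dd[j]; }
    for (int i = 0; i < n; ++i) e[i] = ee[i];
    var_u = st["var_u"]; var_e = st["var_e"]; pi = st["pi"];
  }

  // Precomputed cross-products of the design columns with themselves.
  std::vector<double> xx(p), zz(m);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xx[k] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }

  const int n_save = (n_iter - burnin > 0) ? (n_iter - burnin) / thin : 0;
  NumericMatrix U_save(n_save, m), B_save(n_save, p);
  NumericVector varu_save(n_save), vare_save(n_save), pi_save(n_save),
      varg_save(n_save), h2_save(n_save);
  IntegerVector iter_save(n_save);
  NumericVector pi_trace(n_iter), k_trace(n_iter);

  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  NumericVector g(n);

  GetRNGstate();
  int isave = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, flat prior ---
    for (int k = 0; k < p; ++k) {
      if (xx[k] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, k) * (e[i] + X(i, k) * beta[k]);
      double mean = rhs / xx[k];
      double newb = mean + norm_rand() * std::sqrt(var_e / xx[k]);
      double diff = newb - beta[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * diff;
      beta[k] = newb;
    }

    // --- marker effects with inclusion indicators ---
    permute(order);
    int k_in = 0;
    double uSS = 0.0;
    const double log_prior_in = (pi >= 1.0) ? R_NegInf
        : (pi <= 0.0) ? R_PosInf : std::log((1.0 - pi) / pi);
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      if (zz[j] <= 0.0) { u[j] = 0.0; delta[j] = 0; continue; }
      double rhs = 0.0;
      if (delta[j]) {
        const double uj = u[j];
        for (int i = 0; i < n; ++i) {
          e[i] += Z(i, j) * uj;
          rhs += Z(i, j) * e[i];
        }
      } else {
        for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      }
      const double C = zz[j] + var_e / var_u;
      // log Bayes factor of inclusion vs exclusion (effect integrated out)
      const double logBF = 0.5 * rhs * rhs / (var_e * C)
          - 0.5 * std::log(zz[j] * var_u / var_e + 1.0);
      double log_odds = logBF + log_prior_in;
      int inc;
      if (log_odds == R_PosInf) inc = 1;
      else if (log_odds == R_NegInf) inc = 0;
      else {
        const double pr = 1.0 / (1.0 + std::exp(-log_odds));
        inc = (unif_rand() < pr) ? 1 : 0;
      }
      if (inc) {
        const double mean = rhs / C;
        const double uj = mean + norm_rand() * std::sqrt(var_e / C);
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * uj;
        u[j] = uj; delta[j] = 1;
        ++k_in; uSS += uj * uj;
      } else {
        u[j] = 0.0; delta[j] = 0;
      }
    }

    // --- variance components ---
    if (!fix_variances) {
      // GenSel-style prior scale: the genomic prior variance is spread
      // over the (1 - pi) m markers expected to carry effects, so the
      // per-marker scale grows as pi approaches 1.
      const double s_u = pi_linked_scale
          ? scale_u / std::max(1.0 - pi, 1.0 / m) : scale_u;
      var_u = (uSS + nu_u * s_u) / R::rchisq(nu_u + k_in);
      double eSS = 0.0;
      for (int i = 0; i < n; ++i) eSS += e[i] * e[i];
      var_e = (eSS + nu_e * scale_e) / R::rchisq(nu_e + n);
      if (!R_finite(var_u) || !R_finite(var_e) || var_e <= 0.0) {
        PutRNGstate();
        stop("sampler failure at iteration %d: non-finite variance", it + 1);
      }
    }

    // --- pi ---
    if (estimate_pi) pi = R::rbeta(m - k_in + 1.0, k_in + 1.0);
    pi_trace[it] = pi;
    k_trace[it] = k_in;

    // --- save state ---
    if (it >= burnin && ((it - burnin + 1) % thin == 0) && isave < n_save) {
      double gsum = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = 0.0;
        for (int j = 0; j < m; ++j)
          if (delta[j]) gi += Z(i, j) * u[j];
        g[i] = gi; gsum += gi; gss += gi * gi;
      }
      const double var_g = (n > 1) ? (gss - gsum * gsum / n) / (n - 1) : 0.0;
      for (int j = 0; j < m; ++j) U_save(isave, j) = u[j];
      for (int k = 0; k < p; ++k) B_save(isave, k) = beta[k];
      varu_save[isave] = var_u; vare_save[isave] = var_e;
      pi_save[isave] = pi; varg_save[isave] = var_g;
      h2_save[isave] = (var_g + var_e > 0.0) ? var_g / (var_g + var_e) : 0.0;
      iter_save[isave] = iter_offset + it + 1;
      ++isave;
    }
  }
  PutRNGstate();

  List state = List::create(
      _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["u"] = NumericVector(u.begin(), u.end()),
      _["delta"] = IntegerVector(delta.begin(), delta.end()),
      _["e"] = e, _["var_u"] = var_u, _["var_e"] = var_e, _["pi"] = pi);

  return List::create(
      _["U"] = U_save, _["B"] = B_save,
      _["var_u"] = varu_save, _["var_e"] = vare_save,
      _["pi"] = pi_save, _["var_g"] = varg_save, _["h2"] = h2_save,
      _["iter"] = iter_save,
      _["pi_trace"] = pi_trace, _["n_included_trace"] = k_trace,
      _["state"] = state);
}
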