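// Fast backend for the epigenotype Markov model: transition kernels,
// non-integer matrix powers, expected pairwise divergence and the
// constrained least-squares objective.  The exported R functions in
// R/kernels.R implement the same quantities independently in pure R and
// are cross-checked against these routines in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// systems: 1 = selfing, 2 = clonal/somatic
// forms:   1 = ABneutral, 2 = ABmm, 3 = ABuu, 4 = ABnull
// state order everywhere: (u/u, m/u, m/m)

static mat raw_G(const int system, const double a, const double b) {
  mat G(3, 3);
  G(0, 0) = (1 - a) * (1 - a);
  G(0, 1) = 2 * (1 - a) * a;
  G(0, 2) = a * a;
  G(2, 0) = b * b;
  G(2, 1) = 2 * (1 - b) * b;
  G(2, 2) = (1 - b) * (1 - b);
  if (system == 1) {            // selfing: Mendelian segregation of m/u
    G(1, 0) = 0.25 * (b + 1 - a) * (b + 1 - a);
    G(1, 1) = 0.50 * (b + 1 - a) * (a + 1 - b);
    G(1, 2) = 0.25 * (a + 1 - b) * (a + 1 - b);
  } else {                      // clonal/somatic: alleles switch independently
    G(1, 0) = b * (1 - a);
    G(1, 1) = (1 - a) * (1 - b) + a * b;
    G(1, 2) = a * (1 - b);
  }
  return G;
}

static mat sel_W(const int form, const double w) {
  mat W(3, 3, fill::ones);
  if (form == 2) {              // ABmm: selection against u
    W.col(0).fill(w);
    W.col(1).fill((w + 1) / 2);
  } else if (form == 3) {       // ABuu: selection against m
    W.col(1).fill((w + 1) / 2);
    W.col(2).fill(w);
  }
  return W;
}

static mat norm_kernel(const int system, const int form,
                       const double a, const double b, const double w) {
  mat G = raw_G(system, a, b) % sel_W(form, w);
  const vec rs = sum(G, 1);
  if (rs.min() <= 0)
    Rcpp::stop("selection weights annihilate a whole kernel row");
  G.each_col() /= rs;
  return G;
}

// [[Rcpp::export]]
arma::mat cpp_kernel(const int system, const int form,
                     const double alpha, const double beta, const double w) {
  return norm_kernel(system, form, alpha, beta, w);
}

struct EigPow {
  cx_mat P, Pinv;
  cx_vec d;
  mat rP, rPinv;                // real fast path (typical case)
  vec rd;
  mat G;
  bool ok;                      // eigendecomposition well conditioned
  bool real_ok;                 // spectrum real and positive
};

static EigPow eig_setup(const mat& G) {
  EigPow e;
  e.G = G;
  e.real_ok = false;
  cx_vec d;
  cx_mat P;
  e.ok = eig_gen(d, P, G);
  if (e.ok && rcond(P) > 1e-12) {
    e.P = P;
    e.Pinv = inv(P);
    e.d = d;
    if (norm(imag(d), "inf") < 1e-12 && real(d).min() > 0 &&
        norm(imag(P), "inf") < 1e-12) {
      e.real_ok = true;
      e.rP = real(P);
      e.rPinv = real(e.Pinv);
      e.rd = real(d);
    }
  } else {
    e.ok = false;
  }
  return e;
}

static mat eig_power(const EigPow& e, const double tau) {
  if (tau == 0) return eye(3, 3);
  if (e.real_ok) {
    vec dt(3);
    for (uword i = 0; i < 3; ++i) dt(i) = std::pow(e.rd(i), tau);
    return e.rP * diagmat(dt) * e.rPinv;
  }
  if (e.ok) {
    cx_vec dt(3);
    for (uword i = 0; i < 3; ++i)
      dt(i) = std::pow(e.d(i), std::complex<double>(tau, 0.0));
    return real(e.P * diagmat(dt) * e.Pinv);
  }
  // nearly defective kernel: exact repeated multiplication for integer tau,
  // scaling-and-squaring of the matrix logarithm otherwise
  const double ri = std::round(tau);
  if (std::abs(tau - ri) < 1e-9 && ri >= 0) {
    mat out = eye(3, 3);
    for (int k = 0; k < (int)ri; ++k) out = out * e.G;
    return out;
  }
  const cx_mat L = logmat(conv_to<cx_mat>::from(e.G));
  return real(expmat(cx_mat(L * std::complex<double>(tau, 0.0))));
}

// [[Rcpp::export]]
arma::mat cpp_kernel_power(const arma::mat& G, const double tau) {
  if (tau < 0) Rcpp::stop("tau must be non-negative");
  return eig_power(eig_setup(G), tau);
}

// Expected divergence for every (t_ij, t_i, t_j) row of `times`, given the
// founder distribution built from (p1_obs, p3_obs, gamma).
// [[Rcpp::export]]
arma::vec cpp_pred_d(const int system, const int form,
                     const double alpha, const double beta,
                     const double w, const double gamma,
                     const double p1_obs, const double p3_obs,
                     const arma::mat& times) {
  const mat G = norm_kernel(system, form, alpha, beta, w);
  const EigPow e = eig_setup(G);
  // founder distribution: mass observed as intermediate goes straight to
  // the heterozygote class; gamma splits only the observed-methylated mass
  const double s = p1_obs + p3_obs;
  if (s <= 0) Rcpp::stop("founder state proportions sum to zero");
  if (s > 1 + 1e-9) Rcpp::stop("p1_obs + p3_obs exceeds 1");
  const double resid2 = std::max(1.0 - s, 0.0);
  rowvec pi = {p1_obs, resid2 + gamma * p3_obs, (1 - gamma) * p3_obs};
  pi /= accu(pi);
  mat IND = {{0.0, 0.5, 1.0}, {0.5, 0.0, 0.5}, {1.0, 0.5, 0.0}};

  std::map<double, mat> cache;
  auto powG = [&](double tau) -> const mat& {
    auto it = cache.find(tau);
    if (it == cache.end())
      it = cache.emplace(tau, eig_power(e, tau)).first;
    return it->second;
  };
  // expected divergence depends only on the time triple; datasets from
  // designed pedigrees have few distinct triples, so cache by triple
  std::map<std::array<double, 3>, double> dcache;

  const uword M = times.n_rows;
  vec out(M);
  for (uword q = 0; q < M; ++q) {
    const double tij = times(q, 0), ti = times(q, 1), tj = times(q, 2);
    if (tij < 1 - 1e-9 || ti < tij - 1e-9 || tj < tij - 1e-9)
      Rcpp::stop("invalid pair times: need t_ij >= 1 and t_i, t_j >= t_ij");
    const std::array<double, 3> key = {tij, ti, tj};
    auto hit = dcache.find(key);
    if (hit != dcache.end()) {
      out(q) = hit->second;
      continue;
    }
    const rowvec anc = pi * powG(tij - 1);
    const mat& A = powG(ti - tij);
    const mat& B = powG(tj - tij);
    const mat AIB = A * IND * B.t();
    double d = 0;
    for (uword n = 0; n < 3; ++n) d += anc(n) * AIB(n, n);
    dcache.emplace(key, d);
    out(q) = d;
  }
  return out;
}

// Equilibrium proportion of u/u loci.  Closed forms for the neutral (w = 1)
// selfing and clonal chains; dominant left eigenvector otherwise.
// [[Rcpp::export]]
double cpp_equilibrium_uu(const int system, const int form,
                          const double alpha, const double beta,
                          const double w) {
  if (alpha + beta <= 0)
    Rcpp::stop("equilibrium undefined for alpha = beta = 0");
  if (w == 1 || form == 1 || form == 4) {
    if (system == 2) return (beta * beta) / ((alpha + beta) * (alpha + beta));
    const double num = beta * ((1 - beta) * (1 - beta) -
                               (1 - alpha) * (1 - alpha) - 1);
    const double den = (alpha + beta) *
      ((alpha + beta - 1) * (alpha + beta - 1) - 2);
    return num / den;
  }
  const mat G = norm_kernel(system, form, alpha, beta, w);
  cx_vec d;
  cx_mat V;
  if (!eig_gen(d, V, G.t()))
    Rcpp::stop("eigendecomposition failed for stationary distribution");
  const uword i = index_max(real(d));
  vec v = abs(real(V.col(i)));
  v /= accu(v);
  return v(0);
}

// Constrained least-squares objective (residual SS plus M times the squared
// gap between the pooled u/u proportion and its model equilibrium).
// `utimes` holds the distinct (t_ij, t_i, t_j) triples of the dataset and
// `idx` maps each of the M pairs to its triple (1-based); both are computed
// once per fit so each optimizer step prices only the distinct triples.
// [[Rcpp::export]]
double cpp_objective(const int system, const int form,
                     const double alpha, const double beta,
                     const double w, const double gamma, const double c,
                     const double p1_obs, const double p3_obs,
                     const arma::mat& utimes, const arma::uvec& idx,
                     const arma::vec& D,
                     const double p_bar1, const bool use_constraint) {
  const vec predu = cpp_pred_d(system, form, alpha, beta, w, gamma,
                               p1_obs, p3_obs, utimes);
  double obj = 0;
  for (uword q = 0; q < D.n_elem; ++q) {
    const double r = D(q) - predu(idx(q) - 1) - c;
    obj += r * r;
  }
  if (use_constraint) {
    const double eq = cpp_equilibrium_uu(system, form, alpha, beta, w);
    const double gap = p_bar1 - eq;
    obj += D.n_elem * gap * gap;
  }
  return obj;
}
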