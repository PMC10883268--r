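// Photon-by-photon hidden Markov model on tick-granular inter-photon
// intervals. The hidden chain steps once per clock tick with transition
// matrix A; photons observed at ticks t_1 < ... < t_K emit a stream label
// from the occupying state's emission row. The likelihood conditions on the
// photon arrival times:
//   L = pi' diag(b_1) prod_k [ A^{dt_k} diag(b_{k+1}) ] 1.
// A^{dt} is evaluated exactly through the eigendecomposition A = R L R^{-1},
// cached over the distinct dt values in the data. The E-step transition
// counts over an interval of dt ticks use the spectral geometric sum
//   sum_{d=0}^{dt-1} lam_p^d lam_q^{dt-1-d}
// so no per-tick recursion is ever unrolled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Spectral {
  cx_mat R;   // right eigenvectors (columns)
  cx_mat L;   // inverse of R (rows are left eigenvectors)
  cx_vec lam; // eigenvalues
};

Spectral decompose(const mat& A) {
  Spectral sp;
  const uword N = A.n_rows;
  if (N == 1) {
    sp.R = cx_mat(1, 1, fill::ones);
    sp.L = cx_mat(1, 1, fill::ones);
    sp.lam = cx_vec(1);
    sp.lam(0) = cx_double(A(0, 0), 0.0);
    return sp;
  }
  cx_vec eigval;
  cx_mat eigvec;
  if (!eig_gen(eigval, eigvec, A))
    Rcpp::stop("eigendecomposition of transition matrix failed");
  cx_mat Linv;
  bool ok = inv(Linv, eigvec);
  if (!ok) {
    // near-defective matrix: tiny diagonal jitter restores diagonalizability
    mat Aj = A + 1e-12 * randu<mat>(N, N);
    Aj.each_col() /= sum(Aj, 1);
    if (!eig_gen(eigval, eigvec, Aj) || !inv(Linv, eigvec))
      Rcpp::stop("transition matrix is numerically defective");
  }
  sp.R = eigvec;
  sp.L = Linv;
  sp.lam = eigval;
  return sp;
}

// map from dt value to cache index, plus lam^dt and lam^(dt-1) tables
struct DtCache {
  std::unordered_map<double, uword> index;
  std::vector<mat> P;       // real transition kernel A^dt, clamped >= 0
  std::vector<cx_mat> S;    // spectral geometric sum S_pq(dt)
  std::vector<double> dtv;
};

DtCache build_cache(const Rcpp::List& dts, const Spectral& sp, bool need_S) {
  DtCache cache;
  const uword N = sp.lam.n_elem;
  for (R_xlen_t b = 0; b < dts.size(); ++b) {
    Rcpp::NumericVector v(dts[b]);
    for (R_xlen_t k = 1; k < v.size(); ++k) {
      double dt = v[k];
      if (dt < 0) Rcpp::stop("negative inter-photon interval");
      if (cache.index.count(dt)) continue;
      uword idx = cache.P.size();
      cache.index[dt] = idx;
      cache.dtv.push_back(dt);
      cx_vec lam_dt(N), lam_dtm1(N);
      for (uword p = 0; p < N; ++p) {
        lam_dt(p) = std::pow(sp.lam(p), dt);
        lam_dtm1(p) = dt >= 1.0 ? std::pow(sp.lam(p), dt - 1.0)
                                : cx_double(0.0, 0.0);
      }
      mat P = real(sp.R * diagmat(lam_dt) * sp.L);
      P.clamp(0.0, datum::inf);
      cache.P.push_back(P);
      if (need_S) {
        cx_mat S(N, N, fill::zeros);
        if (dt >= 1.0) {
          for (uword p = 0; p < N; ++p) {
            for (uword q = 0; q < N; ++q) {
              cx_double diff = sp.lam(p) - sp.lam(q);
              double scale = std::max(std::abs(sp.lam(p)),
                                      std::abs(sp.lam(q)));
              if (std::abs(diff) < 1e-10 * std::max(scale, 1e-30)) {
                S(p, q) = dt * lam_dtm1(p);
              } else {
                S(p, q) = (lam_dt(p) - lam_dt(q)) / diff;
              }
            }
          }
        }
        cache.S.push_back(S);
      }
    }
  }
  return cache;
}

} // namespace

// Forward-backward over all bursts. Returns total log-likelihood; when
// estep = true also the sufficient statistics: summed initial-state
// posteriors, emission numerator (N x 3), and expected tick-transition
// counts (N x N).
// [[Rcpp::export]]
Rcpp::List h2mm_forward_backward(Rcpp::List dts, Rcpp::List streams,
                                 arma::vec pi, arma::mat A, arma::mat B,
                                 bool estep) {
  const uword N = A.n_rows;
  Spectral sp = decompose(A);
  DtCache cache = build_cache(dts, sp, estep);

  double total_ll = 0.0;
  const R_xlen_t nb = dts.size();
  Rcpp::NumericVector burst_ll(nb);
  vec gamma1(N, fill::zeros);
  mat Bnum(N, B.n_cols, fill::zeros);
  cx_mat Msum(N, N, fill::zeros);
  bool degenerate = false;

  for (R_xlen_t b = 0; b < nb; ++b) {
    Rcpp::NumericVector dt(dts[b]);
    Rcpp::IntegerVector cs(streams[b]);
    const uword K = cs.size();
    if (K == 0) { burst_ll[b] = 0.0; continue; }

    mat alpha(N, K);
    vec scale(K);

    vec a = pi % B.col(cs[0]);
    double s = accu(a);
    if (s <= 0.0) { degenerate = true; burst_ll[b] = -datum::inf; continue; }
    a /= s;
    alpha.col(0) = a;
    scale(0) = s;

    bool bad = false;
    for (uword k = 1; k < K; ++k) {
      const mat& P = cache.P[cache.index[dt[k]]];
      vec anew = (P.t() * a) % B.col(cs[k]);
      double sk = accu(anew);
      if (sk <= 0.0 || !std::isfinite(sk)) { bad = true; break; }
      anew /= sk;
      alpha.col(k) = anew;
      scale(k) = sk;
      a = anew;
    }
    if (bad) { degenerate = true; burst_ll[b] = -datum::inf; continue; }

    double ll = accu(log(scale));
    burst_ll[b] = ll;
    total_ll += ll;

    if (!estep) continue;

    // backward pass with the same scaling; gamma_k = alpha_k % beta_k
    vec beta(N, fill::ones);
    // photon K-1 contributions
    gamma1 += (K == 1) ? alpha.col(0) : vec(N, fill::zeros);
    Bnum.col(cs[K - 1]) += alpha.col(K - 1) % beta;
    for (uword k = K - 1; k >= 1; --k) {
      uword ci = cache.index[dt[k]];
      const mat& P = cache.P[ci];
      const cx_mat& S = cache.S[ci];
      vec v = B.col(cs[k]) % beta;           // emission-weighted backward
      // interval transition statistics: u = alpha_{k-1}, divide by scale(k)
      cx_rowvec x = conv_to<cx_rowvec>::from(alpha.col(k - 1).t()) * sp.R;
      cx_vec y = sp.L * conv_to<cx_vec>::from(v);
      Msum += (x.st() * y.st()) % S / scale(k);
      beta = (P * v) / scale(k);
      vec g = alpha.col(k - 1) % beta;
      Bnum.col(cs[k - 1]) += g;
      if (k == 1) gamma1 += g;
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = total_ll,
      Rcpp::Named("loglik_burst") = burst_ll,
      Rcpp::Named("degenerate") = degenerate);
  if (estep) {
    mat T = real(sp.L.st() * Msum * sp.R.st());
    mat C = A % T;
    C.clamp(0.0, datum::inf);
    out["gamma1"] = gamma1;
    out["Bnum"] = Bnum;
    out["C"] = C;
  }
  return out;
}

// Most-likely state path per burst under the interval-resolved kernel.
// [[Rcpp::export]]
Rcpp::List h2mm_viterbi_cpp(Rcpp::List dts, Rcpp::List streams,
                            arma::vec pi, arma::mat A, arma::mat B) {
  const uword N = A.n_rows;
  Spectral sp = decompose(A);
  DtCache cache = build_cache(dts, sp, false);

  const double NEG = -datum::inf;
  auto safe_log = [&](double x) { return x > 0.0 ? std::log(x) : NEG; };

  vec lpi(N), work(N);
  for (uword i = 0; i < N; ++i) lpi(i) = safe_log(pi(i));
  mat lB(N, B.n_cols);
  for (uword i = 0; i < N; ++i)
    for (uword c = 0; c < B.n_cols; ++c) lB(i, c) = safe_log(B(i, c));

  const R_xlen_t nb = dts.size();
  Rcpp::List paths(nb);
  std::unordered_map<double, mat> logP;

  for (R_xlen_t b = 0; b < nb; ++b) {
    Rcpp::NumericVector dt(dts[b]);
    Rcpp::IntegerVector cs(streams[b]);
    const uword K = cs.size();
    Rcpp::IntegerVector path(K);
    if (K == 0) { paths[b] = path; continue; }

    vec phi = lpi + lB.col(cs[0]);
    umat back(N, K, fill::zeros);
    for (uword k = 1; k < K; ++k) {
      double d = dt[k];
      auto it = logP.find(d);
      if (it == logP.end()) {
        const mat& P = cache.P[cache.index[d]];
        mat lp(N, N);
        for (uword i = 0; i < N; ++i)
          for (uword j = 0; j < N; ++j) lp(i, j) = safe_log(P(i, j));
        it = logP.emplace(d, std::move(lp)).first;
      }
      const mat& lp = it->second;
      vec phin(N);
      for (uword j = 0; j < N; ++j) {
        double best = NEG;
        uword arg = 0;
        for (uword i = 0; i < N; ++i) {
          double cand = phi(i) + lp(i, j);
          if (cand > best) { best = cand; arg = i; }
        }
        phin(j) = best + lB(j, cs[k]);
        back(j, k) = arg;
      }
      phi = phin;
    }
    uword s = phi.index_max();
    path[K - 1] = s;
    for (uword k = K - 1; k >= 1; --k) {
      s = back(s, k);
      path[k - 1] = s;
    }
    paths[b] = path;
  }
  return paths;
}
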