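#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-10;

// Multiplicative MM updates for KL (Poisson) or Negative Binomial NMF.
// alpha empty => Poisson.  One outer iteration = H update then W update;
// the divergence trace holds the objective after each outer iteration.
// The objective is the generalized KL divergence for Poisson and
// d_N(V||WH) = sum V log(V/L) - (a+V) log((a+V)/(a+L)) for NB.
// [[Rcpp::export(name = ".nmf_mm_cpp")]]
Rcpp::List nmf_mm_cpp(const arma::mat& V, const arma::mat& W0,
                      const arma::mat& H0, const arma::vec& alpha,
                      double tol, int max_iter) {
  mat W = W0, H = H0;
  const bool nb = alpha.n_elem > 0;
  const uword N = V.n_rows, M = V.n_cols, n_cells = V.n_elem;

  // constants of the objective
  double vlogv_sum = 0.0, avlogav_sum = 0.0;
  const double v_sum = accu(V);
  for (uword i = 0; i < n_cells; ++i) {
    double v = V[i];
    if (v > 0) vlogv_sum += v * std::log(v);
  }
  mat AV;                      // alpha_n + V_nm
  if (nb) {
    if (alpha.n_elem != N) Rcpp::stop("alpha must have one entry per row of V");
    AV = V;
    AV.each_col() += alpha;
    for (uword i = 0; i < n_cells; ++i) avlogav_sum += AV[i] * std::log(AV[i]);
  }

  mat L(N, M), R1(N, M), R2;
  if (nb) R2.set_size(N, M);
  std::vector<double> trace;
  trace.reserve(512);
  double d_prev = datum::inf;
  bool converged = false;
  int it = 0;

  // fill R1 = V / clamp(L); for NB also R2 = (alpha+V)/(alpha+L)
  auto ratios = [&]() {
    if (nb) {
      for (uword j = 0; j < M; ++j) {
        const double* vp = V.colptr(j);
        const double* avp = AV.colptr(j);
        double* lp = L.colptr(j);
        double* r1 = R1.colptr(j);
        double* r2 = R2.colptr(j);
        for (uword i = 0; i < N; ++i) {
          double l = lp[i] > EPS ? lp[i] : EPS;
          r1[i] = vp[i] / l;
          r2[i] = avp[i] / (alpha[i] + l);
        }
      }
    } else {
      for (uword i = 0; i < n_cells; ++i) {
        double l = L[i] > EPS ? L[i] : EPS;
        R1[i] = V[i] / l;
      }
    }
  };

  auto objective = [&]() -> double {
    double s = 0.0;
    if (nb) {
      for (uword j = 0; j < M; ++j) {
        const double* vp = V.colptr(j);
        const double* avp = AV.colptr(j);
        const double* lp = L.colptr(j);
        for (uword i = 0; i < N; ++i) {
          double l = lp[i] > EPS ? lp[i] : EPS;
          s += avp[i] * std::log(alpha[i] + l) - vp[i] * std::log(l);
        }
      }
      return vlogv_sum - avlogav_sum + s;
    }
    for (uword i = 0; i < n_cells; ++i) {
      double l = L[i] > EPS ? L[i] : EPS;
      s += l - V[i] * std::log(l);
    }
    return vlogv_sum - v_sum + s;
  };

  for (it = 1; it <= max_iter; ++it) {
    // H update with W fixed
    L = W * H;
    ratios();
    if (nb) {
      H %= (W.t() * R1) / clamp(W.t() * R2, EPS, datum::inf);
    } else {
      H %= W.t() * R1;
      vec wsum = clamp(sum(W, 0).t(), EPS, datum::inf);
      H.each_col() /= wsum;
    }

    // W update with the new H
    L = W * H;
    ratios();
    if (nb) {
      W %= (R1 * H.t()) / clamp(R2 * H.t(), EPS, datum::inf);
    } else {
      W %= R1 * H.t();
      rowvec hsum = clamp(sum(H, 1).t(), EPS, datum::inf);
      W.each_row() /= hsum;
    }

    L = W * H;
    double d = objective();
    trace.push_back(d);
    if (std::abs(d_prev - d) / std::max(1.0, std::abs(d_prev)) < tol) {
      converged = true;
      break;
    }
    d_prev = d;
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// Exact linear assignment maximizing total score by bitmask dynamic
// programming over column subsets; suitable for the ranks used in
// signature matching (K <= 20).
// [[Rcpp::export(name = ".assign_max_cpp")]]
Rcpp::IntegerVector assign_max_cpp(const arma::mat& S) {
  const uword K = S.n_rows;
  if (S.n_cols != K) Rcpp::stop("score matrix must be square");
  if (K > 20) Rcpp::stop("assignment supported for K <= 20");
  const uword M = 1u << K;
  std::vector<double> f(M, -datum::inf);
  std::vector<int> choice(M, -1);
  f[0] = 0.0;
  for (uword mask = 0; mask < M - 1; ++mask) {
    if (!std::isfinite(f[mask])) continue;
    uword row = __builtin_popcount(mask);   // next row to assign
    for (uword j = 0; j < K; ++j) {
      if (mask & (1u << j)) continue;
      uword nmask = mask | (1u << j);
      double cand = f[mask] + S(row, j);
      if (cand > f[nmask]) {
        f[nmask] = cand;
        choice[nmask] = (int)j;
      }
    }
  }
  Rcpp::IntegerVector perm(K);
  uword mask = M - 1;
  for (int row = (int)K - 1; row >= 0; --row) {
    int j = choice[mask];
    perm[row] = j + 1;                      // 1-based
    mask &= ~(1u << j);
  }
  return perm;
}
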