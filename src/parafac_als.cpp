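#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact non-negative least squares for a small number of unknowns:
// minimize 0.5 x' G x - h' x subject to x >= 0, where G = Z'WZ and
// h = Z'Wy are the (weighted) normal equations of the row subproblem.
// For rank R the optimum's support is one of 2^R subsets, so full
// enumeration is exact and cheap for the R <= 8 used in practice.
static vec nnls_small(const mat& G, const vec& h) {
  const uword R = G.n_rows;
  vec x;
  bool ok = solve(x, G, h, solve_opts::no_approx + solve_opts::likely_sympd);
  if (ok && x.min() >= 0.0) return x;

  double best = 0.0;  // empty support: objective 0
  vec bestx(R, fill::zeros);
  const uword nsub = (1u << R);
  for (uword s = 1; s < nsub; ++s) {
    std::vector<uword> idx;
    for (uword r = 0; r < R; ++r)
      if (s & (1u << r)) idx.push_back(r);
    uvec f = conv_to<uvec>::from(idx);
    mat Gf = G.submat(f, f);
    vec hf = h.elem(f);
    vec xf;
    if (!solve(xf, Gf, hf, solve_opts::no_approx)) continue;
    if (xf.min() < 0.0) continue;
    vec xs(R, fill::zeros);
    xs.elem(f) = xf;
    double obj = 0.5 * dot(xs, G * xs) - dot(h, xs);
    if (obj < best) { best = obj; bestx = xs; }
  }
  return bestx;
}

static mat khatri_rao_cb(const mat& B, const mat& C) {
  // KR(jk, r) = B(j, r) * C(k, r), jk = j + J*k (column-major J x K)
  const uword J = B.n_rows, K = C.n_rows, R = B.n_cols;
  mat KR(J * K, R);
  for (uword r = 0; r < R; ++r)
    KR.col(r) = vectorise(B.col(r) * C.col(r).t());
  return KR;
}

// Weighted (masked) non-negative CP/PARAFAC alternating least squares.
// Xz:   I x (J*K) unfolded cube with masked-out cells set to zero
// mvec: length J*K, 1 for observed cells, 0 for missing; the mask is
//       shared by all samples (scatter excision depends on wavelengths only)
// [[Rcpp::export]]
Rcpp::List cpAlsNN(const arma::mat& Xz, const arma::vec& mvec,
                   int J, int K,
                   arma::mat A, arma::mat B, arma::mat C,
                   int maxIter, double tol) {
  const uword I = Xz.n_rows;
  const uword R = A.n_cols;
  const mat M = reshape(mvec, J, K);

  std::vector<double> losses;
  losses.reserve(maxIter);
  const double ssData = accu(square(Xz));
  double prev = datum::inf;
  bool converged = false;
  int it = 0;

  for (it = 0; it < maxIter; ++it) {
    // --- update A (sample scores): shared mask => one Gram matrix
    mat KR = khatri_rao_cb(B, C);
    mat KRm = KR.each_col() % mvec;
    mat G = KR.t() * KRm;
    mat H = Xz * KR;  // Xz is already zero on masked cells
    for (uword i = 0; i < I; ++i)
      A.row(i) = nnls_small(G, H.row(i).t()).t();

    mat T1 = A.t() * A;
    mat P = Xz.t() * A;  // (J*K) x R

    // --- update B (emission loadings), per-row mask over K
    mat C2(C.n_rows, R * R);
    for (uword r = 0; r < R; ++r)
      for (uword s = 0; s < R; ++s)
        C2.col(r * R + s) = C.col(r) % C.col(s);
    mat W = M * C2;  // J x R^2
    mat Q(J, R);
    for (uword r = 0; r < R; ++r) {
      mat Pr = reshape(P.col(r), J, K);
      Q.col(r) = Pr * C.col(r);
    }
    for (uword j = 0; j < (uword)J; ++j) {
      mat Gj = T1 % reshape(W.row(j).t(), R, R);
      B.row(j) = nnls_small(Gj, Q.row(j).t()).t();
    }

    // --- update C (excitation loadings), per-column mask over J
    mat B2(B.n_rows, R * R);
    for (uword r = 0; r < R; ++r)
      for (uword s = 0; s < R; ++s)
        B2.col(r * R + s) = B.col(r) % B.col(s);
    mat W2 = M.t() * B2;  // K x R^2
    mat Qc(K, R);
    for (uword r = 0; r < R; ++r) {
      mat Pr = reshape(P.col(r), J, K);
      Qc.col(r) = Pr.t() * B.col(r);
    }
    for (uword k = 0; k < (uword)K; ++k) {
      mat Gk = T1 % reshape(W2.row(k).t(), R, R);
      C.row(k) = nnls_small(Gk, Qc.row(k).t()).t();
    }

    // --- masked reconstruction loss
    mat KR2 = khatri_rao_cb(B, C);
    mat Xhat = A * KR2.t();
    Xhat.each_row() %= mvec.t();
    double loss = accu(square(Xz - Xhat));
    losses.push_back(loss);

    // converged on relative loss change, or on an exact fit: with
    // exact-rank data the loss decays geometrically toward zero and the
    // relative-change rule alone can never fire
    if ((std::isfinite(prev) &&
         std::fabs(prev - loss) <= tol * std::max(prev, 1e-300)) ||
        loss <= 1e-14 * ssData) {
      converged = true;
      ++it;
      break;
    }
    prev = loss;
  }

  return Rcpp::List::create(
      Rcpp::Named("A") = A, Rcpp::Named("B") = B, Rcpp::Named("C") = C,
      Rcpp::Named("losses") = losses,
      Rcpp::Named("iterations") = (int)losses.size(),
      Rcpp::Named("converged") = converged);
}
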