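// Pixelwise Lu-Chipman polar decomposition, the image-scale inner loop.
// Mirrors decompose_mueller() in R/decompose.R; the two are cross-checked
// in the test suite on random matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Inverse with singular values floored at eps.
static mat reg_inverse(const mat& m, double eps) {
  mat U, V;
  vec s;
  svd(U, s, V, m);
  return V * diagmat(1.0 / clamp(s, eps, datum::inf)) * U.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_decompose_image(Rcpp::NumericVector elements,
                               Rcpp::LogicalVector mask,
                               double eps) {
  Rcpp::IntegerVector dims = elements.attr("dim");
  if (dims.size() != 4 || dims[2] != 4 || dims[3] != 4)
    Rcpp::stop("`elements` must have dimension (rows, cols, 4, 4)");
  const int nr = dims[0], nc = dims[1];
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  if (mask.size() != npx) Rcpp::stop("mask size mismatch");

  Rcpp::NumericVector Dv(npx, NA_REAL), Pv(npx, NA_REAL),
      Rv(npx, NA_REAL), Del(npx, NA_REAL);
  int n_singular = 0, n_clamped = 0;

  const double* el = elements.begin();
  mat M(4, 4), MD(4, 4), Mp(4, 4), mp(3, 3), S(3, 3), m_delta(3, 3), m_r(3, 3);
  vec lam(3);
  mat evec(3, 3);

  for (R_xlen_t p = 0; p < npx; ++p) {
    if (!mask[p]) continue;
    for (int j = 0; j < 4; ++j)
      for (int i = 0; i < 4; ++i)
        M(i, j) = el[p + npx * (i + 4 * j)];
    if (!M.is_finite()) continue;

    const vec d = M.row(0).subvec(1, 3).t();
    const double D = norm(d);
    const double P = norm(M.col(0).subvec(1, 3));

    // diattenuator factor
    MD.eye();
    if (D > 0) {
      const vec du = (D > 1.0) ? vec(d / D) : d;
      const double Du = norm(du);
      MD(0, span(1, 3)) = du.t();
      MD(span(1, 3), 0) = du;
      const double sq = std::sqrt(std::max(0.0, 1.0 - Du * Du));
      MD(span(1, 3), span(1, 3)) =
          sq * eye(3, 3) + (1.0 - sq) * (du * du.t()) / (Du * Du);
    }

    bool singular = (D >= 1.0 - eps);
    if (singular) {
      ++n_singular;
      Mp = M * reg_inverse(MD, eps);
    } else {
      Mp = M * inv(MD);
    }
    mp = Mp(span(1, 3), span(1, 3));

    S = mp * mp.t();
    S = (S + S.t()) / 2.0;
    eig_sym(lam, evec, S);
    if (lam.min() < -eps && !singular) ++n_clamped;
    lam = clamp(lam, 0.0, datum::inf);
    double sgn = det(mp) < 0 ? -1.0 : 1.0;
    m_delta = sgn * evec * diagmat(sqrt(lam)) * evec.t();

    m_r = reg_inverse(m_delta, eps) * mp;
    double cR = (trace(m_r) + 1.0) / 2.0 - 1.0;
    cR = std::min(1.0, std::max(-1.0, cR));

    Dv[p] = D;
    Pv[p] = P;
    Rv[p] = std::acos(cR);
    Del[p] = 1.0 - std::fabs(trace(m_delta)) / 3.0;
  }

  return Rcpp::List::create(
      Rcpp::Named("D") = Dv, Rcpp::Named("P") = Pv,
      Rcpp::Named("R") = Rv, Rcpp::Named("Delta") = Del,
      Rcpp::Named("n_singular") = n_singular,
      Rcpp::Named("n_clamped") = n_clamped);
}
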