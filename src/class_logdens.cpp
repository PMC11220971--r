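// Multivariate-normal class densities for the latent class mixed model.
// Random effects are integrated analytically: for subject i and class g the
// transformed outcomes are jointly normal with covariance
//   V_ig = sigma^2 I + Z_i (omega_g^2 B) Z_i'.
// With A = Z_i (omega_g L), B = L L', the Woodbury identity and the matrix
// determinant lemma reduce every subject-class term to q x q algebra
// (q = number of random effects, at most 2):
//   r' V^{-1} r = (r'r - w' M^{-1} w) / sigma^2,  w = A' r,
//   log det V   = (n_i - q) log sigma^2 + log det M,
//   M = sigma^2 I_q + A' A.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double LOG2PI = 1.8378770664093454836;

// Returns an n_subj x G matrix of log(pi_g) + log phi(h_i; mu_ig, V_ig).
// R holds the link-transformed outcomes minus the shared fixed effects
// (h(y) - X beta); U the class design; L the lower Cholesky factor of B.
// start is the 0-based first row of each subject's block.
// [[Rcpp::export]]
arma::mat class_logdens_cpp(const arma::vec& R,
                            const arma::mat& U,
                            const arma::mat& Z,
                            const arma::ivec& start,
                            const arma::ivec& len,
                            const arma::mat& delta,
                            const arma::mat& L,
                            const double sigma2,
                            const arma::vec& logpi,
                            const arma::vec& omega2) {
  const int n_subj = start.n_elem;
  const int G = delta.n_cols;
  const int q = Z.n_cols;
  arma::mat out(n_subj, G);
  if (sigma2 <= 0.0) { out.fill(arma::datum::nan); return out; }
  const double log_s2 = std::log(sigma2);

  // scalar fast path for the standard configuration: random and class
  // designs both (intercept, time), so U and Z coincide
  const bool std_design = (q == 2) && (U.n_cols == 2) &&
    (Z.n_cols == U.n_cols) && arma::approx_equal(U, Z, "absdiff", 0.0);
  if (std_design) {
    const double l11 = L(0, 0), l21 = L(1, 0), l22 = L(1, 1);
    for (int i = 0; i < n_subj; ++i) {
      const int a = start[i];
      const int n_i = len[i];
      double n = 0, St = 0, St2 = 0, SR = 0, StR = 0, SR2 = 0;
      for (int j = a; j < a + n_i; ++j) {
        const double t = U(j, 1), r = R[j];
        n += 1.0; St += t; St2 += t * t;
        SR += r; StR += t * r; SR2 += r * r;
      }
      for (int g = 0; g < G; ++g) {
        const double d0 = delta(0, g), d1 = delta(1, g);
        // residual cross-products after subtracting the class trajectory
        const double zr0 = SR - d0 * n - d1 * St;       // sum e
        const double zr1 = StR - d0 * St - d1 * St2;    // sum t e
        const double rtr = SR2 - 2.0 * (d0 * SR + d1 * StR) +
          d0 * d0 * n + 2.0 * d0 * d1 * St + d1 * d1 * St2;
        const double om = std::sqrt(omega2[g]);
        // w = (om L)' (Z'e);  M = s2 I + (om L)' Z'Z (om L)
        const double w0 = om * (l11 * zr0 + l21 * zr1);
        const double w1 = om * (l22 * zr1);
        const double a11 = l11 * n + l21 * St, a12 = l22 * St;
        const double a21 = l11 * St + l21 * St2, a22 = l22 * St2;
        const double m11 = sigma2 + omega2[g] * (l11 * a11 + l21 * a21);
        const double m12 = omega2[g] * (l11 * a12 + l21 * a22);
        const double m22 = sigma2 + omega2[g] * (l22 * a22);
        const double detM = m11 * m22 - m12 * m12;
        if (!(detM > 0.0) || !(m11 > 0.0)) {
          out.fill(arma::datum::nan);
          return out;
        }
        const double wMw = (m22 * w0 * w0 - 2.0 * m12 * w0 * w1 +
                            m11 * w1 * w1) / detM;
        double quad = (rtr - wMw) / sigma2;
        if (quad < 0.0) quad = 0.0;
        const double logdet = (n_i - 2) * log_s2 + std::log(detM);
        out(i, g) = logpi[g] - 0.5 * (n_i * LOG2PI + logdet + quad);
      }
    }
    return out;
  }

  for (int i = 0; i < n_subj; ++i) {
    const int a = start[i];
    const int b = a + len[i] - 1;
    const int n_i = len[i];
    const arma::subview<double> U_i = U.rows(a, b);
    const arma::vec R_i = R.subvec(a, b);
    const double RtR = arma::dot(R_i, R_i);
    const arma::vec UtR = U_i.t() * R_i;
    const arma::mat UtU = U_i.t() * U_i;

    arma::mat ZtZ, ZtU;
    arma::vec ZtR;
    if (q > 0) {
      const arma::subview<double> Z_i = Z.rows(a, b);
      ZtZ = Z_i.t() * Z_i;
      ZtU = Z_i.t() * U_i;
      ZtR = Z_i.t() * R_i;
    }

    for (int g = 0; g < G; ++g) {
      const arma::vec dg = delta.col(g);
      const double rtr = RtR - 2.0 * arma::dot(dg, UtR) +
        arma::dot(dg, UtU * dg);
      double quad, logdet;
      if (q > 0) {
        const arma::mat Lw = std::sqrt(omega2[g]) * L;
        const arma::mat M = sigma2 * arma::eye(q, q) + Lw.t() * ZtZ * Lw;
        const arma::vec w = Lw.t() * (ZtR - ZtU * dg);
        arma::mat Mc;
        if (!arma::chol(Mc, M, "lower")) {
          out.fill(arma::datum::nan);
          return out;
        }
        const arma::vec u = arma::solve(arma::trimatl(Mc), w);
        quad = (rtr - arma::dot(u, u)) / sigma2;
        logdet = (n_i - q) * log_s2 + 2.0 * arma::sum(arma::log(Mc.diag()));
      } else {
        quad = rtr / sigma2;
        logdet = n_i * log_s2;
      }
      if (quad < 0.0) quad = 0.0;   // guard against roundoff at near-singular V
      out(i, g) = logpi[g] - 0.5 * (n_i * LOG2PI + logdet + quad);
    }
  }
  return out;
}
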