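// Core discrete-time forward model for the two-metabolite hyperpolarized
// experiment: closed-form transition matrix, state/signal recursion, analytic
// sensitivities, Fisher information, and the B1-prior-marginalized L-optimality
// objective used by the scheme optimizers.
//
// Angles are radians throughout this file. Parameter ordering is fixed as
// (k, R1S, R1P, S0, P0[, B1S]).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// psi(z) = (1 - exp(-z))/z, stable at z -> 0
inline double psi_fun(double z) {
  if (std::fabs(z) < 1e-12) return 1.0 - 0.5 * z;
  return -std::expm1(-z) / z;
}

// psi'(z), series below 1e-4 to avoid cancellation
inline double psi_grad(double z) {
  if (std::fabs(z) < 1e-4) return -0.5 + z / 3.0 - z * z / 8.0;
  return (std::exp(-z) - psi_fun(z)) / z;
}

struct TransMat {
  double g11, g21, g22;
};

// G = expm(TR * [[-(k+R1S), 0], [k, -R1P]]), lower triangular closed form.
inline TransMat trans_mat(double k, double r1s, double r1p, double TR) {
  TransMat G;
  const double a = k + r1s;
  const double d = r1p - a;
  G.g11 = std::exp(-a * TR);
  G.g22 = std::exp(-r1p * TR);
  G.g21 = k * TR * G.g11 * psi_fun(d * TR);
  return G;
}

// dG/dk, dG/dR1S, dG/dR1P via the psi form (stable through the degeneracy).
inline void trans_mat_grad(double k, double r1s, double r1p, double TR,
                           TransMat &dk, TransMat &dr1s, TransMat &dr1p) {
  const double a = k + r1s;
  const double d = r1p - a;
  const double e11 = std::exp(-a * TR);
  const double e22 = std::exp(-r1p * TR);
  const double ps = psi_fun(d * TR);
  const double dps = psi_grad(d * TR);

  dk.g11 = -TR * e11;
  dk.g22 = 0.0;
  // G21 = k * TR * e11 * psi(d*TR), dd/dk = -1
  dk.g21 = TR * e11 * ps + k * TR * (-TR * e11) * ps +
           k * TR * e11 * dps * TR * (-1.0);

  dr1s.g11 = -TR * e11;
  dr1s.g22 = 0.0;
  dr1s.g21 = k * TR * (-TR * e11) * ps + k * TR * e11 * dps * TR * (-1.0);

  dr1p.g11 = 0.0;
  dr1p.g22 = -TR * e22;
  dr1p.g21 = k * TR * e11 * dps * TR;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_transition_matrix(double k, double r1s, double r1p, double TR) {
  TransMat G = trans_mat(k, r1s, r1p, TR);
  NumericMatrix out(2, 2);
  out(0, 0) = G.g11;
  out(1, 0) = G.g21;
  out(0, 1) = 0.0;
  out(1, 1) = G.g22;
  return out;
}

// State x (2 x T, longitudinal magnetization before each excitation) and
// signal y (2 x T, transverse magnitude after each excitation).
// [[Rcpp::export]]
List cpp_simulate(NumericVector theta, NumericVector angles_rad, double TR,
                  double b1s) {
  const int T = angles_rad.size();
  const double k = theta[0], r1s = theta[1], r1p = theta[2];
  TransMat G = trans_mat(k, r1s, r1p, TR);
  NumericMatrix x(2, T), y(2, T);
  double xs = theta[3], xp = theta[4];
  for (int t = 0; t < T; ++t) {
    const double ae = b1s * angles_rad[t];
    const double s = std::sin(ae), c = std::cos(ae);
    x(0, t) = xs;
    x(1, t) = xp;
    y(0, t) = s * xs;
    y(1, t) = s * xp;
    const double xcs = c * xs, xcp = c * xp;
    xs = G.g11 * xcs;
    xp = G.g21 * xcs + G.g22 * xcp;
  }
  return List::create(_["x"] = x, _["y"] = y);
}

// Analytic sensitivities dy/dtheta_i. Returns (2*T) x p matrix, rows in the
// column-major order of the 2 x T signal matrix. If with_b1 is true the
// parameter set is (k, R1S, R1P, S0, P0, B1S), else the first five.
// [[Rcpp::export]]
NumericMatrix cpp_sensitivities(NumericVector theta, NumericVector angles_rad,
                                double TR, double b1s, bool with_b1) {
  const int T = angles_rad.size();
  const int p = with_b1 ? 6 : 5;
  const double k = theta[0], r1s = theta[1], r1p = theta[2];
  TransMat G = trans_mat(k, r1s, r1p, TR);
  TransMat dGk, dGr1s, dGr1p;
  trans_mat_grad(k, r1s, r1p, TR, dGk, dGr1s, dGr1p);

  NumericMatrix dy(2 * T, p);
  // dx[i] as pairs (substrate, product)
  std::vector<double> dxs(p, 0.0), dxp(p, 0.0);
  dxs[3] = 1.0; // d/dS0
  dxp[4] = 1.0; // d/dP0
  double xs = theta[3], xp = theta[4];

  for (int t = 0; t < T; ++t) {
    const double al = angles_rad[t];
    const double ae = b1s * al;
    const double s = std::sin(ae), c = std::cos(ae);
    for (int i = 0; i < p; ++i) {
      dy(2 * t, i) = s * dxs[i];
      dy(2 * t + 1, i) = s * dxp[i];
    }
    if (with_b1) {
      dy(2 * t, 5) += al * c * xs;
      dy(2 * t + 1, 5) += al * c * xp;
    }
    const double xcs = c * xs, xcp = c * xp;
    for (int i = 0; i < p; ++i) {
      double dcs = c * dxs[i], dcp = c * dxp[i];
      if (with_b1 && i == 5) {
        dcs += -al * s * xs;
        dcp += -al * s * xp;
      }
      double ns = G.g11 * dcs;
      double np = G.g21 * dcs + G.g22 * dcp;
      if (i == 0) {
        ns += dGk.g11 * xcs;
        np += dGk.g21 * xcs + dGk.g22 * xcp;
      } else if (i == 1) {
        ns += dGr1s.g11 * xcs;
        np += dGr1s.g21 * xcs + dGr1s.g22 * xcp;
      } else if (i == 2) {
        ns += dGr1p.g11 * xcs;
        np += dGr1p.g21 * xcs + dGr1p.g22 * xcp;
      }
      dxs[i] = ns;
      dxp[i] = np;
    }
    xs = G.g11 * xcs;
    xp = G.g21 * xcs + G.g22 * xcp;
  }
  return dy;
}

// Fisher information: sum over metabolites and time points of outer products
// of sensitivities, scaled by 1/(sigma_m * normC)^2 with the signal divided by
// normC. sigma is length 2 (per metabolite).
// [[Rcpp::export]]
NumericMatrix cpp_fim(NumericVector theta, NumericVector angles_rad, double TR,
                      double b1s, bool with_b1, NumericVector sigma,
                      double normC) {
  NumericMatrix dy = cpp_sensitivities(theta, angles_rad, TR, b1s, with_b1);
  const int p = dy.ncol();
  const int T = angles_rad.size();
  arma::mat I(p, p, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    for (int m = 0; m < 2; ++m) {
      const double w = 1.0 / (sigma[m] * sigma[m]);
      const int r = 2 * t + m;
      for (int i = 0; i < p; ++i) {
        const double di = dy(r, i);
        for (int j = i; j < p; ++j) I(i, j) += w * di * dy(r, j);
      }
    }
  }
  I = arma::symmatu(I) / (normC * normC);
  return wrap(I);
}

// Prior-marginalized, regularized L-optimality objective.
//
// angles_rad: prescribed angles; b1_grid/b1_w: B1 prior support and masses;
// w: length-5 nonnegative weights applied to the non-dimensionalized CRLB
// diagonal (rates scaled by TR, magnetizations by the t=0 substrate signal);
// reg = n * sigma^2 * lambda * sum(sin^2(alpha)); singular information at any
// grid point contributes `penalty`.
// [[Rcpp::export]]
double cpp_design_objective(NumericVector angles_rad, NumericVector theta,
                            NumericVector w, NumericVector b1_grid,
                            NumericVector b1_w, double TR, double sigma,
                            double lambda, int n_weighted, double penalty) {
  const int T = angles_rad.size();
  NumericVector sig2(2, sigma);
  double total = 0.0;
  for (int g = 0; g < b1_grid.size(); ++g) {
    const double b1 = b1_grid[g];
    NumericMatrix Im = cpp_fim(theta, angles_rad, TR, b1, false, sig2, 1.0);
    arma::mat I(Im.begin(), 5, 5, false);
    arma::mat C;
    bool ok = arma::inv_sympd(C, I);
    if (ok) {
      // condition guard mirroring the non-invertibility threshold
      double rc = arma::rcond(I);
      if (!(rc > 1e-12)) ok = false;
    }
    if (!ok) {
      total += b1_w[g] * penalty;
      continue;
    }
    const double y00 = theta[3] * std::sin(b1 * angles_rad[0]);
    double L = 0.0;
    for (int i = 0; i < 5; ++i) {
      if (w[i] <= 0.0) continue;
      const double ci = (i < 3) ? TR : (y00 != 0.0 ? 1.0 / y00 : 0.0);
      L += w[i] * ci * ci * C(i, i);
    }
    total += b1_w[g] * L;
  }
  if (lambda > 0.0 && n_weighted > 0) {
    double sreg = 0.0;
    for (int t = 0; t < T; ++t) {
      const double s = std::sin(angles_rad[t]);
      sreg += s * s;
    }
    total += n_weighted * sigma * sigma * lambda * sreg;
  }
  return total;
}

// Forward-difference gradient of the design objective w.r.t. each angle.
// [[Rcpp::export]]
NumericVector cpp_design_gradient(NumericVector angles_rad, NumericVector theta,
                                  NumericVector w, NumericVector b1_grid,
                                  NumericVector b1_w, double TR, double sigma,
                                  double lambda, int n_weighted, double penalty,
                                  double h) {
  const int T = angles_rad.size();
  NumericVector grad(T);
  const double f0 = cpp_design_objective(angles_rad, theta, w, b1_grid, b1_w,
                                         TR, sigma, lambda, n_weighted, penalty);
  NumericVector a = clone(angles_rad);
  for (int t = 0; t < T; ++t) {
    const double orig = a[t];
    a[t] = orig + h;
    const double f1 = cpp_design_objective(a, theta, w, b1_grid, b1_w, TR,
                                           sigma, lambda, n_weighted, penalty);
    grad[t] = (f1 - f0) / h;
    a[t] = orig;
  }
  return grad;
}
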