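#include <Rcpp.h>
#include <cmath>

// Recursive evaluation of integer-order Bessel functions of the first kind,
// the kernel of the order-n Hankel transform.  Two-stage scheme:
//   * J0 and J1 from their ascending power series (x < 12) or the Hankel
//     asymptotic expansion (x >= 12);
//   * n >= 2 by upward three-term recurrence when the argument dominates the
//     order (x > n, the stable direction), otherwise by downward (Miller)
//     recurrence started well above n and normalized with the even-order sum
//     identity J0 + 2*sum_k J_{2k} = 1.
// Negative orders are resolved at call sites via J_{-n} = (-1)^n J_n.

static const double PI_ = 3.14159265358979323846;

// ascending series: J_n(x) = sum_m (-1)^m (x/2)^(n+2m) / (m! (n+m)!)
// used only for n = 0, 1 at moderate x where cancellation is harmless
static double jn_series(int n, double x) {
  double half = 0.5 * x;
  double term = 1.0;
  for (int k = 1; k <= n; ++k) term *= half / k;   // (x/2)^n / n!
  double sum = term;
  double x2 = -half * half;
  for (int m = 1; m < 60; ++m) {
    term *= x2 / (m * (double)(n + m));
    sum += term;
    if (std::fabs(term) < 1e-18 * (std::fabs(sum) + 1e-30)) break;
  }
  return sum;
}

// Hankel asymptotic expansion for J_n, large argument:
// J_n(x) = sqrt(2/(pi x)) * [ P_n(x) cos(chi) - Q_n(x) sin(chi) ],
// chi = x - (2n+1) pi/4, P/Q truncated at the smallest term.
static double jn_asymptotic(int n, double x) {
  double mu = 4.0 * n * n;
  double P = 1.0, Q = 0.0;
  double t = 1.0;
  double prev = 1e300;
  for (int k = 1; k <= 20; ++k) {
    double odd = 2.0 * k - 1.0;
    t *= (mu - odd * odd) / (k * 8.0 * x);
    double at = std::fabs(t);
    if (at > prev) break;          // asymptotic series started diverging
    prev = at;
    if (k % 2 == 1) {              // odd k -> Q, alternating signs
      Q += ((k % 4 == 1) ? t : -t);
    } else {                       // even k -> P
      P += ((k % 4 == 2) ? -t : t);
    }
    if (at < 1e-17) break;
  }
  double chi = x - (2.0 * n + 1.0) * PI_ / 4.0;
  return std::sqrt(2.0 / (PI_ * x)) * (P * std::cos(chi) - Q * std::sin(chi));
}

static double j0_eval(double x) {
  if (x == 0.0) return 1.0;
  return (x < 12.0) ? jn_series(0, x) : jn_asymptotic(0, x);
}

static double j1_eval(double x) {
  if (x == 0.0) return 0.0;
  return (x < 12.0) ? jn_series(1, x) : jn_asymptotic(1, x);
}

// Miller downward recurrence for J_n(x), 0 <= n, valid for x <= n regime;
// computes the whole ladder and normalizes by the even-order sum identity.
static double jn_miller(int n, double x) {
  if (x == 0.0) return (n == 0) ? 1.0 : 0.0;
  int start = n + 2 * (int)std::ceil(std::sqrt(40.0 * (double)n));
  if (start < 16) start = 16;
  if (start % 2 == 1) ++start;              // even start keeps the sum tidy
  double jp = 0.0;                          // J_{k+1}
  double jc = 1e-30;                        // J_k (arbitrary seed)
  double sum = 0.0;                         // J0 + 2*sum J_{2k}
  double jn = 0.0;
  for (int k = start; k >= 0; --k) {
    double jm = (2.0 * (k + 1.0) / x) * jc - jp;  // J_k from J_{k+1}, J_{k+2}
    jp = jc;
    jc = jm;
    if (k % 2 == 0) sum += (k == 0) ? jc : 2.0 * jc;
    if (k == n) jn = jc;
    if (std::fabs(jc) > 1e250) {            // rescale to avoid overflow
      jc *= 1e-250; jp *= 1e-250; sum *= 1e-250; jn *= 1e-250;
    }
  }
  return jn / sum;
}

static double jn_eval(int n, double x) {
  if (n == 0) return j0_eval(x);
  if (n == 1) return j1_eval(x);
  if (x == 0.0) return 0.0;
  if (x > (double)n) {
    // upward recurrence from J0, J1 (stable while order < argument)
    double jm = j0_eval(x), jc = j1_eval(x);
    for (int k = 1; k < n; ++k) {
      double jp = (2.0 * k / x) * jc - jm;
      jm = jc;
      jc = jp;
    }
    return jc;
  }
  return jn_miller(n, x);
}

// [[Rcpp::export(name = ".besselJnCpp")]]
Rcpp::NumericVector besselJnCpp(int n, Rcpp::NumericVector x) {
  if (n < 0) Rcpp::stop("order must be nonnegative");
  R_xlen_t m = x.size();
  Rcpp::NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double xi = x[i];
    if (!std::isfinite(xi) || xi < 0.0)
      Rcpp::stop("argument must be finite and nonnegative");
    out[i] = jn_eval(n, xi);
  }
  return out;
}

// Kernel table values[n+1][k][j] = J_n(2*pi*rho_k*r_j), order-major so each
// order's rho x r block is contiguous (consumed as one matrix product).
// [[Rcpp::export(name = ".besselTableCpp")]]
Rcpp::NumericVector besselTableCpp(int nMax, Rcpp::NumericVector rho,
                                   Rcpp::NumericVector r) {
  if (nMax < 0) Rcpp::stop("nMax must be nonnegative");
  R_xlen_t K = rho.size(), J = r.size();
  Rcpp::NumericVector out((R_xlen_t)(nMax + 1) * K * J);
  out.attr("dim") = Rcpp::IntegerVector::create(K, J, nMax + 1);
  // entries delegate to the scalar evaluator so the table is bit-identical
  // to besselJn() calls on the same arguments
  for (R_xlen_t j = 0; j < J; ++j) {
    for (R_xlen_t k = 0; k < K; ++k) {
      double x = 2.0 * PI_ * rho[k] * r[j];
      for (int n = 0; n <= nMax; ++n)
        out[(R_xlen_t)n * K * J + j * K + k] = jn_eval(n, x);
    }
  }
  return out;
}
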