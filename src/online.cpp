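#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form Gaussian integrals driving the expected one-step update of the
// online order parameters. The student field lambda = W.x/sqrt(N) and teacher
// field nu = W_T.x_r/sqrt(N) are jointly Gaussian with
//   Var(lambda) = Q = Q_r + Delta Q_i,  Var(nu) = T,  Cov = R.
// With the error signal G = sigma'(lambda) (sign(nu) - sigma(lambda)),
// sigma(u) = erf(u/sqrt(2)), the update needs E[G nu], E[G lambda_r],
// E[G lambda_i] and E[G^2]; all four reduce to elementary functions.
struct OnlineInts {
  double Inu, Glr, Gli, I2;
};

static inline double clip1(double x) {
  const double lim = 1.0 - 1e-15;
  if (x > lim) return lim;
  if (x < -lim) return -lim;
  return x;
}

static inline OnlineInts online_integrals(double Qr, double Qi, double R,
                                          double T, double Delta) {
  const double Q = Qr + Delta * Qi;
  const double E2 = T * (1.0 + Q) - R * R;          // > 0 when R^2 <= Q T
  const double E3 = T * (1.0 + 2.0 * Q) - 2.0 * R * R;
  const double twopi = 2.0 / M_PI;
  const double s12 = std::sqrt(1.0 + 2.0 * Q);
  const double Inu = twopi * (std::sqrt(std::max(E2, 0.0)) - R / s12) / (1.0 + Q);
  const double Ilam = twopi *
      (R / std::sqrt(std::max(E2, 1e-300)) - Q / s12) / (1.0 + Q);
  const double I2 = twopi / s12 +
      (2.0 * twopi / M_PI) / s12 *
          (std::asin(clip1(Q / (1.0 + 3.0 * Q))) -
           2.0 * std::asin(clip1(R / std::sqrt(std::max((1.0 + 3.0 * Q) * E3,
                                                        1e-300)))));
  // Split E[G lambda] into relevant/irrelevant parts via the conditional mean
  // of lambda_r given (lambda, nu).
  const double D = Q * T - R * R;
  double Glr;
  if (D > 1e-14) {
    const double a = (Qr * T - R * R) / D;
    const double b = R * Delta * Qi / D;
    Glr = a * Ilam + b * Inu;
  } else {
    Glr = Ilam;  // lambda_i vanishes (Delta*Q_i = 0) or degenerate alignment
  }
  OnlineInts out;
  out.Inu = Inu;
  out.Glr = Glr;
  out.Gli = Ilam - Glr;
  out.I2 = I2;
  return out;
}

// One expected step of the order-parameter map at difficulty Delta.
// Per-step scale 1/N_theory; gamma is the per-step weight-decay intensity.
static inline void theory_step(const double st[4], double Delta, double eta,
                               double gamma, double invN, double rho,
                               double out[4]) {
  OnlineInts I = online_integrals(st[0], st[1], st[2], st[3], Delta);
  const double d = 1.0 - gamma;
  out[0] = d * d * st[0] + 2.0 * d * eta * invN * I.Glr +
           eta * eta * invN * rho * I.I2;
  out[1] = d * d * st[1] + 2.0 * d * eta * invN * I.Gli +
           eta * eta * invN * (1.0 - rho) * Delta * I.I2;
  out[2] = d * st[2] + eta * invN * I.Inu;
  out[3] = st[3];
}

// [[Rcpp::export(name = ".cpp_online_integrals")]]
NumericVector cpp_online_integrals(double Qr, double Qi, double R, double T,
                                   double Delta) {
  OnlineInts I = online_integrals(Qr, Qi, R, T, Delta);
  return NumericVector::create(_["Gnu"] = I.Inu, _["Glr"] = I.Glr,
                               _["Gli"] = I.Gli, _["G2"] = I.I2);
}

// Iterate the expected map through a two-or-more-slice schedule.
// deltas/steps give the presentation order; if mix_weights is non-empty the
// per-step increment is the weighted mixture over all deltas (shuffled
// baseline in expectation) and `steps` is the single total step count.
// [[Rcpp::export(name = ".cpp_run_theory")]]
NumericMatrix cpp_run_theory(NumericVector deltas, IntegerVector steps,
                             NumericVector mix_weights, double eta,
                             double gamma, double sigma0_sq, int N_theory,
                             double rho, int n_record) {
  const bool mixture = mix_weights.size() > 0;
  long total = 0;
  if (mixture) {
    total = steps[0];
  } else {
    for (int k = 0; k < steps.size(); ++k) total += steps[k];
  }
  NumericMatrix rec(n_record + 1, 5);
  double st[4] = {rho * sigma0_sq, (1.0 - rho) * sigma0_sq, 0.0, rho};
  const double invN = 1.0 / (double)N_theory;
  long next_rec = 0;
  int ri = 0;
  auto record = [&](long step) {
    rec(ri, 0) = (double)step * invN;
    rec(ri, 1) = st[0];
    rec(ri, 2) = st[1];
    rec(ri, 3) = st[2];
    rec(ri, 4) = st[3];
    ++ri;
  };
  record(0);
  next_rec = (long)std::llround((double)total / n_record);
  long done = 0;
  int slice = 0;
  long in_slice = 0;
  double tmp[4], acc[4];
  for (long t = 1; t <= total; ++t) {
    if (mixture) {
      acc[0] = acc[1] = acc[2] = acc[3] = 0.0;
      for (int k = 0; k < deltas.size(); ++k) {
        theory_step(st, deltas[k], eta, gamma, invN, rho, tmp);
        for (int j = 0; j < 4; ++j) acc[j] += mix_weights[k] * tmp[j];
      }
      for (int j = 0; j < 4; ++j) st[j] = acc[j];
    } else {
      while (in_slice >= steps[slice]) {
        ++slice;
        in_slice = 0;
      }
      theory_step(st, deltas[slice], eta, gamma, invN, rho, tmp);
      for (int j = 0; j < 4; ++j) st[j] = tmp[j];
      ++in_slice;
    }
    ++done;
    // Cauchy-Schwarz sanity: R^2 <= Q_r T within tolerance
    if (st[2] * st[2] > st[0] * st[3] + 1e-9 * (1.0 + st[0] * st[3])) {
      stop("order-parameter invariant R^2 <= Q_r T violated at alpha = %f",
           (double)done * invN);
    }
    if (done == next_rec || done == total) {
      if (ri <= n_record) record(done);
      next_rec = (long)std::llround((double)(ri) * (double)total / n_record);
      if (next_rec <= done) next_rec = done + 1;
    }
  }
  colnames(rec) = CharacterVector::create("alpha", "Qr", "Qi", "R", "T");
  return rec(Range(0, ri - 1), _);
}

// Finite-N online SGD (one pass, each sample used once), generating samples
// on the fly. Order of difficulties: for the shuffled baseline each step
// draws a slice with probability proportional to its remaining sample count.
// Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export(name = ".cpp_run_sim")]]
NumericMatrix cpp_run_sim(NumericVector teacher, int n_rel,
                          NumericVector deltas, IntegerVector counts,
                          bool shuffled, double eta, double gamma,
                          double sigma0_sq, int n_record) {
  const int N = teacher.size();
  const double sqN = std::sqrt((double)N);
  long total = 0;
  for (int k = 0; k < counts.size(); ++k) total += counts[k];
  std::vector<long> remaining(counts.begin(), counts.end());
  std::vector<double> W(N), x(N);
  const double s0 = std::sqrt(sigma0_sq);
  for (int j = 0; j < N; ++j) W[j] = norm_rand() * s0;

  double Temp = 0.0;
  for (int j = 0; j < n_rel; ++j) Temp += teacher[j] * teacher[j];
  Temp /= N;

  NumericMatrix rec(n_record + 1, 5);
  int ri = 0;
  auto record = [&](long step) {
    double Qr = 0.0, Qi = 0.0, R = 0.0;
    for (int j = 0; j < n_rel; ++j) {
      Qr += W[j] * W[j];
      R += W[j] * teacher[j];
    }
    for (int j = n_rel; j < N; ++j) Qi += W[j] * W[j];
    rec(ri, 0) = (double)step / N;
    rec(ri, 1) = Qr / N;
    rec(ri, 2) = Qi / N;
    rec(ri, 3) = R / N;
    rec(ri, 4) = Temp;
    ++ri;
  };
  record(0);
  long next_rec = (long)std::llround((double)total / n_record);
  int slice = 0;
  const double c0 = std::sqrt(2.0 / M_PI);
  for (long t = 1; t <= total; ++t) {
    if (shuffled) {
      long left = total - t + 1;
      double u = unif_rand() * left;
      double cum = 0.0;
      for (int k = 0; k < (int)remaining.size(); ++k) {
        cum += remaining[k];
        if (u < cum) {
          slice = k;
          break;
        }
      }
    } else {
      while (remaining[slice] == 0) ++slice;
    }
    --remaining[slice];
    const double sdel = std::sqrt(deltas[slice]);
    double lam = 0.0, nu = 0.0;
    for (int j = 0; j < n_rel; ++j) {
      x[j] = norm_rand();
      lam += W[j] * x[j];
      nu += teacher[j] * x[j];
    }
    for (int j = n_rel; j < N; ++j) {
      x[j] = norm_rand() * sdel;
      lam += W[j] * x[j];
    }
    lam /= sqN;
    nu /= sqN;
    const double y = (nu >= 0.0) ? 1.0 : -1.0;
    const double G = c0 * std::exp(-0.5 * lam * lam) *
                     (y - std::erf(lam / std::sqrt(2.0)));
    if (!std::isfinite(G)) stop("non-finite update at step %ld", t);
    const double coef = eta / sqN * G;
    const double dec = 1.0 - gamma;
    for (int j = 0; j < N; ++j) W[j] = dec * W[j] + coef * x[j];
    if (t == next_rec || t == total) {
      if (ri <= n_record) record(t);
      next_rec = (long)std::llround((double)ri * (double)total / n_record);
      if (next_rec <= t) next_rec = t + 1;
    }
  }
  colnames(rec) = CharacterVector::create("alpha", "Qr", "Qi", "R", "T");
  return rec(Range(0, ri - 1), _);
}
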