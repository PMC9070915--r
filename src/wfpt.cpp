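#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary for a diffusion with
// drift v, boundary separation a, relative start w (fraction of a above the
// lower bound) and unit diffusion coefficient.  Series representation with the
// usual small-time / large-time switch; the number of terms is chosen from the
// truncation error bound at tolerance `err`.

static const double WFPT_ERR = 1e-7;

// density of the normalized problem (a = 1, v = 0, start w) at scaled time tt
static double wfpt_f0(double tt, double w, double err) {
  // number of terms needed by each expansion
  double ks, kl;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) {               // small-time expansion
    int K = (int)std::ceil(ks);
    int kmin = -(int)std::floor((K - 1) / 2.0);
    int kmax = (int)std::ceil((K - 1) / 2.0);
    for (int k = kmin; k <= kmax; k++) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                     // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// log density, lower boundary, decision time t (non-decision time already removed)
static double wfpt_lpdf_lower(double t, double v, double a, double w) {
  if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0) || !R_finite(t))
    return R_NegInf;
  double tt = t / (a * a);
  double p = wfpt_f0(tt, w, WFPT_ERR);
  if (!(p > 0.0)) return R_NegInf;
  return std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

// choice-coded log density: choice 1 = upper boundary, choice 2 = lower
double wfpt_lpdf_choice(double t, int choice, double v, double a, double w) {
  if (choice == 1) return wfpt_lpdf_lower(t, -v, a, 1.0 - w);
  return wfpt_lpdf_lower(t, v, a, w);
}

//' @keywords internal
// [[Rcpp::export(name = ".wfpt_lpdf_cpp")]]
NumericVector wfpt_lpdf_cpp(NumericVector t, IntegerVector choice,
                            double v, double a, double w) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = wfpt_lpdf_choice(t[i], choice[i], v, a, w);
  return out;
}

// Forward simulation of the two-boundary diffusion: Euler steps of size dt with
// a Brownian-bridge correction for within-step boundary crossings, so the
// discretization bias of plain Euler is removed to first order.
// Returns (choice, decision time); choice 0 = still undecided at tmax.
//' @keywords internal
// [[Rcpp::export(name = ".wfpt_sample_cpp")]]
NumericMatrix wfpt_sample_cpp(int n, double v, double a, double w,
                              double tmax, double dt) {
  NumericMatrix out(n, 2);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; i++) {
    double x = w * a, t = 0.0;
    int ch = 0;
    while (t < tmax) {
      double xn = x + v * dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) { ch = 1; break; }
      if (xn <= 0.0) { ch = 2; break; }
      // within-step crossing probabilities (Brownian bridge)
      double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
      if (unif_rand() < pu) { ch = 1; break; }
      double pl = std::exp(-2.0 * x * xn / dt);
      if (unif_rand() < pl) { ch = 2; break; }
      x = xn;
    }
    out(i, 0) = ch;
    out(i, 1) = t;
  }
  return out;
}
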