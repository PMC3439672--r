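// Gillespie direct-method SSA for mass-action reaction networks.
// Reversible reactions are split into forward/reverse channels; propensities
// use falling-factorial combinatorics with the volume scale omega converting
// deterministic rate constants (uM, s) to stochastic ones.
#include <Rcpp.h>
using namespace Rcpp;

// propensity of one channel: k * omega^(1 - order) * prod_i C(x_i, c_i) * c_i!
// written as k * omega * prod_i falling(x_i, c_i) / (c_i! * omega^c_i)
static double channel_propensity(double k, double omega,
                                 const int* stoich, int ns,
                                 const double* x) {
  if (k <= 0.0) return 0.0;
  double a = k * omega;
  for (int i = 0; i < ns; ++i) {
    int c = stoich[i];
    if (c == 0) continue;
    for (int j = 0; j < c; ++j) {
      a *= (x[i] - j) / omega;
      if (a <= 0.0) return 0.0;
    }
    if (c == 2) a /= 2.0;
    else if (c > 2) { double f = 1.0; for (int j = 2; j <= c; ++j) f *= j; a /= f; }
  }
  return a;
}

// [[Rcpp::export(name = "ssa_direct_cpp")]]
NumericMatrix ssa_direct_cpp(IntegerMatrix Rmat, IntegerMatrix Pmat,
                             NumericVector kf, NumericVector kr,
                             NumericVector x0, double omega,
                             NumericVector report_times) {
  const int ns = Rmat.nrow(), nr = Rmat.ncol(), nt = report_times.size();
  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];
  NumericMatrix out(nt, ns);
  std::vector<double> a(2 * nr);
  double t = 0.0;
  int it = 0;
  RNGScope scope;
  for (;;) {
    double a0 = 0.0;
    for (int r = 0; r < nr; ++r) {
      a[2 * r]     = channel_propensity(kf[r], omega, &Rmat(0, r), ns, x.data());
      a[2 * r + 1] = channel_propensity(kr[r], omega, &Pmat(0, r), ns, x.data());
      a0 += a[2 * r] + a[2 * r + 1];
    }
    double t_next = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    while (it < nt && report_times[it] <= t_next) {
      for (int i = 0; i < ns; ++i) out(it, i) = x[i];
      ++it;
    }
    if (it >= nt) break;
    t = t_next;
    // select channel
    double u = unif_rand() * a0, acc = 0.0;
    int ch = 2 * nr - 1;
    for (int c = 0; c < 2 * nr; ++c) {
      acc += a[c];
      if (u <= acc) { ch = c; break; }
    }
    int r = ch / 2;
    if (ch % 2 == 0) {  // forward: consume reactants, produce products
      for (int i = 0; i < ns; ++i) x[i] += Pmat(i, r) - Rmat(i, r);
    } else {            // reverse
      for (int i = 0; i < ns; ++i) x[i] += Rmat(i, r) - Pmat(i, r);
    }
  }
  return out;
}
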