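#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment production / misfolding / clearance loop.
//
// Process magnitudes (production draws, templating b = RM*Cn*Cp, adaptive
// clearance means) are computed from the start-of-step concentrations and
// applied sequentially in the stated order. Draws use R's RNG (seed set by
// the caller); exactly four normals are consumed per step regardless of
// which processes are active, so runs with different rates share noise
// under a common seed.
//
// [[Rcpp::export(name = ".pointModelLoop")]]
List pointModelLoop(double Cn0, double Cp0, double Cnn, double Cpn,
                    double RPn, double RPp, double RCn, double RCp,
                    double RM, double horizon, double lossThreshold,
                    double Cmax, double traceStride) {
  RNGScope scope;
  double Cn = Cn0, Cp = Cp0;
  const double em1 = M_E - 1.0;
  const long long H = (long long) horizon;
  const long long stride = (long long) traceStride;
  const long long nTrace = H / stride + 1;
  NumericVector tT(nTrace), tCn(nTrace), tCp(nTrace);
  tT[0] = 0.0; tCn[0] = Cn; tCp[0] = Cp;
  long long row = 0;
  double lossTime = -1.0;
  for (long long t = 1; t <= H; ++t) {
    double z1 = norm_rand(), z2 = norm_rand();
    double z3 = norm_rand(), z4 = norm_rand();
    // draws keep their nominal means (may be negative); the applied update
    // is clamped so 0 <= C and Cn + Cp <= Cmax
    double an = RPn > 0 ? RPn * (1.0 + z1) : 0.0;
    double ap = RPp > 0 ? RPp * (1.0 + z2) : 0.0;
    double b = RM * Cn * Cp;
    double mun = (RCn > 0 && Cn > 0) ? RCn * log1p(em1 * Cn / Cnn) : 0.0;
    double mup = (RCp > 0 && Cp > 0) ? RCp * log1p(em1 * Cp / Cpn) : 0.0;
    double qn = mun * (1.0 + z3);
    double qp = mup * (1.0 + z4);
    Cn = std::min(std::max(Cn + an, 0.0), Cmax - Cp);
    Cp = std::min(std::max(Cp + ap, 0.0), Cmax - Cn);
    if (b > Cn) b = Cn;
    Cn -= b; Cp += b;
    Cn = std::min(std::max(Cn - qn, 0.0), Cmax - Cp);
    Cp = std::min(std::max(Cp - qp, 0.0), Cmax - Cn);
    if (t % stride == 0 && row + 1 < nTrace) {
      ++row; tT[row] = (double) t; tCn[row] = Cn; tCp[row] = Cp;
    }
    if (lossTime < 0 && Cp > lossThreshold * Cmax) { lossTime = (double) t; break; }
  }
  return List::create(
    _["lossTime"] = lossTime,
    _["t"] = tT[Range(0, row)],
    _["Cn"] = tCn[Range(0, row)],
    _["Cp"] = tCp[Range(0, row)]);
}
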