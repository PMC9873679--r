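// Discrete-ordinates transport sweep for 1-D slab geometry.
// Diamond-difference spatial closure with a set-to-zero negative-flux
// fixup (balance-preserving step closure in fixed-up cells).

#include <Rcpp.h>
using namespace Rcpp;

// mu, w: angular quadrature (mu != 0); sig: cell total removal [1/cm];
// dx: cell widths [cm]; q: per-direction emission density (nang x ncell);
// inc_left/inc_right: incoming angular flux at the two faces.
// Returns cell-average angular flux, outgoing face fluxes and fixup count.
// [[Rcpp::export(name = ".sweep_slab_cpp")]]
List sweep_slab_cpp(NumericVector mu, NumericVector w, NumericVector sig,
                    NumericVector dx, NumericMatrix q,
                    NumericVector inc_left, NumericVector inc_right,
                    bool fixup) {
  const int nang = mu.size();
  const int ncell = sig.size();
  NumericMatrix psi(nang, ncell);
  NumericVector out_left(nang), out_right(nang);
  int nfix = 0;

  for (int n = 0; n < nang; ++n) {
    const double m = mu[n];
    if (m > 0) {
      double pin = inc_left[n];
      for (int c = 0; c < ncell; ++c) {
        const double a = m / dx[c];
        const double s = sig[c];
        double pout = (q(n, c) + pin * (a - 0.5 * s)) / (a + 0.5 * s);
        double pavg;
        if (pout < 0.0 && fixup) {
          ++nfix;
          pout = 0.0;
          pavg = (q(n, c) + a * pin) / (s + a);
        } else {
          if (pout < 0.0) ++nfix;
          pavg = 0.5 * (pin + pout);
        }
        psi(n, c) = pavg;
        pin = pout;
      }
      out_right[n] = pin;
    } else {
      const double am = -m;
      double pin = inc_right[n];
      for (int c = ncell - 1; c >= 0; --c) {
        const double a = am / dx[c];
        const double s = sig[c];
        double pout = (q(n, c) + pin * (a - 0.5 * s)) / (a + 0.5 * s);
        double pavg;
        if (pout < 0.0 && fixup) {
          ++nfix;
          pout = 0.0;
          pavg = (q(n, c) + a * pin) / (s + a);
        } else {
          if (pout < 0.0) ++nfix;
          pavg = 0.5 * (pin + pout);
        }
        psi(n, c) = pavg;
        pin = pout;
      }
      out_left[n] = pin;
    }
  }
  return List::create(_["psi"] = psi, _["out_left"] = out_left,
                      _["out_right"] = out_right, _["nfix"] = nfix);
}
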