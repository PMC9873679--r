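// Independent multigroup condensed-history Monte Carlo for 1-D slab
// electron transport.  Physics anchored to the same analytic kernels and
// the same multigroup library as the deterministic solver: free flight to
// the next catastrophic event sampled from the library's group-wise total,
// energy treated continuously between events (the group only indexes the
// cross-section lookup), continuous loss beta*ds deposited along the
// flight, catastrophic energy losses sampled from the Moller and Koch-Motz
// cross sections restricted to the catastrophic domains, and elastic
// deflections sampled from the analytic screened-Mott cross section
// restricted to mu <= 0.999999 (inverse-CDF screened Rutherford with a
// Mott-ratio rejection), NOT from truncated Legendre reconstructions.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double ME = 0.51099895;        // electron rest energy [MeV]
const double ALPHA = 7.2973525693e-3;
const double MU_STAR = 0.999999;     // forward-elastic boundary

struct Particle {
  double E, mu, x;
  int vox, grp;
};

inline double beta2_of(double E) {
  double g = 1.0 + E / ME;
  return 1.0 - 1.0 / (g * g);
}

inline double moliere_eta(double E, double Z) {
  double b2 = beta2_of(E);
  double pc2 = E * (E + 2.0 * ME);
  return (ALPHA * ALPHA * std::pow(Z, 2.0 / 3.0) / (4.0 * 0.885 * 0.885)) *
         (ME * ME / pc2) * (1.13 + 3.76 * ALPHA * ALPHA * Z * Z / b2);
}

// Moller energy-loss bracket B(eps), eps = W/E in (0, 1/2]
inline double moller_bracket(double E, double eps) {
  double tau = E / ME;
  double g1 = tau / (tau + 1.0);
  g1 *= g1;
  double g2 = (2.0 * tau + 1.0) / ((tau + 1.0) * (tau + 1.0));
  double om = 1.0 - eps;
  return 1.0 / (eps * eps) + 1.0 / (om * om) + g1 - g2 / (eps * om);
}

inline double moller_mu_of(double E, double Ep) {
  double m = std::sqrt((Ep / E) * (E + 2.0 * ME) / (Ep + 2.0 * ME));
  return m > 1.0 ? 1.0 : m;
}

// Koch-Motz 3BN with Elwert factor, relative shape in k (absolute scale
// irrelevant for sampling); Z(Z+1) folded outside
inline double brems_shape(double E, double k, double Z) {
  double E0 = (E + ME) / ME, Ef = (E - k + ME) / ME, kk = k / ME;
  double p0 = std::sqrt(E0 * E0 - 1.0);
  double pf2 = Ef * Ef - 1.0;
  if (pf2 <= 0.0) return 0.0;
  double pf = std::sqrt(pf2);
  double eps0 = 2.0 * std::log(E0 + p0);
  double epsf = 2.0 * std::log(Ef + pf);
  double L = 2.0 * std::log((E0 * Ef + p0 * pf - 1.0) / kk);
  double t1 = 4.0 / 3.0 -
              2.0 * E0 * Ef * (pf * pf + p0 * p0) / (p0 * p0 * pf * pf) +
              eps0 * Ef / (p0 * p0 * p0) + epsf * E0 / (pf * pf * pf) -
              epsf * eps0 / (p0 * pf);
  double t2 = 8.0 * E0 * Ef / (3.0 * p0 * pf) +
              kk * kk * (E0 * E0 * Ef * Ef + p0 * p0 * pf * pf) /
                  (p0 * p0 * p0 * pf * pf * pf);
  double t3 = (kk / (2.0 * p0 * pf)) *
              ((E0 * Ef + p0 * p0) * eps0 / (p0 * p0 * p0) -
               (E0 * Ef + pf * pf) * epsf / (pf * pf * pf) +
               2.0 * kk * E0 * Ef / (pf * pf * p0 * p0));
  double v = (pf / p0) / kk * (t1 + L * (t2 + t3));
  if (v < 0.0) v = 0.0;
  // Elwert factor
  double bi = std::sqrt(beta2_of(E));
  double bf = std::sqrt(beta2_of(E - k));
  double xz = 2.0 * M_PI * ALPHA * Z;
  v *= (bi / bf) * (1.0 - std::exp(-xz / bi)) / (1.0 - std::exp(-xz / bf));
  return v;
}

// lab-frame direction cosine after deflection mus with random azimuth
inline double rotate_mu(double mu, double mus) {
  double s1 = 1.0 - mu * mu, s2 = 1.0 - mus * mus;
  if (s1 < 0.0) s1 = 0.0;
  if (s2 < 0.0) s2 = 0.0;
  double m = mu * mus + std::sqrt(s1 * s2) * std::cos(2.0 * M_PI * unif_rand());
  if (m > 1.0) m = 1.0;
  if (m < -1.0) m = -1.0;
  return m;
}

struct MatData {
  std::vector<double> sig_ion, sig_brems, sig_el, beta;
  std::vector<double> Z;                  // element Z
  std::vector<double> br_cdf;             // element selection for brems
  std::vector<double> el_cdf;             // N x nel, row-major elastic CDF
  int nel;
};

}  // namespace

// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(NumericVector bnd, NumericVector edges, IntegerVector mat,
                NumericVector scale, List matdata, double E0, double mu0,
                int nhist, int nbatch, bool do_ion, bool do_brems,
                bool do_el, bool mott_auto, int record_first) {
  const int N = bnd.size() - 1;
  const int nvox = mat.size();
  const double ecut = bnd[N];
  const double xmax = edges[nvox];

  // unpack material tables
  const int nmat = matdata.size();
  std::vector<MatData> md(nmat);
  for (int m = 0; m < nmat; ++m) {
    List mm = matdata[m];
    md[m].sig_ion = as<std::vector<double>>(mm["sig_ion"]);
    md[m].sig_brems = as<std::vector<double>>(mm["sig_brems"]);
    md[m].sig_el = as<std::vector<double>>(mm["sig_el"]);
    md[m].beta = as<std::vector<double>>(mm["beta"]);
    md[m].Z = as<std::vector<double>>(mm["Z"]);
    md[m].br_cdf = as<std::vector<double>>(mm["br_cdf"]);
    md[m].el_cdf = as<std::vector<double>>(mm["el_cdf"]);
    md[m].nel = md[m].Z.size();
  }

  NumericVector dep(nvox);
  NumericMatrix dep_batch(nbatch, nvox);
  double led_dep = 0.0, led_rad = 0.0, led_leak = 0.0, led_below = 0.0;
  NumericVector first_depth(record_first > 0 ? record_first : 0);
  int nfirst = 0;

  std::vector<Particle> stack;
  stack.reserve(64);

  int per_batch = nhist / nbatch;
  if (per_batch < 1) { per_batch = 1; nbatch = nhist; }

  for (int b = 0; b < nbatch; ++b) {
    int nh = (b == nbatch - 1) ? nhist - per_batch * (nbatch - 1) : per_batch;
    for (int h = 0; h < nh; ++h) {
      stack.clear();
      Particle p;
      p.E = E0; p.mu = mu0; p.x = 0.0; p.vox = 0; p.grp = 0;
      bool primary_live = true;
      bool first_recorded = false;
      while (true) {
        if (!primary_live && stack.empty()) break;
        if (!primary_live) { p = stack.back(); stack.pop_back(); }
        primary_live = false;  // after this track ends, pop the stack
        // locate group for current energy (energies only decrease)
        while (p.grp < N && p.E <= bnd[p.grp + 1]) ++p.grp;
        // track loop
        bool alive = true;
        while (alive) {
          if (p.E <= ecut * (1.0 + 1e-12) || p.grp >= N) {
            // below (or at) transport cutoff: deposit locally
            dep_batch(b, p.vox) += p.E; led_below += p.E;
            alive = false; break;
          }
          const int m = mat[p.vox];
          const double sc = scale[p.vox];
          const MatData& M = md[m];
          const int g = p.grp;
          double s_ion = do_ion ? M.sig_ion[g] * sc : 0.0;
          double s_br = do_brems ? M.sig_brems[g] * sc : 0.0;
          double s_el = do_el ? M.sig_el[g] * sc : 0.0;
          double sig = s_ion + s_br + s_el;
          double beta = M.beta[g] * sc;
          // candidate step lengths
          double s_evt = (sig > 0.0) ? -std::log(unif_rand()) / sig : 1e30;
          double amu = std::fabs(p.mu) < 1e-12 ? 1e-12 : std::fabs(p.mu);
          double s_vox = (p.mu >= 0.0) ? (edges[p.vox + 1] - p.x) / amu
                                       : (p.x - edges[p.vox]) / amu;
          if (s_vox < 0.0) s_vox = 0.0;
          double s_grp = (p.E - bnd[g + 1]) / beta;
          double s = s_evt; int kind = 0;           // 0 event
          if (s_vox < s) { s = s_vox; kind = 1; }   // 1 voxel crossing
          if (s_grp < s) { s = s_grp; kind = 2; }   // 2 group boundary
          // continuous loss along the segment
          double eloss = beta * s;
          if (eloss > p.E - ecut) {                 // never skid below cutoff
            eloss = p.E - ecut; s = eloss / beta; kind = 2;
          }
          dep_batch(b, p.vox) += eloss; led_dep += eloss;
          p.E -= eloss;
          p.x += p.mu * s;
          if (kind == 1) {
            if (p.mu >= 0.0) {
              if (++p.vox >= nvox) { led_leak += p.E; alive = false; }
              else p.x = edges[p.vox];
            } else {
              if (--p.vox < 0) { led_leak += p.E; alive = false; }
              else p.x = edges[p.vox + 1];
            }
            continue;
          }
          if (kind == 2) {
            if (p.E <= bnd[g + 1] * (1.0 + 1e-12)) ++p.grp;
            continue;
          }
          // catastrophic event
          if (record_first > 0 && !first_recorded && nfirst < record_first) {
            first_depth[nfirst++] = p.x;
            first_recorded = true;
          }
          double xi = unif_rand() * sig;
          if (xi < s_el) {
            // elastic: select element, sample screened Rutherford, Mott reject
            const double* cdf = &M.el_cdf[(size_t)g * M.nel];
            double u = unif_rand();
            int e = 0;
            while (e < M.nel - 1 && u > cdf[e]) ++e;
            double Z = M.Z[e];
            double eta = moliere_eta(p.E, Z);
            double a = 1.0 + 2.0 * eta;
            double i1 = 1.0 / (a + 1.0);             // at mu = -1
            double i2 = 1.0 / (a - MU_STAR);
            double mus;
            bool use_mott = mott_auto ? (p.E > 0.256) : false;
            double bb = std::sqrt(beta2_of(p.E));
            double rmax = 1.0 + M_PI * ALPHA * Z * bb * 0.25;
            for (int it = 0; it < 1000; ++it) {
              double r = i1 + unif_rand() * (i2 - i1);
              mus = a - 1.0 / r;
              if (!use_mott) break;
              double ss = std::sqrt((1.0 - mus) * 0.5);
              double ratio = 1.0 - bb * bb * ss * ss +
                             M_PI * ALPHA * Z * bb * ss * (1.0 - ss);
              if (unif_rand() * rmax <= ratio) break;
            }
            p.mu = rotate_mu(p.mu, mus);
          } else if (xi < s_el + s_ion) {
            // Moller ionization restricted to the catastrophic domain
            double t = bnd[g + 2 <= N ? g + 2 : N];
            double Wc = p.E - t;
            if (Wc < ecut) Wc = ecut;   // un-trackable deltas stay soft
            double Wmax = 0.5 * p.E;
            if (Wc < Wmax && Wc > 0.0) {
              double ec = Wc / p.E;
              double W;
              for (int it = 0; it < 10000; ++it) {
                double u = unif_rand();
                double inv = 1.0 / ec - u * (1.0 / ec - 2.0);
                double eps = 1.0 / inv;
                if (unif_rand() * 2.25 / (eps * eps) <=
                    moller_bracket(p.E, eps)) {
                  W = eps * p.E;
                  break;
                }
                W = Wc;  // fallback, overwritten on accept
              }
              double Ep = p.E - W;
              double mu_p = moller_mu_of(p.E, Ep);
              double mu_d = moller_mu_of(p.E, W);
              double phi = 2.0 * M_PI * unif_rand();
              double s1 = std::sqrt(std::max(0.0, 1.0 - p.mu * p.mu));
              double c1 = std::cos(phi), c2 = std::cos(phi + M_PI);
              double mup_lab = p.mu * mu_p +
                  s1 * std::sqrt(std::max(0.0, 1.0 - mu_p * mu_p)) * c1;
              double mud_lab = p.mu * mu_d +
                  s1 * std::sqrt(std::max(0.0, 1.0 - mu_d * mu_d)) * c2;
              if (mup_lab > 1.0) mup_lab = 1.0;
              if (mup_lab < -1.0) mup_lab = -1.0;
              if (mud_lab > 1.0) mud_lab = 1.0;
              if (mud_lab < -1.0) mud_lab = -1.0;
              // delta ray: track if above cutoff, else deposit
              if (W > ecut) {
                Particle d;
                d.E = W; d.mu = mud_lab; d.x = p.x; d.vox = p.vox;
                d.grp = 0;  // will be relocated at pop
                stack.push_back(d);
              } else {
                dep_batch(b, p.vox) += W; led_below += W;
              }
              p.E = Ep;
              p.mu = mup_lab;
              while (p.grp < N && p.E <= bnd[p.grp + 1]) ++p.grp;
            }
          } else if (s_br > 0.0) {
            // bremsstrahlung restricted to the catastrophic domain
            double t = bnd[g + 2 <= N ? g + 2 : N];
            double kc = p.E - t;
            if (kc < ecut) kc = ecut;
            double kmax = p.E - ecut;
            if (kc < kmax) {
              double u = unif_rand();
              int e = 0;
              while (e < M.nel - 1 && u > M.br_cdf[e]) ++e;
              double Z = M.Z[e];
              // majorant scan of S(k) = k * dsig/dk (flat-ish in log k)
              double smax = 0.0;
              for (int i = 0; i < 25; ++i) {
                double k = kc * std::pow(kmax / kc, i / 24.0);
                double v = k * brems_shape(p.E, k, Z);
                if (v > smax) smax = v;
              }
              smax *= 1.3;
              double k = kmax;
              for (int it = 0; it < 10000; ++it) {
                k = kc * std::pow(kmax / kc, unif_rand());
                if (unif_rand() * smax <= k * brems_shape(p.E, k, Z)) break;
              }
              led_rad += k;
              p.E -= k;      // no angular deflection for the electron
              while (p.grp < N && p.E <= bnd[p.grp + 1]) ++p.grp;
            }
          }
        }  // track loop
      }    // stack loop
    }      // histories
    for (int v = 0; v < nvox; ++v) dep[v] += dep_batch(b, v);
  }        // batches

  return List::create(
      _["dep"] = dep, _["dep_batch"] = dep_batch,
      _["deposited"] = led_dep, _["radiated"] = led_rad,
      _["leaked"] = led_leak, _["below_cutoff"] = led_below,
      _["first_depth"] = first_depth, _["n_first"] = nfirst,
      _["xmax"] = xmax);
}
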