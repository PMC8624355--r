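#include <Rcpp.h>
using namespace Rcpp;

// Stochastic Landau-Lifshitz-Gilbert macrospin integrator (Heun scheme,
// Stratonovich-consistent, thermal field frozen within each step).
//
//   dm/dt = -gamma*mu0/(1+alpha^2) * [ m x H + alpha * m x (m x H) ]
//   H     = H_K (m.n) n + H_app(t) z + H_th
//
// All fields in A/m; gmu0 = gamma_e * mu0 has units 1/(s A/m).
// sigma_h is the per-component thermal-field standard deviation for the
// given timestep (Brown's fluctuation-dissipation relation); 0 at T = 0.
// The moment is renormalised after every Heun update; the maximum observed
// post-renormalisation deviation of |m| from 1 is returned as a diagnostic.

static inline void llg_rhs(const double m[3], const double n[3],
                           const double hth[3], double happ, double hk,
                           double alpha, double pref, double out[3]) {
  double mn = m[0] * n[0] + m[1] * n[1] + m[2] * n[2];
  double H[3] = {hk * mn * n[0] + hth[0],
                 hk * mn * n[1] + hth[1],
                 hk * mn * n[2] + hth[2] + happ};
  double c1[3] = {m[1] * H[2] - m[2] * H[1],
                  m[2] * H[0] - m[0] * H[2],
                  m[0] * H[1] - m[1] * H[0]};
  double c2[3] = {m[1] * c1[2] - m[2] * c1[1],
                  m[2] * c1[0] - m[0] * c1[2],
                  m[0] * c1[1] - m[1] * c1[0]};
  out[0] = -pref * (c1[0] + alpha * c2[0]);
  out[1] = -pref * (c1[1] + alpha * c2[1]);
  out[2] = -pref * (c1[2] + alpha * c2[2]);
}

// [[Rcpp::export(name = ".sllg_core")]]
List sllg_core(NumericMatrix m0, NumericMatrix axes, double hk, double alpha,
               double gmu0, double sigma_h, NumericVector happ, double dt,
               int record_every, int sample_every) {
  const int np = m0.nrow();
  const int nsteps = happ.size() - 1;
  if (axes.nrow() != np || m0.ncol() != 3 || axes.ncol() != 3)
    stop("m0 and axes must be n x 3 matrices of equal row count");
  const double pref = gmu0 / (1.0 + alpha * alpha);

  std::vector<double> m(3 * np), n(3 * np);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 3; ++j) {
      m[3 * i + j] = m0(i, j);
      n[3 * i + j] = axes(i, j);
    }

  int nrec = (record_every > 0) ? nsteps / record_every : 0;
  NumericVector mz_rec(nrec);
  IntegerVector rec_idx(nrec);  // index into happ (0-based) of each record
  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericMatrix mdotn(nsamp, np);

  double max_norm_dev = 0.0;
  int irec = 0, isamp = 0;

  for (int k = 0; k < nsteps; ++k) {
    NumericVector noise;
    if (sigma_h > 0.0) noise = rnorm(3 * np, 0.0, sigma_h);
    const double h0 = happ[k], h1 = happ[k + 1];
    for (int i = 0; i < np; ++i) {
      double *mi = &m[3 * i];
      const double *ni = &n[3 * i];
      double hth[3] = {0.0, 0.0, 0.0};
      if (sigma_h > 0.0) {
        hth[0] = noise[3 * i];
        hth[1] = noise[3 * i + 1];
        hth[2] = noise[3 * i + 2];
      }
      double f0[3], f1[3], mp[3];
      llg_rhs(mi, ni, hth, h0, hk, alpha, pref, f0);
      mp[0] = mi[0] + dt * f0[0];
      mp[1] = mi[1] + dt * f0[1];
      mp[2] = mi[2] + dt * f0[2];
      llg_rhs(mp, ni, hth, h1, hk, alpha, pref, f1);
      mi[0] += 0.5 * dt * (f0[0] + f1[0]);
      mi[1] += 0.5 * dt * (f0[1] + f1[1]);
      mi[2] += 0.5 * dt * (f0[2] + f1[2]);
      double nrm = std::sqrt(mi[0] * mi[0] + mi[1] * mi[1] + mi[2] * mi[2]);
      if (!(nrm > 0.0) || !std::isfinite(nrm))
        stop("sLLG integration diverged at step %d; the timestep is too "
             "coarse for the field magnitudes involved", k + 1);
      mi[0] /= nrm; mi[1] /= nrm; mi[2] /= nrm;
      double dev = std::fabs(std::sqrt(mi[0] * mi[0] + mi[1] * mi[1] +
                                       mi[2] * mi[2]) - 1.0);
      if (dev > max_norm_dev) max_norm_dev = dev;
    }
    if (record_every > 0 && (k + 1) % record_every == 0) {
      double s = 0.0;
      for (int i = 0; i < np; ++i) s += m[3 * i + 2];
      mz_rec[irec] = s / np;
      rec_idx[irec] = k + 1;
      ++irec;
    }
    if (sample_every > 0 && (k + 1) % sample_every == 0) {
      for (int i = 0; i < np; ++i)
        mdotn(isamp, i) = m[3 * i] * n[3 * i] + m[3 * i + 1] * n[3 * i + 1] +
                          m[3 * i + 2] * n[3 * i + 2];
      ++isamp;
    }
  }

  NumericMatrix mfin(np, 3);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 3; ++j) mfin(i, j) = m[3 * i + j];

  return List::create(_["mz"] = mz_rec, _["rec_idx"] = rec_idx,
                      _["mdotn"] = mdotn, _["m_final"] = mfin,
                      _["max_norm_dev"] = max_norm_dev);
}
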