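#include <Rcpp.h>
using namespace Rcpp;

// Explicit FTCS stepper for the spherically symmetric heat equation
//   dT/dt = nu (1/r^2) d/dr (r^2 dT/dr) + q(r)
// in conservative (flux) form.  Node i sits at r_i = i*dr; the control
// volume of node 0 is the ball of radius dr/2, so the r = 0 update reduces
// to the symmetric stencil 6 nu (T1 - T0)/dr^2 and total energy
// sum_i V_i T_i is conserved exactly under adiabatic boundaries.
//
// rec_steps: strictly increasing 1-based step counts at which snapshots are
// taken; the run advances to the largest entry.
// [[Rcpp::export]]
NumericMatrix ftcs_radial_run(NumericVector T0, NumericVector src,
                              double dr, double dt, double nu,
                              IntegerVector rec_steps,
                              bool heating, bool dirichlet) {
  const int n = T0.size();
  const int nrec = rec_steps.size();
  const int nstep = rec_steps[nrec - 1];
  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> Tn(n);
  NumericMatrix out(nrec, n);

  const double inv_dr2 = 1.0 / (dr * dr);
  // face areas r_{i+1/2}^2 / r_i^2, precomputed per node
  std::vector<double> ap(n), am(n);
  for (int i = 1; i < n - 1; ++i) {
    double r = i * dr;
    double rp = r + 0.5 * dr, rm = r - 0.5 * dr;
    ap[i] = (rp * rp) / (r * r);
    am[i] = (rm * rm) / (r * r);
  }

  int irec = 0;
  for (int s = 1; s <= nstep; ++s) {
    Tn[0] = T[0] + dt * (6.0 * nu * (T[1] - T[0]) * inv_dr2 +
                         (heating ? src[0] : 0.0));
    for (int i = 1; i < n - 1; ++i) {
      double lap = (ap[i] * (T[i + 1] - T[i]) - am[i] * (T[i] - T[i - 1])) * inv_dr2;
      Tn[i] = T[i] + dt * (nu * lap + (heating ? src[i] : 0.0));
    }
    if (dirichlet) {
      Tn[n - 1] = 0.0;
    } else {
      // adiabatic: no flux through the outer face
      double r = (n - 1) * dr, rm = r - 0.5 * dr;
      double lap = -(rm * rm) / (r * r) * (T[n - 1] - T[n - 2]) * inv_dr2;
      Tn[n - 1] = T[n - 1] + dt * (nu * lap + (heating ? src[n - 1] : 0.0));
    }
    T.swap(Tn);
    if (irec < nrec && s == rec_steps[irec]) {
      for (int i = 0; i < n; ++i) out(irec, i) = T[i];
      ++irec;
    }
  }
  return out;
}

// Axisymmetric (r, z) FTCS for layered media with z-dependent conductivity
// K(z) and volumetric heat capacity C(z):
//   C dT/dt = d/dz (K dT/dz) + (1/r) d/dr (r K dT/dr)
// Conservative form; interface conductivities are harmonic means so that
// heat flux is continuous across material boundaries (K_w dT/dz = K_c dT/dz).
// All outer boundaries adiabatic.  Records the lateral-centre water-layer
// line integral sum_z wz(z) T(z, r=0) every rec_every steps.
// [[Rcpp::export]]
List ftcs_rz_run(NumericMatrix T0, NumericVector K, NumericVector C,
                 double dz, double dr, double dt,
                 int nstep, int rec_every, NumericVector wz) {
  const int nz = T0.nrow(), nr = T0.ncol();
  std::vector<double> T(nz * nr), Tn(nz * nr);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nz; ++i) T[i + j * nz] = T0(i, j);

  // harmonic-mean conductivity on z faces
  std::vector<double> Kh(nz - 1);
  for (int i = 0; i < nz - 1; ++i)
    Kh[i] = 2.0 * K[i] * K[i + 1] / (K[i] + K[i + 1]);

  const double inv_dz2 = 1.0 / (dz * dz), inv_dr2 = 1.0 / (dr * dr);
  std::vector<double> fp(nr), fm(nr);  // radial face factors r_{j+-1/2}/r_j
  for (int j = 1; j < nr - 1; ++j) {
    fp[j] = (j + 0.5) / (double)j;
    fm[j] = (j - 0.5) / (double)j;
  }

  int nrec = nstep / rec_every;
  NumericVector times(nrec), centre(nrec);
  int irec = 0;

  for (int s = 1; s <= nstep; ++s) {
    for (int j = 0; j < nr; ++j) {
      const double *Tc = &T[j * nz];
      const double *Tl = (j > 0) ? &T[(j - 1) * nz] : nullptr;
      const double *Tr = (j < nr - 1) ? &T[(j + 1) * nz] : nullptr;
      double *Tno = &Tn[j * nz];
      for (int i = 0; i < nz; ++i) {
        double fz = 0.0;
        if (i > 0)      fz -= Kh[i - 1] * (Tc[i] - Tc[i - 1]);
        if (i < nz - 1) fz += Kh[i] * (Tc[i + 1] - Tc[i]);
        fz *= inv_dz2;
        double frad = 0.0;
        if (j == 0) {
          frad = 4.0 * K[i] * (Tr[i] - Tc[i]) * inv_dr2;
        } else if (j == nr - 1) {
          // adiabatic outer face: inward flux only
          frad = -K[i] * ((j - 0.5) / (double)j) * (Tc[i] - Tl[i]) * inv_dr2;
        } else {
          frad = K[i] * (fp[j] * (Tr[i] - Tc[i]) - fm[j] * (Tc[i] - Tl[i])) * inv_dr2;
        }
        Tno[i] = Tc[i] + dt * (fz + frad) / C[i];
      }
    }
    T.swap(Tn);
    if (s % rec_every == 0 && irec < nrec) {
      double w = 0.0;
      for (int i = 0; i < nz; ++i) w += wz[i] * T[i];  // r = 0 column
      times[irec] = s * dt;
      centre[irec] = w;
      ++irec;
    }
  }

  NumericMatrix Tout(nz, nr);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nz; ++i) Tout(i, j) = T[i + j * nz];
  return List::create(_["time"] = times, _["centre"] = centre,
                      _["field"] = Tout);
}
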