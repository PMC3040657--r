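// Overdamped Langevin (Euler-Maruyama) engine for the coarse-grained
// bead-spring model. Forces: harmonic bonds, truncated-harmonic breakable
// contacts, truncated-harmonic hinge angles, a COM tether on the
// constrained group, and the pulling force of the active protocol.
// Uses R's RNG (norm_rand) so a given seed replays bit-identically.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dist3(const double* p, const double* q, double* d) {
  d[0] = p[0] - q[0]; d[1] = p[1] - q[1]; d[2] = p[2] - q[2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Dihedral angle a-b-c-d and, if F != nullptr, accumulate forces for the
// harmonic torsional potential U = 0.5 k (phi - phi0)^2 (phi wrapped).
// Standard analytic gradient (see e.g. Allen & Tildesley).
static double dihedralTerm(const double* xa, const double* xb,
                           const double* xc, const double* xd,
                           double phi0, double k,
                           double* Fa, double* Fb, double* Fc, double* Fd) {
  double b1[3], b2[3], b3[3];
  for (int i = 0; i < 3; ++i) {
    b1[i] = xb[i] - xa[i];
    b2[i] = xc[i] - xb[i];
    b3[i] = xd[i] - xc[i];
  }
  double n1[3], n2[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double ln1 = std::sqrt(dot3(n1, n1)), ln2 = std::sqrt(dot3(n2, n2));
  double lb2 = std::sqrt(dot3(b2, b2));
  double lb1 = std::sqrt(dot3(b1, b1)), lb3 = std::sqrt(dot3(b3, b3));
  if (lb2 < 1e-9) return 0.0;
  // skip near-degenerate geometries (arm almost parallel to the axis):
  // the angle becomes ill-defined and its gradient diverges
  if (ln1 < 0.15 * lb1 * lb2 || ln2 < 0.15 * lb3 * lb2) return 0.0;
  double m1[3];
  cross3(n1, b2, m1);
  double xcomp = dot3(n1, n2);
  double ycomp = dot3(m1, n2) / lb2;
  double phi = std::atan2(ycomp, xcomp);
  double dphi = phi - phi0;
  while (dphi > M_PI) dphi -= 2.0 * M_PI;
  while (dphi <= -M_PI) dphi += 2.0 * M_PI;
  if (Fa != 0) {
    // saturate the restoring torque at 1 rad deviation: the restraint is
    // a soft guide, and an unsaturated wrap-around torque can spike
    double dclamp = dphi > 1.0 ? 1.0 : (dphi < -1.0 ? -1.0 : dphi);
    double coef = -k * dclamp;                // -dU/dphi
    double fa[3], fd[3];
    for (int i = 0; i < 3; ++i) {
      fa[i] = coef * (lb2 / (ln1 * ln1)) * n1[i];
      fd[i] = coef * (-lb2 / (ln2 * ln2)) * n2[i];
    }
    double s1 = dot3(b1, b2) / (lb2 * lb2);
    double s2 = dot3(b3, b2) / (lb2 * lb2);
    for (int i = 0; i < 3; ++i) {
      double tb = -fa[i] - s1 * fa[i] + s2 * fd[i];
      double tc = -fd[i] + s1 * fa[i] - s2 * fd[i];
      Fa[i] += fa[i];
      Fb[i] += tb;
      Fc[i] += tc;
      Fd[i] += fd[i];
    }
  }
  return dphi;
}

// [[Rcpp::export(name = ".cppRunDynamics")]]
List cppRunDynamics(NumericMatrix xyz0,
                    IntegerVector bi, IntegerVector bj,
                    NumericVector br0, NumericVector bk,
                    IntegerVector ha, IntegerVector hb, IntegerVector hc,
                    NumericVector htheta0, NumericVector hk,
                    NumericVector hcut,
                    IntegerVector ci, IntegerVector cj,
                    NumericVector cr0, NumericVector ck,
                    NumericVector crbreak,
                    IntegerVector da, IntegerVector db,
                    IntegerVector dc, IntegerVector dd,
                    NumericVector dphi0, NumericVector dk,
                    IntegerVector pullIdx, IntegerVector consIdx,
                    int mode,            // 0 free, 1 const-velocity, 2 const-force
                    double kSpring, double vPull, double fConst,
                    bool trackDir, double kCons,
                    double gamma, double kbt, double dt,
                    int nsteps, int saveStride) {
  const int n = xyz0.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz0(i, d);

  const int nb = bi.size(), nh = ha.size(), nc = ci.size();
  const int nd = da.size();
  const int npull = pullIdx.size(), ncons = consIdx.size();
  const double noiseAmp = std::sqrt(2.0 * kbt * dt / gamma);

  // COM helpers (uniform weights)
  auto com = [&](const IntegerVector& idx, double* out) {
    out[0] = out[1] = out[2] = 0.0;
    for (int k = 0; k < idx.size(); ++k)
      for (int d = 0; d < 3; ++d) out[d] += x[3 * idx[k] + d];
    for (int d = 0; d < 3; ++d) out[d] /= idx.size();
  };

  double pull0[3] = {0, 0, 0}, cons0[3] = {0, 0, 0}, anchor[3] = {0, 0, 0};
  double uFix[3] = {0, 0, 1};
  if (npull > 0) com(pullIdx, pull0);
  if (ncons > 0) { com(consIdx, cons0); for (int d = 0; d < 3; ++d) anchor[d] = cons0[d]; }
  if (npull > 0 && ncons > 0) {
    double dvec[3], dn = dist3(pull0, cons0, dvec);
    if (dn > 1e-12) for (int d = 0; d < 3; ++d) uFix[d] = dvec[d] / dn;
  }

  const int nsave = 1 + nsteps / saveStride;
  NumericVector times(nsave);
  NumericVector traj(Dimension(nsave, n, 3));
  NumericMatrix forceRec(nsave, 12); // t fx fy fz fmag x pcom(3) ccom(3)

  std::vector<double> F(3 * n);
  int isave = 0;

  auto recordFrame = [&](int step) {
    double t = step * dt;
    times[isave] = t;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        traj[isave + nsave * (i + (R_xlen_t)n * d)] = x[3 * i + d];
    double pcom[3] = {0, 0, 0}, ccom[3] = {0, 0, 0};
    if (npull > 0) com(pullIdx, pcom);
    if (ncons > 0) com(consIdx, ccom);
    double u[3] = {uFix[0], uFix[1], uFix[2]};
    if (trackDir && npull > 0 && ncons > 0) {
      double dvec[3], dn = dist3(pcom, ccom, dvec);
      if (dn > 1e-12) for (int d = 0; d < 3; ++d) u[d] = dvec[d] / dn;
    }
    double xc = 0.0;
    for (int d = 0; d < 3; ++d) xc += (pcom[d] - pull0[d]) * u[d];
    double fmag = 0.0;
    if (mode == 1) fmag = kSpring * (vPull * t - xc);
    else if (mode == 2) fmag = fConst;
    forceRec(isave, 0) = t;
    for (int d = 0; d < 3; ++d) forceRec(isave, 1 + d) = fmag * u[d];
    forceRec(isave, 4) = fmag;
    forceRec(isave, 5) = xc;
    for (int d = 0; d < 3; ++d) forceRec(isave, 6 + d) = pcom[d];
    for (int d = 0; d < 3; ++d) forceRec(isave, 9 + d) = ccom[d];
    ++isave;
  };

  recordFrame(0);

  for (int step = 1; step <= nsteps; ++step) {
    std::fill(F.begin(), F.end(), 0.0);
    // bonds
    for (int b = 0; b < nb; ++b) {
      const int i = bi[b], j = bj[b];
      double dvec[3];
      double r = dist3(&x[3 * i], &x[3 * j], dvec);
      if (r < 1e-12) continue;
      double fm = -bk[b] * (r - br0[b]) / r;
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += fm * dvec[d];
        F[3 * j + d] -= fm * dvec[d];
      }
    }
    // breakable contacts (force only inside the break radius)
    for (int c = 0; c < nc; ++c) {
      const int i = ci[c], j = cj[c];
      double dvec[3];
      double r = dist3(&x[3 * i], &x[3 * j], dvec);
      if (r >= crbreak[c] || r < 1e-12) continue;
      double fm = -ck[c] * (r - cr0[c]) / r;
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += fm * dvec[d];
        F[3 * j + d] -= fm * dvec[d];
      }
    }
    // hinge angles (torque zero beyond the cutoff deviation)
    for (int h = 0; h < nh; ++h) {
      const int a = ha[h], b = hb[h], c = hc[h];
      double u[3], w[3];
      double lu = dist3(&x[3 * a], &x[3 * b], u);
      double lw = dist3(&x[3 * c], &x[3 * b], w);
      if (lu < 1e-12 || lw < 1e-12) continue;
      double cosT = (u[0] * w[0] + u[1] * w[1] + u[2] * w[2]) / (lu * lw);
      if (cosT > 1.0) cosT = 1.0; else if (cosT < -1.0) cosT = -1.0;
      double theta = std::acos(cosT);
      double dev = theta - htheta0[h];
      if (std::fabs(dev) >= hcut[h]) continue;
      double sinT = std::sqrt(1.0 - cosT * cosT);
      // floor the sine to keep the near-collinear gradient bounded
      if (sinT < 0.05) sinT = 0.05;
      double coef = -hk[h] * dev;     // -dU/dtheta
      for (int d = 0; d < 3; ++d) {
        double dthA = (cosT * u[d] / lu - w[d] / lw) / (lu * sinT);
        double dthC = (cosT * w[d] / lw - u[d] / lu) / (lw * sinT);
        double fa = coef * dthA, fc = coef * dthC;
        F[3 * a + d] += fa;
        F[3 * c + d] += fc;
        F[3 * b + d] -= (fa + fc);
      }
    }
    // torsional restraints
    for (int t = 0; t < nd; ++t)
      dihedralTerm(&x[3 * da[t]], &x[3 * db[t]], &x[3 * dc[t]],
                   &x[3 * dd[t]], dphi0[t], dk[t],
                   &F[3 * da[t]], &F[3 * db[t]], &F[3 * dc[t]],
                   &F[3 * dd[t]]);
    // constraint tether on the constrained COM
    if (ncons > 0 && kCons > 0) {
      double ccom[3];
      com(consIdx, ccom);
      for (int d = 0; d < 3; ++d) {
        double f = -kCons * (ccom[d] - anchor[d]) / ncons;
        for (int k = 0; k < ncons; ++k) F[3 * consIdx[k] + d] += f;
      }
    }
    // pulling force
    if (mode != 0 && npull > 0) {
      double pcom[3];
      com(pullIdx, pcom);
      double u[3] = {uFix[0], uFix[1], uFix[2]};
      if (trackDir && ncons > 0) {
        double ccom[3], dvec[3];
        com(consIdx, ccom);
        double dn = dist3(pcom, ccom, dvec);
        if (dn > 1e-12) for (int d = 0; d < 3; ++d) u[d] = dvec[d] / dn;
      }
      double fmag;
      if (mode == 1) {
        double t = step * dt;   // force evaluated at the step being taken
        double xc = 0.0;
        for (int d = 0; d < 3; ++d) xc += (pcom[d] - pull0[d]) * u[d];
        fmag = kSpring * (vPull * t - xc);
      } else {
        fmag = fConst;
      }
      for (int d = 0; d < 3; ++d) {
        double f = fmag * u[d] / npull;
        for (int k = 0; k < npull; ++k) F[3 * pullIdx[k] + d] += f;
      }
    }
    // Euler-Maruyama update with instability guard
    for (int i = 0; i < n; ++i) {
      double dx[3], norm2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = F[3 * i + d] * dt / gamma;
        if (noiseAmp > 0) dx[d] += noiseAmp * norm_rand();
        norm2 += dx[d] * dx[d];
      }
      if (norm2 > 25.0)
        stop("dynamics unstable at step %d, bead %d: displacement %.2f A "
             "(reduce dt or stiffness)", step, i + 1, std::sqrt(norm2));
      for (int d = 0; d < 3; ++d) x[3 * i + d] += dx[d];
    }
    if (step % saveStride == 0) recordFrame(step);
  }

  return List::create(_["times"] = times, _["coords"] = traj,
                      _["forceRecord"] = forceRec);
}

// Potential energy of a configuration (bonds + contacts + hinges),
// used by tests and analysis; pulling/tether terms excluded.
// [[Rcpp::export(name = ".cppPotentialEnergy")]]
double cppPotentialEnergy(NumericMatrix xyz,
                          IntegerVector bi, IntegerVector bj,
                          NumericVector br0, NumericVector bk,
                          IntegerVector ha, IntegerVector hb,
                          IntegerVector hc, NumericVector htheta0,
                          NumericVector hk, NumericVector hcut,
                          IntegerVector ci, IntegerVector cj,
                          NumericVector cr0, NumericVector ck,
                          NumericVector crbreak,
                          IntegerVector da, IntegerVector db,
                          IntegerVector dc, IntegerVector dd,
                          NumericVector dphi0, NumericVector dk) {
  const int n = xyz.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  double U = 0.0;
  double dvec[3];
  for (int b = 0; b < bi.size(); ++b) {
    double r = dist3(&x[3 * bi[b]], &x[3 * bj[b]], dvec);
    U += 0.5 * bk[b] * (r - br0[b]) * (r - br0[b]);
  }
  for (int c = 0; c < ci.size(); ++c) {
    double r = dist3(&x[3 * ci[c]], &x[3 * cj[c]], dvec);
    double dref = crbreak[c] - cr0[c];
    // continuous piecewise well: inside the break radius a shifted
    // harmonic, constant (zero) outside
    if (r < crbreak[c])
      U += 0.5 * ck[c] * ((r - cr0[c]) * (r - cr0[c]) - dref * dref);
  }
  for (int h = 0; h < ha.size(); ++h) {
    double u[3], w[3];
    double lu = dist3(&x[3 * ha[h]], &x[3 * hb[h]], u);
    double lw = dist3(&x[3 * hc[h]], &x[3 * hb[h]], w);
    if (lu < 1e-12 || lw < 1e-12) continue;
    double cosT = (u[0] * w[0] + u[1] * w[1] + u[2] * w[2]) / (lu * lw);
    if (cosT > 1.0) cosT = 1.0; else if (cosT < -1.0) cosT = -1.0;
    double dev = std::acos(cosT) - htheta0[h];
    double cut = hcut[h];
    if (std::fabs(dev) < cut)
      U += 0.5 * hk[h] * (dev * dev - cut * cut);
  }
  for (int t = 0; t < da.size(); ++t) {
    double dphi = dihedralTerm(&x[3 * da[t]], &x[3 * db[t]],
                               &x[3 * dc[t]], &x[3 * dd[t]],
                               dphi0[t], dk[t], 0, 0, 0, 0);
    U += 0.5 * dk[t] * dphi * dphi;
  }
  return U;
}
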