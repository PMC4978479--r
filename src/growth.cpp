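#include <Rcpp.h>
using namespace Rcpp;

// Rejection-sampling kernel for one chain-growth placement.
//
// Draws candidate positions at distance `step` from the origin bead until a
// candidate passes the acceptance conditions (inside nucleus, outside
// nucleolus, clearances to own and foreign beads, d1 upper window), or the
// shared failure counter reaches `restart_after`. Uses R's RNG so a seed set
// in R fully determines the draw sequence.
//
// xyz:   n x 3 matrix of existing bead centres (only rows 1..n are live)
// own:   logical, TRUE where the row belongs to the growing chromosome
// pool:  1-based row indices of the candidate precursory beads; one is
//        re-drawn uniformly on every attempt (so a wedged precursory bead
//        cannot exhaust the failure budget on its own) and is excluded
//        from the own-bead clearance scan
// Returns a list: either x/y/z/origin/fail on success, or restart=TRUE/fail
// when the failure budget is exhausted.
// [[Rcpp::export(name = ".place_domain_cpp")]]
List place_domain_cpp(NumericMatrix xyz, int n, LogicalVector own,
                      IntegerVector pool, double step, double r_in2,
                      double nox, double noy, double noz, double no_clear2,
                      double thr_own2, double thr_for2, double d1max2,
                      int fail0, double restart_after) {
  int npool = pool.size();
  double fail = fail0;
  for (;;) {
    int origin = pool[0];
    if (npool > 1) {
      int j = (int)(R::unif_rand() * npool);
      if (j >= npool) j = npool - 1;
      origin = pool[j];
    }
    double ox = xyz(origin - 1, 0), oy = xyz(origin - 1, 1),
           oz = xyz(origin - 1, 2);
    double theta = R::runif(0.0, M_PI);
    double phi = R::runif(0.0, 2.0 * M_PI);
    double sphi = sin(phi);
    double px = ox + step * cos(theta) * sphi;
    double py = oy + step * sin(theta) * sphi;
    double pz = oz + step * cos(phi);
    bool ok = (px * px + py * py + pz * pz < r_in2);
    if (ok) {
      double dx = px - nox, dy = py - noy, dz = pz - noz;
      ok = (dx * dx + dy * dy + dz * dz > no_clear2);
    }
    if (ok) {
      double min_own = R_PosInf;
      bool has_own = false;
      for (int i = 0; i < n; ++i) {
        double dx = xyz(i, 0) - px, dy = xyz(i, 1) - py, dz = xyz(i, 2) - pz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (own[i]) {
          has_own = true;
          if (d2 < min_own) min_own = d2;
          if (i != origin - 1 && d2 < thr_own2) { ok = false; break; }
        } else if (d2 < thr_for2) { ok = false; break; }
      }
      if (ok && has_own && !(min_own <= d1max2)) ok = false;  // C4
      if (ok)
        return List::create(_["x"] = px, _["y"] = py, _["z"] = pz,
                            _["origin"] = origin, _["fail"] = fail);
    }
    if (++fail >= restart_after)
      return List::create(_["restart"] = true, _["fail"] = fail);
    if (((long long)fail & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
}

// Same idea for centromere seeding: candidates drawn uniformly in the
// nucleus bounding cube, accepted by conditions C1-C3.
// [[Rcpp::export(name = ".place_centromere_cpp")]]
List place_centromere_cpp(NumericMatrix cen, int ncen, double R,
                          double rmax2, double nox, double noy, double noz,
                          double no_clear2, double min_sep2,
                          int fail0, double restart_after) {
  double fail = fail0;
  for (;;) {
    double px = R::runif(-R, R);
    double py = R::runif(-R, R);
    double pz = R::runif(-R, R);
    bool ok = (px * px + py * py + pz * pz < rmax2);
    if (ok) {
      double dx = px - nox, dy = py - noy, dz = pz - noz;
      ok = (dx * dx + dy * dy + dz * dz > no_clear2);
    }
    if (ok) {
      for (int i = 0; i < ncen; ++i) {
        double dx = cen(i, 0) - px, dy = cen(i, 1) - py, dz = cen(i, 2) - pz;
        if (dx * dx + dy * dy + dz * dz <= min_sep2) { ok = false; break; }
      }
    }
    if (ok)
      return List::create(_["x"] = px, _["y"] = py, _["z"] = pz,
                          _["fail"] = fail);
    if (++fail >= restart_after)
      return List::create(_["restart"] = true, _["fail"] = fail);
    if (((long long)fail & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
}
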