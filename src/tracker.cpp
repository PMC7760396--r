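// Cell location and Lagrangian particle advection on (possibly moving)
// tetrahedral meshes. Velocity is interpolated barycentrically in space and
// linearly in time; the stored frames cover one period and are extended
// periodically. Exits are detected by crossing a cap plane within the cap
// radius; wall penetrations are resolved by bisecting back to the interior.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct MeshView {
  const int *tets;      // m x 4, 0-based, column-major
  const int *nbr;       // m x 4, -1 = boundary
  int m;
  const double *ref;    // n x 3 reference nodes, column-major
  int n;
  bool moving;
  std::vector<const double *> pos;  // per-frame node positions (n x 3)
  std::vector<const double *> vel;  // per-frame node velocities (n x 3)
  const double *times;
  int nframes;
  double t0, period;
};

struct TimeLoc {
  int j;        // lower frame index
  double alpha; // interpolation weight toward frame j+1
};

inline TimeLoc timeLocate(const MeshView &mv, double t) {
  // periodic reduction of t into [t0, t0 + period)
  double u = (t - mv.t0) / mv.period;
  double tau = mv.t0 + (u - std::floor(u)) * mv.period;
  if (tau < mv.times[0]) tau = mv.times[0];
  if (tau > mv.times[mv.nframes - 1]) tau = mv.times[mv.nframes - 1];
  int lo = 0, hi = mv.nframes - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (mv.times[mid] <= tau) lo = mid; else hi = mid;
  }
  double dt = mv.times[lo + 1] - mv.times[lo];
  TimeLoc tl;
  tl.j = lo;
  tl.alpha = dt > 0 ? (tau - mv.times[lo]) / dt : 0.0;
  return tl;
}

inline void nodePos(const MeshView &mv, const TimeLoc &tl, int node, double *out) {
  if (!mv.moving) {
    out[0] = mv.ref[node];
    out[1] = mv.ref[node + mv.n];
    out[2] = mv.ref[node + 2 * mv.n];
  } else {
    const double *a = mv.pos[tl.j];
    const double *b = mv.pos[tl.j + 1];
    double al = tl.alpha;
    out[0] = (1 - al) * a[node] + al * b[node];
    out[1] = (1 - al) * a[node + mv.n] + al * b[node + mv.n];
    out[2] = (1 - al) * a[node + 2 * mv.n] + al * b[node + 2 * mv.n];
  }
}

// barycentric weights of x in cell c at the given time; returns det
inline double bary(const MeshView &mv, const TimeLoc &tl, int c,
                   const double *x, double *w) {
  double P[4][3];
  for (int k = 0; k < 4; ++k) nodePos(mv, tl, mv.tets[c + k * mv.m], P[k]);
  double b[3], cc[3], d[3], p[3];
  for (int i = 0; i < 3; ++i) {
    b[i] = P[1][i] - P[0][i];
    cc[i] = P[2][i] - P[0][i];
    d[i] = P[3][i] - P[0][i];
    p[i] = x[i] - P[0][i];
  }
  double cd0 = cc[1] * d[2] - cc[2] * d[1];
  double cd1 = cc[2] * d[0] - cc[0] * d[2];
  double cd2 = cc[0] * d[1] - cc[1] * d[0];
  double det = b[0] * cd0 + b[1] * cd1 + b[2] * cd2;
  double w2 = (p[0] * cd0 + p[1] * cd1 + p[2] * cd2) / det;
  double pd0 = p[1] * d[2] - p[2] * d[1];
  double pd1 = p[2] * d[0] - p[0] * d[2];
  double pd2 = p[0] * d[1] - p[1] * d[0];
  double w3 = (b[0] * pd0 + b[1] * pd1 + b[2] * pd2) / det;
  double cp0 = cc[1] * p[2] - cc[2] * p[1];
  double cp1 = cc[2] * p[0] - cc[0] * p[2];
  double cp2 = cc[0] * p[1] - cc[1] * p[0];
  double w4 = (b[0] * cp0 + b[1] * cp1 + b[2] * cp2) / det;
  w[0] = 1 - w2 - w3 - w4;
  w[1] = w2;
  w[2] = w3;
  w[3] = w4;
  return det;
}

int locateScan(const MeshView &mv, const TimeLoc &tl, const double *x,
               double tol, double *w) {
  for (int c = 0; c < mv.m; ++c) {
    bary(mv, tl, c, x, w);
    if (w[0] >= -tol && w[1] >= -tol && w[2] >= -tol && w[3] >= -tol) return c;
  }
  return -1;
}

int locateWalk(const MeshView &mv, const TimeLoc &tl, const double *x,
               int start, double tol, double *w, bool allow_scan) {
  int c = (start >= 0 && start < mv.m) ? start : 0;
  int prev = -1;
  for (int iter = 0; iter < 2000; ++iter) {
    bary(mv, tl, c, x, w);
    int worst = 0;
    double wmin = w[0];
    for (int k = 1; k < 4; ++k) if (w[k] < wmin) { wmin = w[k]; worst = k; }
    if (wmin >= -tol) return c;
    int nxt = mv.nbr[c + worst * mv.m];
    if (nxt < 0 || nxt == prev) {
      // try the second-most-negative direction before giving up
      int alt = -1;
      double amin = 0;
      for (int k = 0; k < 4; ++k) {
        if (k == worst) continue;
        if (w[k] < amin) { amin = w[k]; alt = k; }
      }
      if (alt >= 0) {
        int nxt2 = mv.nbr[c + alt * mv.m];
        if (nxt2 >= 0 && nxt2 != prev) { prev = c; c = nxt2; continue; }
      }
      // wedged at the boundary: the point is (almost surely) outside through
      // this face; a full scan is only done when robustness is requested
      return allow_scan ? locateScan(mv, tl, x, tol, w) : -1;
    }
    prev = c;
    c = nxt;
  }
  return allow_scan ? locateScan(mv, tl, x, tol, w) : -1;
}

// bounded breadth-first search around a hint cell; resolves points the
// face-walk wedges on (e.g. in corner cells with two boundary faces)
int locateLocal(const MeshView &mv, const TimeLoc &tl, const double *x,
                int start, double tol, double *w, int budget = 96) {
  if (start < 0 || start >= mv.m) return -1;
  std::vector<int> queue;
  queue.reserve(budget + 4);
  queue.push_back(start);
  for (int qi = 0; qi < (int)queue.size() && qi < budget; ++qi) {
    int c = queue[qi];
    bary(mv, tl, c, x, w);
    if (w[0] >= -tol && w[1] >= -tol && w[2] >= -tol && w[3] >= -tol) return c;
    for (int f = 0; f < 4; ++f) {
      int nb = mv.nbr[c + f * mv.m];
      if (nb < 0) continue;
      bool seen = false;
      for (int j = 0; j < (int)queue.size(); ++j)
        if (queue[j] == nb) { seen = true; break; }
      if (!seen && (int)queue.size() < budget) queue.push_back(nb);
    }
  }
  return -1;
}

// interpolated velocity at (x, t); returns false if x is outside the mesh
bool velocityAt(const MeshView &mv, double t, const double *x, int &cell_hint,
                double tol, bool scan_only, double *v) {
  TimeLoc tl = timeLocate(mv, t);
  double w[4];
  int c = scan_only ? locateScan(mv, tl, x, tol, w)
                    : locateWalk(mv, tl, x, cell_hint, tol, w, false);
  if (c < 0 && !scan_only) c = locateLocal(mv, tl, x, cell_hint, tol, w);
  if (c < 0) return false;
  cell_hint = c;
  const double *va = mv.vel[tl.j];
  const double *vb = mv.vel[tl.j + 1];
  double al = tl.alpha;
  v[0] = v[1] = v[2] = 0;
  for (int k = 0; k < 4; ++k) {
    int node = mv.tets[c + k * mv.m];
    for (int i = 0; i < 3; ++i) {
      double vn = (1 - al) * va[node + i * mv.n] + al * vb[node + i * mv.n];
      v[i] += w[k] * vn;
    }
  }
  return true;
}

bool insideAt(const MeshView &mv, double t, const double *x, int &cell_hint,
              double tol, bool scan_only) {
  TimeLoc tl = timeLocate(mv, t);
  double w[4];
  int c = scan_only ? locateScan(mv, tl, x, tol, w)
                    : locateWalk(mv, tl, x, cell_hint, tol, w, false);
  if (c < 0 && !scan_only) c = locateLocal(mv, tl, x, cell_hint, tol, w);
  if (c >= 0) { cell_hint = c; return true; }
  return false;
}

// centroid of cell c at time t
inline void cellCentroid(const MeshView &mv, double t, int c, double *out) {
  TimeLoc tl = timeLocate(mv, t);
  double P[3];
  out[0] = out[1] = out[2] = 0;
  for (int k = 0; k < 4; ++k) {
    nodePos(mv, tl, mv.tets[c + k * mv.m], P);
    for (int i = 0; i < 3; ++i) out[i] += 0.25 * P[i];
  }
}


// outward unit normal of local face f of cell c (face = nodes except f),
// oriented away from the opposite vertex
inline void faceOutwardNormal(const MeshView &mv, const TimeLoc &tl, int c,
                              int f, double *nrm) {
  int idx[3], q = 0;
  for (int k = 0; k < 4; ++k) if (k != f) idx[q++] = mv.tets[c + k * mv.m];
  double A[3], B[3], Cc[3], O[3];
  nodePos(mv, tl, idx[0], A);
  nodePos(mv, tl, idx[1], B);
  nodePos(mv, tl, idx[2], Cc);
  nodePos(mv, tl, mv.tets[c + f * mv.m], O);
  double e1[3], e2[3];
  for (int i = 0; i < 3; ++i) { e1[i] = B[i] - A[i]; e2[i] = Cc[i] - A[i]; }
  nrm[0] = e1[1] * e2[2] - e1[2] * e2[1];
  nrm[1] = e1[2] * e2[0] - e1[0] * e2[2];
  nrm[2] = e1[0] * e2[1] - e1[1] * e2[0];
  double dot = 0, nn = 0;
  for (int i = 0; i < 3; ++i) { dot += nrm[i] * (O[i] - A[i]); nn += nrm[i] * nrm[i]; }
  double sgn = dot > 0 ? -1.0 : 1.0;  // point away from the opposite vertex
  nn = std::sqrt(nn);
  for (int i = 0; i < 3; ++i) nrm[i] *= sgn / nn;
}

} // namespace

// [[Rcpp::export]]
List cpp_locate_point(IntegerMatrix tets0, IntegerMatrix nbr0,
                      NumericMatrix positions, NumericVector point,
                      int start_cell, double tol) {
  MeshView mv;
  mv.tets = tets0.begin();
  mv.nbr = nbr0.begin();
  mv.m = tets0.nrow();
  mv.ref = positions.begin();
  mv.n = positions.nrow();
  mv.moving = false;
  static const double tms[2] = {0.0, 1.0};
  mv.times = tms;
  mv.nframes = 2;
  mv.t0 = 0;
  mv.period = 1;
  TimeLoc tl; tl.j = 0; tl.alpha = 0;
  double w[4];
  double x[3] = {point[0], point[1], point[2]};
  int c = locateWalk(mv, tl, x, start_cell, tol, w, true);
  NumericVector wv(4);
  if (c >= 0) {
    double s = 0;
    for (int k = 0; k < 4; ++k) { if (w[k] < 0) w[k] = 0; s += w[k]; }
    for (int k = 0; k < 4; ++k) wv[k] = w[k] / s;
  }
  return List::create(_["cell"] = c, _["weights"] = wv);
}

// [[Rcpp::export]]
List cpp_advect(IntegerMatrix tets0, IntegerMatrix nbr0, NumericMatrix nodes_ref,
                List frame_pos, List frame_vel, NumericVector frame_times,
                double period, bool moving, NumericMatrix caps,
                NumericMatrix seeds, NumericVector seed_times,
                double substep, double t_end, double tol, bool scan_only) {
  MeshView mv;
  mv.tets = tets0.begin();
  mv.nbr = nbr0.begin();
  mv.m = tets0.nrow();
  mv.ref = nodes_ref.begin();
  mv.n = nodes_ref.nrow();
  mv.moving = moving;
  int F = frame_vel.size();
  std::vector<NumericMatrix> velM, posM;
  for (int f = 0; f < F; ++f) {
    velM.push_back(as<NumericMatrix>(frame_vel[f]));
    mv.vel.push_back(velM.back().begin());
  }
  if (moving) {
    for (int f = 0; f < F; ++f) {
      posM.push_back(as<NumericMatrix>(frame_pos[f]));
      mv.pos.push_back(posM.back().begin());
    }
  }
  mv.times = frame_times.begin();
  mv.nframes = F;
  mv.t0 = frame_times[0];
  mv.period = period;

  int P = seeds.nrow();
  int K = caps.nrow();
  IntegerVector state(P), exit_patch(P), final_cell(P);
  NumericVector exit_time(P, NA_REAL);
  NumericMatrix final_pos(P, 3);

  for (int p = 0; p < P; ++p) {
    double x[3] = {seeds(p, 0), seeds(p, 1), seeds(p, 2)};
    double t = seed_times[p];
    int cell = 0;
    int st = 0; // 0 active, 1 exited, 2 stranded
    {
      TimeLoc tl = timeLocate(mv, t);
      double w[4];
      cell = locateScan(mv, tl, x, tol, w);
      if (cell < 0) st = 2;
    }
    int stuck = 0;
    while (st == 0 && t < t_end - 1e-12) {
      double h = substep;
      if (t + h > t_end) h = t_end - t;
      double k1[3], k2[3], k3[3], k4[3], xs[3];
      int hint = cell;
      bool ok = velocityAt(mv, t, x, hint, tol, scan_only, k1);
      if (!ok) { st = 2; break; }
      for (int i = 0; i < 3; ++i) xs[i] = x[i] + 0.5 * h * k1[i];
      if (!velocityAt(mv, t + 0.5 * h, xs, hint, tol, scan_only, k2))
        for (int i = 0; i < 3; ++i) k2[i] = k1[i];
      for (int i = 0; i < 3; ++i) xs[i] = x[i] + 0.5 * h * k2[i];
      if (!velocityAt(mv, t + 0.5 * h, xs, hint, tol, scan_only, k3))
        for (int i = 0; i < 3; ++i) k3[i] = k2[i];
      for (int i = 0; i < 3; ++i) xs[i] = x[i] + h * k3[i];
      if (!velocityAt(mv, t + h, xs, hint, tol, scan_only, k4))
        for (int i = 0; i < 3; ++i) k4[i] = k3[i];
      double xn[3];
      for (int i = 0; i < 3; ++i)
        xn[i] = x[i] + h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);

      // cap-plane crossing
      bool exited = false;
      for (int k = 0; k < K && !exited; ++k) {
        double cx = caps(k, 0), cy = caps(k, 1), cz = caps(k, 2);
        double nx = caps(k, 3), ny = caps(k, 4), nz = caps(k, 5);
        double so = (x[0] - cx) * nx + (x[1] - cy) * ny + (x[2] - cz) * nz;
        double sn = (xn[0] - cx) * nx + (xn[1] - cy) * ny + (xn[2] - cz) * nz;
        if (sn > 0 && so <= 1e-12 && sn > so) {
          double frac = so < 0 ? so / (so - sn) : 0.0;
          double xc[3];
          for (int i = 0; i < 3; ++i) xc[i] = x[i] + frac * (xn[i] - x[i]);
          double dx = xc[0] - cx, dy = xc[1] - cy, dz = xc[2] - cz;
          double along = dx * nx + dy * ny + dz * nz;
          double lx = dx - along * nx, ly = dy - along * ny, lz = dz - along * nz;
          double lat = std::sqrt(lx * lx + ly * ly + lz * lz);
          if (lat <= 1.15 * caps(k, 6)) {
            exited = true;
            st = 1;
            exit_patch[p] = (int)caps(k, 7);
            exit_time[p] = t + frac * h;
            for (int i = 0; i < 3; ++i) x[i] = xc[i];
          }
        }
      }
      if (exited) break;

      int cell_new = cell;
      if (insideAt(mv, t + h, xn, cell_new, tol, scan_only)) {
        for (int i = 0; i < 3; ++i) x[i] = xn[i];
        cell = cell_new;
        t += h;
        stuck = 0;
        continue;
      }
      // wall penetration: bisect along the step segment back to the
      // interior, then slide the unconsumed displacement along the wall
      double lo = 0.0, hi = 1.0;
      for (int it = 0; it < 12; ++it) {
        double mid = 0.5 * (lo + hi);
        double xm[3];
        for (int i = 0; i < 3; ++i) xm[i] = x[i] + mid * (xn[i] - x[i]);
        int ch = cell;
        if (insideAt(mv, t + h, xm, ch, tol, scan_only)) lo = mid; else hi = mid;
      }
      double theta = 0.95 * lo;
      double xm[3];
      for (int i = 0; i < 3; ++i) xm[i] = x[i] + theta * (xn[i] - x[i]);
      int ch = cell;
      bool placed = false;
      if (insideAt(mv, t + h, xm, ch, tol, scan_only)) {
        placed = true;
      } else if (insideAt(mv, t + h, x, ch, tol, scan_only)) {
        for (int i = 0; i < 3; ++i) xm[i] = x[i];
        placed = true;
      }
      if (placed) {
        // identify the wall face the particle is resting on (a boundary face
        // of ch with near-zero barycentric weight) and slide the remaining
        // displacement along its plane
        TimeLoc tlh = timeLocate(mv, t + h);
        double wb[4];
        bary(mv, tlh, ch, xm, wb);
        int bface = -1;
        double bw = 0.2;
        for (int f = 0; f < 4; ++f) {
          if (mv.nbr[ch + f * mv.m] < 0 && wb[f] < bw) { bw = wb[f]; bface = f; }
        }
        if (bface >= 0) {
          double nrm[3];
          faceOutwardNormal(mv, tlh, ch, bface, nrm);
          double rem[3];
          for (int i = 0; i < 3; ++i) rem[i] = (1.0 - theta) * (xn[i] - x[i]);
          double rn = rem[0] * nrm[0] + rem[1] * nrm[1] + rem[2] * nrm[2];
          if (rn > 0) for (int i = 0; i < 3; ++i) rem[i] -= rn * nrm[i];
          // corner (two wall planes): project off the second boundary face
          // as well, so the particle can creep along the wall edge
          for (int f = 0; f < 4; ++f) {
            if (f == bface || mv.nbr[ch + f * mv.m] >= 0 || wb[f] >= 0.2)
              continue;
            double n2v[3];
            faceOutwardNormal(mv, tlh, ch, f, n2v);
            double dd = n2v[0] * nrm[0] + n2v[1] * nrm[1] + n2v[2] * nrm[2];
            for (int i = 0; i < 3; ++i) n2v[i] -= dd * nrm[i];
            double nn2 = std::sqrt(n2v[0] * n2v[0] + n2v[1] * n2v[1] +
                                   n2v[2] * n2v[2]);
            if (nn2 < 1e-8) continue;
            for (int i = 0; i < 3; ++i) n2v[i] /= nn2;
            double rn2 = rem[0] * n2v[0] + rem[1] * n2v[1] + rem[2] * n2v[2];
            if (rn2 > 0) for (int i = 0; i < 3; ++i) rem[i] -= rn2 * n2v[i];
            break;
          }
          double xs[3];
          for (int i = 0; i < 3; ++i) xs[i] = xm[i] + rem[i];
          int ch3 = ch;
          if (insideAt(mv, t + h, xs, ch3, tol, scan_only)) {
            for (int i = 0; i < 3; ++i) x[i] = xs[i];
            cell = ch3;
            t += h;
            if (++stuck > 1000000) { st = 2; break; }
            continue;
          }
          // sliding target outside (corner): bisect the slide too
          double sl = 0.0, sh = 1.0;
          for (int it = 0; it < 8; ++it) {
            double mid = 0.5 * (sl + sh);
            double xq[3];
            for (int i = 0; i < 3; ++i) xq[i] = xm[i] + mid * rem[i];
            int cq = ch;
            if (insideAt(mv, t + h, xq, cq, tol, scan_only)) sl = mid; else sh = mid;
          }
          if (sl > 0) {
            double xq[3];
            for (int i = 0; i < 3; ++i) xq[i] = xm[i] + 0.9 * sl * rem[i];
            int cq = ch;
            if (insideAt(mv, t + h, xq, cq, tol, scan_only)) {
              for (int i = 0; i < 3; ++i) xm[i] = xq[i];
              ch = cq;
            }
          }
        }
        // project off the wall: pull toward the cell interior so the
        // particle keeps a finite slip velocity instead of freezing on the
        // no-slip boundary. Only the component transverse to the local
        // velocity is applied, so the pull cannot cancel streamwise advance
        // (a full centroid pull can pin particles against a tapering wall).
        double ctr[3], xp[3];
        cellCentroid(mv, t + h, ch, ctr);
        double d0[3], d[3];
        for (int i = 0; i < 3; ++i) d0[i] = 0.25 * (ctr[i] - xm[i]);
        for (int i = 0; i < 3; ++i) d[i] = d0[i];
        double v2 = k1[0] * k1[0] + k1[1] * k1[1] + k1[2] * k1[2];
        if (v2 > 0) {
          double dv = (d[0] * k1[0] + d[1] * k1[1] + d[2] * k1[2]) / v2;
          for (int i = 0; i < 3; ++i) d[i] -= dv * k1[i];
        }
        // if the transverse remainder is negligible (slim cell aligned with
        // the flow), fall back to the full centroid pull
        double n2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        double m2 = d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2];
        if (n2 < 0.01 * m2) for (int i = 0; i < 3; ++i) d[i] = d0[i];
        for (int i = 0; i < 3; ++i) xp[i] = xm[i] + d[i];
        int ch2 = ch;
        if (insideAt(mv, t + h, xp, ch2, tol, scan_only)) {
          for (int i = 0; i < 3; ++i) x[i] = xp[i];
          cell = ch2;
        } else {
          // transverse pull blocked: try the full pull before giving up
          for (int i = 0; i < 3; ++i) xp[i] = xm[i] + d0[i];
          ch2 = ch;
          if (insideAt(mv, t + h, xp, ch2, tol, scan_only)) {
            for (int i = 0; i < 3; ++i) x[i] = xp[i];
            cell = ch2;
          } else {
            for (int i = 0; i < 3; ++i) x[i] = xm[i];
            cell = ch;
          }
        }
        if (++stuck > 1000000) { st = 2; break; }
      } else {
        st = 2;  // lost (e.g. squeezed out by mesh motion)
        break;
      }
      t += h;
    }
    state[p] = st;
    final_cell[p] = cell + 1;
    for (int i = 0; i < 3; ++i) final_pos(p, i) = x[i];
  }
  return List::create(_["state"] = state, _["exit_patch"] = exit_patch,
                      _["exit_time"] = exit_time, _["final_pos"] = final_pos,
                      _["final_cell"] = final_cell);
}
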