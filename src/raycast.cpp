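#include <Rcpp.h>
using namespace Rcpp;

// Ray / capsule-set intersection used by the synthetic lidar.
//
// All rays share one origin (the sensor). Capsules are rows of a m x 7
// matrix (p0x p0y p0z p1x p1y p1z radius). The axis-aligned room box
// (xmin xmax ymin ymax zmin zmax) encloses the sensor; every ray therefore
// exits through a box face, which models the floor/walls/ceiling return.
//
// Returns, per ray, the range to the first surface hit and an integer id:
// 0 = box face, k >= 1 = capsule row k.

static inline double ray_capsule(const double ox, const double oy, const double oz,
                                 const double dx, const double dy, const double dz,
                                 const double *cap) {
  const double ax = cap[0], ay = cap[1], az = cap[2];
  const double bx = cap[3] - ax, by = cap[4] - ay, bz = cap[5] - az;
  const double r = cap[6];
  const double bb = bx * bx + by * by + bz * bz;
  const double wx = ox - ax, wy = oy - ay, wz = oz - az;
  double best = R_PosInf;

  if (bb > 1e-16) {
    // infinite cylinder about the segment axis
    const double db = dx * bx + dy * by + dz * bz;
    const double wb = wx * bx + wy * by + wz * bz;
    const double A = 1.0 - db * db / bb;
    const double B = (dx * wx + dy * wy + dz * wz) - db * wb / bb;
    const double C = (wx * wx + wy * wy + wz * wz) - wb * wb / bb - r * r;
    if (std::fabs(A) > 1e-14) {
      const double disc = B * B - A * C;
      if (disc >= 0.0) {
        const double t = (-B - std::sqrt(disc)) / A;
        if (t > 1e-9) {
          const double s = (wb + t * db) / bb;  // axial parameter of hit
          if (s >= 0.0 && s <= 1.0) best = t;
        }
      }
    }
  }
  // spherical end caps
  for (int cap_i = 0; cap_i < 2; ++cap_i) {
    const double cx = cap_i ? cap[3] : cap[0];
    const double cy = cap_i ? cap[4] : cap[1];
    const double cz = cap_i ? cap[5] : cap[2];
    const double ux = ox - cx, uy = oy - cy, uz = oz - cz;
    const double B = dx * ux + dy * uy + dz * uz;
    const double C = ux * ux + uy * uy + uz * uz - r * r;
    const double disc = B * B - C;
    if (disc >= 0.0) {
      const double t = -B - std::sqrt(disc);
      if (t > 1e-9 && t < best) best = t;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_raycast(NumericVector origin, NumericMatrix dirs,
                 NumericMatrix capsules, NumericVector box) {
  const int n = dirs.nrow();
  const int m = capsules.nrow();
  NumericVector tout(n);
  IntegerVector hit(n);
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  std::vector<double> caps(m * 7);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < 7; ++j) caps[k * 7 + j] = capsules(k, j);

  for (int i = 0; i < n; ++i) {
    const double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    // exit range through the box (origin assumed strictly inside)
    double tbox = R_PosInf;
    const double o[3] = {ox, oy, oz};
    const double d[3] = {dx, dy, dz};
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(d[ax]) < 1e-14) continue;
      const double bound = d[ax] > 0 ? box[2 * ax + 1] : box[2 * ax];
      const double t = (bound - o[ax]) / d[ax];
      if (t > 0 && t < tbox) tbox = t;
    }
    double tbest = tbox;
    int id = 0;
    for (int k = 0; k < m; ++k) {
      const double t = ray_capsule(ox, oy, oz, dx, dy, dz, &caps[k * 7]);
      if (t < tbest) { tbest = t; id = k + 1; }
    }
    tout[i] = tbest;
    hit[i] = id;
  }
  return List::create(_["range"] = tout, _["hit"] = hit);
}
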