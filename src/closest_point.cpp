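#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on a single triangle (a, b, c) to point p.
// Region-based algorithm (Ericson, Real-Time Collision Detection, ch. 5).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".closest_point_mesh")]]
List closest_point_mesh(NumericMatrix query, NumericMatrix verts,
                        IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  NumericVector dist(nq);
  NumericMatrix pts(nq, 3);
  IntegerVector fidx(nq);

  // column-major copies for cache-friendly row access
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int d = 0; d < 3; ++d) V[3 * i + d] = verts(i, d);
  std::vector<int> F(nf * 3);
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < 3; ++d) F[3 * i + d] = faces(i, d) - 1;

  // per-face centroid and bounding radius for a quick reject
  std::vector<double> cen(nf * 3), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const double *a = &V[3 * F[3 * f]], *b = &V[3 * F[3 * f + 1]],
                 *c = &V[3 * F[3 * f + 2]];
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) cen[3 * f + d] = (a[d] + b[d] + c[d]) / 3.0;
    const double *corners[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      for (int d = 0; d < 3; ++d) {
        double t = corners[k][d] - cen[3 * f + d];
        s += t * t;
      }
      if (s > r2) r2 = s;
    }
    rad[f] = std::sqrt(r2);
  }

  double q[3], best[3], cand[3];
  for (int i = 0; i < nq; ++i) {
    for (int d = 0; d < 3; ++d) q[d] = query(i, d);
    double bestd = R_PosInf;
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      double dc = 0.0;
      for (int d = 0; d < 3; ++d) {
        double t = q[d] - cen[3 * f + d];
        dc += t * t;
      }
      double lower = std::sqrt(dc) - rad[f];
      if (lower >= bestd) continue;
      const double *a = &V[3 * F[3 * f]], *b = &V[3 * F[3 * f + 1]],
                   *c = &V[3 * F[3 * f + 2]];
      closest_on_tri(q, a, b, c, cand);
      double s = 0.0;
      for (int d = 0; d < 3; ++d) {
        double t = q[d] - cand[d];
        s += t * t;
      }
      double dd = std::sqrt(s);
      if (dd < bestd) {
        bestd = dd;
        bestf = f;
        for (int d = 0; d < 3; ++d) best[d] = cand[d];
      }
    }
    dist[i] = bestd;
    fidx[i] = bestf + 1;
    for (int d = 0; d < 3; ++d) pts(i, d) = best[d];
  }
  return List::create(_["dist"] = dist, _["point"] = pts, _["face"] = fidx);
}
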