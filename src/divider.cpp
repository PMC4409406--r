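#include <Rcpp.h>
using namespace Rcpp;

// Divider ("ruler") walk along a polyline.
//
// Starting at the first vertex, repeatedly step to the first point along the
// polyline (linearly interpolated within edges) whose straight-line (chord)
// distance from the current anchor equals delta.  On a straight edge the
// chord distance from a fixed anchor is a convex function of arc position,
// so the first edge whose far endpoint reaches distance >= delta contains
// the crossing, and the crossing is the unique positive root of a quadratic.
//
// Returns the number of full divider steps and the straight-line remainder
// from the last anchor to the final vertex.  Zero full steps means the path
// is shorter than delta at the chord scale; callers treat L as undefined.
// [[Rcpp::export]]
List divider_walk_cpp(NumericVector x, NumericVector y, double delta) {
  const int n = x.size();
  if (n < 2 || delta <= 0.0)
    return List::create(_["n_steps"] = 0, _["remainder"] = NA_REAL);

  const double d2 = delta * delta;
  double ax = x[0], ay = y[0];   // current anchor
  double cx = ax, cy = ay;       // current position on the polyline
  int j = 0;                     // edge index: current position lies on [j, j+1]
  long nsteps = 0;

  while (true) {
    bool found = false;
    for (int k = j; k < n - 1; ++k) {
      const double px = (k == j) ? cx : x[k];
      const double py = (k == j) ? cy : y[k];
      const double qx = x[k + 1], qy = y[k + 1];
      const double dqx = qx - ax, dqy = qy - ay;
      if (dqx * dqx + dqy * dqy >= d2) {
        // crossing within [p, q]
        const double dx = qx - px, dy = qy - py;
        const double ex = px - ax, ey = py - ay;
        const double a = dx * dx + dy * dy;
        if (a <= 0.0) continue;  // degenerate duplicate vertex
        const double b = 2.0 * (dx * ex + dy * ey);
        const double c = ex * ex + ey * ey - d2;
        double disc = b * b - 4.0 * a * c;
        if (disc < 0.0) disc = 0.0;
        double t = (-b + std::sqrt(disc)) / (2.0 * a);
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
        cx = px + t * dx;
        cy = py + t * dy;
        ax = cx;
        ay = cy;
        j = k;
        ++nsteps;
        found = true;
        break;
      }
    }
    if (!found) {
      const double rx = x[n - 1] - ax, ry = y[n - 1] - ay;
      const double rem = std::sqrt(rx * rx + ry * ry);
      return List::create(_["n_steps"] = (double)nsteps, _["remainder"] = rem);
    }
  }
}
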