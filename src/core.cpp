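#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Free path of pedestrian i moving at speed v0 along heading (ex, ey):
// centre travel distance until first body contact with another pedestrian
// (extrapolated linearly at its current velocity) or with a wall circle,
// capped at d_max. Touching while separating does not count as a collision.
static double free_path(const double* P, const double* V, const double* radii,
                        int n, int i, double ex, double ey, double v0,
                        double d_max, double r_in, double r_out,
                        double slack) {
  const double xi = P[2 * i], yi = P[2 * i + 1], ri = radii[i];
  double f = d_max;

  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = P[2 * j] - xi, dy = P[2 * j + 1] - yi;
    // anticipation uses slightly shrunk bodies: pedestrians in contact can
    // still slide past each other by turning their shoulders, which rigid
    // discs cannot represent; without the slack, head-on plugs never melt
    double R = ri + radii[j] - slack;
    if (R < 1e-3) R = 1e-3;
    double c = dx * dx + dy * dy - R * R;
    double ux = V[2 * j] - v0 * ex, uy = V[2 * j + 1] - v0 * ey;
    double b = 2.0 * (dx * ux + dy * uy);
    if (c <= 1e-12) {          // already touching / overlapping
      if (b < 0.0) return 0.0; // and approaching
      continue;                // separating: ignore
    }
    if (b >= 0.0) continue;    // moving apart
    double a = ux * ux + uy * uy;
    if (a <= 1e-16) continue;  // no relative motion
    double disc = b * b - 4.0 * a * c;
    if (disc < 0.0) continue;  // closest approach misses the contact circle
    double t = (-b - std::sqrt(disc)) / (2.0 * a);
    if (t >= 0.0) {
      double fc = v0 * t;
      if (fc < f) f = fc;
    }
  }

  // Walls: centre ray p(s) = x + s e against the contact circles
  // |p| = r_out - ri (outer) and |p| = r_in + ri (inner).
  double xe = xi * ex + yi * ey;
  double r2 = xi * xi + yi * yi;

  double Ro = r_out - ri;
  double co = r2 - Ro * Ro;
  if (co >= -1e-12) {
    if (xe > 0.0) return 0.0;  // touching the outer wall, still heading out
  } else {
    double s = -xe + std::sqrt(xe * xe - co); // exists and is >= 0 from inside
    if (s < f) f = s;
  }

  double Ric = r_in + ri;
  double ci = r2 - Ric * Ric;
  if (ci <= 1e-12) {
    if (xe < 0.0) return 0.0;  // touching the inner wall, heading inward
  } else if (xe < 0.0) {
    double disc = xe * xe - ci;
    if (disc >= 0.0) {
      double s = -xe - std::sqrt(disc);
      if (s >= 0.0 && s < f) f = s;
    }
  }

  return f < d_max ? f : d_max;
}

// [[Rcpp::export]]
double cpp_collision_distance(NumericMatrix pos, NumericMatrix vel,
                              NumericVector radii, int i, double alpha,
                              double v0, double d_max, double r_in,
                              double r_out, double slack) {
  int n = pos.nrow();
  std::vector<double> P(2 * n), V(2 * n);
  for (int j = 0; j < n; ++j) {
    P[2 * j] = pos(j, 0); P[2 * j + 1] = pos(j, 1);
    V[2 * j] = vel(j, 0); V[2 * j + 1] = vel(j, 1);
  }
  return free_path(P.data(), V.data(), radii.begin(), n, i,
                   std::cos(alpha), std::sin(alpha), v0, d_max, r_in, r_out,
                   slack);
}

// Distance-to-destination proxy after travelling f along alpha, destination
// taken d_max away along alpha0 (law of cosines).
static inline double dest_distance(double d_max, double f, double dalpha) {
  double d2 = d_max * d_max + f * f - 2.0 * d_max * f * std::cos(dalpha);
  return d2 > 0.0 ? std::sqrt(d2) : 0.0;
}

// Steering decision for pedestrian i: minimise the distance-to-destination
// proxy over a uniform grid of candidate headings spanning the vision field
// around the looking direction alpha0 (direction toward the destination).
// Ties go to the heading closest to alpha0; exact symmetric ties are broken
// by a coin flip from R's RNG to avoid systematic chirality.
static void steer(const double* P, const double* V, const double* radii,
                  int n, int i, double destx, double desty, double v0,
                  double d_max, double phi, int n_dir, double r_in,
                  double r_out, double slack, double* out_alpha,
                  double* out_dh, double* f_samples, double* alpha_samples) {
  const double xi = P[2 * i], yi = P[2 * i + 1];
  double alpha0 = std::atan2(desty - yi, destx - xi);
  int best = -1;
  double dmin = R_PosInf;
  for (int k = 0; k < n_dir; ++k) {
    double alpha = n_dir == 1 ? alpha0
                              : alpha0 - phi + 2.0 * phi * k / (n_dir - 1);
    double f = free_path(P, V, radii, n, i, std::cos(alpha), std::sin(alpha),
                         v0, d_max, r_in, r_out, slack);
    double d = dest_distance(d_max, f, alpha0 - alpha);
    if (f_samples) f_samples[k] = f;
    if (alpha_samples) alpha_samples[k] = alpha;
    if (best < 0) { best = k; dmin = d; continue; }
    double tol = 1e-9 * (1.0 + dmin);
    if (d < dmin - tol) { best = k; dmin = d; continue; }
    if (std::fabs(d - dmin) <= tol) {
      double devk = std::fabs(alpha - alpha0);
      double devb = std::fabs((n_dir == 1 ? alpha0
                               : alpha0 - phi + 2.0 * phi * best / (n_dir - 1)) - alpha0);
      if (devk < devb - 1e-12) { best = k; dmin = d; }
      else if (std::fabs(devk - devb) <= 1e-12 && unif_rand() < 0.5) {
        best = k; dmin = d;
      }
    }
  }
  double alpha_des = n_dir == 1 ? alpha0
                                : alpha0 - phi + 2.0 * phi * best / (n_dir - 1);
  *out_alpha = alpha_des;
  *out_dh = free_path(P, V, radii, n, i, std::cos(alpha_des),
                      std::sin(alpha_des), v0, d_max, r_in, r_out, slack);
}

// [[Rcpp::export]]
List cpp_desired_direction(NumericMatrix pos, NumericMatrix vel,
                           NumericVector radii, NumericVector dest, int i,
                           double v0, double d_max, double phi, int n_dir,
                           double r_in, double r_out, double slack) {
  int n = pos.nrow();
  std::vector<double> P(2 * n), V(2 * n);
  for (int j = 0; j < n; ++j) {
    P[2 * j] = pos(j, 0); P[2 * j + 1] = pos(j, 1);
    V[2 * j] = vel(j, 0); V[2 * j + 1] = vel(j, 1);
  }
  NumericVector f_samples(n_dir), alpha_samples(n_dir);
  double alpha_des, d_h;
  steer(P.data(), V.data(), radii.begin(), n, i, dest[0], dest[1], v0, d_max,
        phi, n_dir, r_in, r_out, slack, &alpha_des, &d_h, f_samples.begin(),
        alpha_samples.begin());
  double alpha0 = std::atan2(dest[1] - P[2 * i + 1], dest[0] - P[2 * i]);
  return List::create(_["alpha_des"] = alpha_des, _["alpha0"] = alpha0,
                      _["d_h"] = d_h, _["alpha_samples"] = alpha_samples,
                      _["f_samples"] = f_samples);
}

// Sum of body-body and body-wall contact accelerations on pedestrian i.
// Returns true when any positive overlap exists.
static bool contact_force(const double* P, const double* radii, int n, int i,
                          double k, double r_in, double r_out, double* Fx,
                          double* Fy) {
  const double xi = P[2 * i], yi = P[2 * i + 1], ri = radii[i];
  double fx = 0.0, fy = 0.0;
  bool touching = false;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = xi - P[2 * j], dy = yi - P[2 * j + 1];
    double dist = std::sqrt(dx * dx + dy * dy);
    double over = ri + radii[j] - dist;
    if (over > 0.0) {
      if (dist < 1e-9) Rcpp::stop("degenerate state: coincident pedestrian centres");
      touching = true;
      fx += k * over * dx / dist;
      fy += k * over * dy / dist;
    }
  }
  double r = std::sqrt(xi * xi + yi * yi);
  if (r > 1e-12) {
    double over_out = ri - (r_out - r); // overlap with the outer wall
    if (over_out > 0.0) {
      touching = true;
      fx -= k * over_out * xi / r;
      fy -= k * over_out * yi / r;
    }
    double over_in = ri - (r - r_in);   // overlap with the inner wall
    if (over_in > 0.0) {
      touching = true;
      fx += k * over_in * xi / r;
      fy += k * over_in * yi / r;
    }
  }
  *Fx = fx; *Fy = fy;
  return touching;
}

// [[Rcpp::export]]
NumericVector cpp_contact_force(NumericMatrix pos, NumericVector radii, int i,
                                double k, double r_in, double r_out) {
  int n = pos.nrow();
  std::vector<double> P(2 * n);
  for (int j = 0; j < n; ++j) { P[2 * j] = pos(j, 0); P[2 * j + 1] = pos(j, 1); }
  double fx, fy;
  contact_force(P.data(), radii.begin(), n, i, k, r_in, r_out, &fx, &fy);
  return NumericVector::create(fx, fy);
}

// One synchronous Euler step of the full model: steering accelerations are
// computed for every pedestrian from the current state, then velocity and
// position are updated (velocity first, position with the new velocity).
// While a pedestrian overlaps a body or wall, the heuristic steering term is
// replaced by the contact force.
static void step_all(std::vector<double>& P, std::vector<double>& V,
                     const int* dirs, const double* v0, const double* radii,
                     int n, double tau, double phi, double d_max, double k,
                     double d_dest, double dt, int n_dir, double r_in,
                     double r_out, double slack) {
  std::vector<double> A(2 * n);
  for (int i = 0; i < n; ++i) {
    double xi = P[2 * i], yi = P[2 * i + 1];
    double r = std::sqrt(xi * xi + yi * yi);
    if (r < 1e-12) Rcpp::stop("pedestrian at the corridor centre");
    // destination: d_dest away along the tangent in the attributed sense
    double tx = -yi / r * dirs[i], ty = xi / r * dirs[i];
    double destx = xi + d_dest * tx, desty = yi + d_dest * ty;
    double fx, fy;
    contact_force(P.data(), radii, n, i, k, r_in, r_out, &fx, &fy);
    // heuristic steering relaxation plus contact forces; the contact term
    // vanishes without overlap, and the -v/tau relaxation damps the stiff
    // contact spring during collisions
    double alpha_des, d_h;
    steer(P.data(), V.data(), radii, n, i, destx, desty, v0[i], d_max, phi,
          n_dir, r_in, r_out, slack, &alpha_des, &d_h, nullptr, nullptr);
    double v_des = d_h / tau;
    if (v_des > v0[i]) v_des = v0[i];
    A[2 * i] = (v_des * std::cos(alpha_des) - V[2 * i]) / tau + fx;
    A[2 * i + 1] = (v_des * std::sin(alpha_des) - V[2 * i + 1]) / tau + fy;
  }
  for (int i = 0; i < 2 * n; ++i) {
    V[i] += A[i] * dt;
    P[i] += V[i] * dt;
    if (!std::isfinite(P[i]))
      Rcpp::stop("non-finite state after update: integration unstable (dt too large?)");
  }
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix pos, NumericMatrix vel, IntegerVector dirs,
              NumericVector v0, NumericVector radii, double tau, double phi,
              double d_max, double k, double d_dest, double dt, int n_dir,
              double r_in, double r_out, double slack) {
  int n = pos.nrow();
  std::vector<double> P(2 * n), V(2 * n);
  for (int j = 0; j < n; ++j) {
    P[2 * j] = pos(j, 0); P[2 * j + 1] = pos(j, 1);
    V[2 * j] = vel(j, 0); V[2 * j + 1] = vel(j, 1);
  }
  step_all(P, V, dirs.begin(), v0.begin(), radii.begin(), n, tau, phi, d_max,
           k, d_dest, dt, n_dir, r_in, r_out, slack);
  NumericMatrix np(n, 2), nv(n, 2);
  for (int j = 0; j < n; ++j) {
    np(j, 0) = P[2 * j]; np(j, 1) = P[2 * j + 1];
    nv(j, 0) = V[2 * j]; nv(j, 1) = V[2 * j + 1];
  }
  return List::create(_["positions"] = np, _["velocities"] = nv);
}

// [[Rcpp::export]]
NumericVector cpp_simulate(NumericMatrix init_pos, IntegerVector dirs,
                           NumericVector v0, NumericVector radii, double tau,
                           double phi, double d_max, double k, double d_dest,
                           double dt, int n_dir, double r_in, double r_out,
                           double slack, int n_steps, int thin) {
  int n = init_pos.nrow();
  std::vector<double> P(2 * n), V(2 * n, 0.0);
  for (int j = 0; j < n; ++j) {
    P[2 * j] = init_pos(j, 0); P[2 * j + 1] = init_pos(j, 1);
  }
  int n_rec = n_steps / thin + 1;
  NumericVector out(static_cast<R_xlen_t>(n_rec) * n * 2);
  out.attr("dim") = IntegerVector::create(n_rec, n, 2);
  auto record = [&](int rec) {
    for (int j = 0; j < n; ++j) {
      out[rec + (R_xlen_t)n_rec * j] = P[2 * j];
      out[rec + (R_xlen_t)n_rec * (n + j)] = P[2 * j + 1];
    }
  };
  record(0);
  int rec = 1;
  for (int s = 1; s <= n_steps; ++s) {
    step_all(P, V, dirs.begin(), v0.begin(), radii.begin(), n, tau, phi,
             d_max, k, d_dest, dt, n_dir, r_in, r_out, slack);
    if (s % thin == 0) record(rec++);
  }
  return out;
}

// M[i][j] = min over frames s in [t_idx, t_idx + w_frames] of the distance
// between pedestrian j at s and pedestrian i at t_idx (follow relation:
// compare with delta; j follows i when M[i][j] < delta).
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_min_dist(NumericVector pos, int t_idx,
                                    int w_frames) {
  IntegerVector dims = pos.attr("dim");
  int T = dims[0], N = dims[1];
  int t0 = t_idx - 1; // R is 1-based
  if (t0 < 0 || t0 + w_frames >= T)
    stop("look-ahead window exceeds the recording");
  NumericMatrix M(N, N);
  std::fill(M.begin(), M.end(), R_PosInf);
  for (int j = 0; j < N; ++j) {
    for (int s = t0; s <= t0 + w_frames; ++s) {
      double xj = pos[s + (R_xlen_t)T * j];
      double yj = pos[s + (R_xlen_t)T * (N + j)];
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        double dx = xj - pos[t0 + (R_xlen_t)T * i];
        double dy = yj - pos[t0 + (R_xlen_t)T * (N + i)];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < M(i, j)) M(i, j) = d;
      }
    }
  }
  return M;
}

// Local density profile rho(theta) per frame: mean over radial sample points
// of the Gaussian-kernel-weighted pedestrian count
// rho(x) = sum_j exp(-d_jx^2 / R^2) / (pi R^2).
// [[Rcpp::export]]
NumericMatrix cpp_density_map(NumericVector pos, IntegerVector frames,
                              NumericVector theta, NumericVector r_samples,
                              double kernel_R) {
  IntegerVector dims = pos.attr("dim");
  int T = dims[0], N = dims[1];
  int nf = frames.size(), nth = theta.size(), nr = r_samples.size();
  double R2 = kernel_R * kernel_R;
  double norm = 1.0 / (M_PI * R2);
  NumericMatrix out(nf, nth);
  for (int fi = 0; fi < nf; ++fi) {
    int t = frames[fi] - 1;
    if (t < 0 || t >= T) stop("frame index out of range");
    for (int b = 0; b < nth; ++b) {
      double ct = std::cos(theta[b]), st = std::sin(theta[b]);
      double acc = 0.0;
      for (int s = 0; s < nr; ++s) {
        double px = r_samples[s] * ct, py = r_samples[s] * st;
        double rho = 0.0;
        for (int j = 0; j < N; ++j) {
          double dx = pos[t + (R_xlen_t)T * j] - px;
          double dy = pos[t + (R_xlen_t)T * (N + j)] - py;
          rho += std::exp(-(dx * dx + dy * dy) / R2);
        }
        acc += rho * norm;
      }
      out(fi, b) = acc / nr;
    }
  }
  return out;
}
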