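#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation on a periodic-in-xy orthorhombic lattice.
// Values are stored column-major (x fastest).  z is clamped to the grid
// support; callers validate ranges.
struct Field {
  const double *v;
  int nx, ny, nz;
  double ox, oy, oz, hx, hy, hz;

  double at(double x, double y, double z) const {
    double fx = (x - ox) / hx, fy = (y - oy) / hy, fz = (z - oz) / hz;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
        iz = (int)std::floor(fz);
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    // periodic wrap in x and y
    ix %= nx; if (ix < 0) ix += nx;
    iy %= ny; if (iy < 0) iy += ny;
    int ix1 = (ix + 1) % nx, iy1 = (iy + 1) % ny;
    // clamp z
    if (iz < 0) { iz = 0; tz = 0.0; }
    if (iz > nz - 2) { iz = nz - 2; tz = 1.0; }
    int iz1 = iz + 1;
    const double *vv = v;
    auto V = [&](int i, int j, int l) {
      return vv[i + (size_t)nx * (j + (size_t)ny * l)];
    };
    double c00 = V(ix, iy, iz) * (1 - tx) + V(ix1, iy, iz) * tx;
    double c10 = V(ix, iy1, iz) * (1 - tx) + V(ix1, iy1, iz) * tx;
    double c01 = V(ix, iy, iz1) * (1 - tx) + V(ix1, iy, iz1) * tx;
    double c11 = V(ix, iy1, iz1) * (1 - tx) + V(ix1, iy1, iz1) * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    return c0 * (1 - tz) + c1 * tz;
  }
};

static Field make_field(const NumericVector &values,
                        const NumericVector &origin,
                        const NumericVector &spacing) {
  IntegerVector dim = values.attr("dim");
  Field f;
  f.v = REAL(values);
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
  f.ox = origin[0]; f.oy = origin[1]; f.oz = origin[2];
  f.hx = spacing[0]; f.hy = spacing[1]; f.hz = spacing[2];
  return f;
}

// [[Rcpp::export]]
NumericVector interp_trilinear_cpp(NumericVector values,
                                   NumericVector origin,
                                   NumericVector spacing,
                                   NumericMatrix pos) {
  Field f = make_field(values, origin, spacing);
  int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = f.at(pos(i, 0), pos(i, 1), pos(i, 2));
  return out;
}

// Probe relaxation on the lever sphere.  The probe hangs a lever arm
// delta below the pivot; a lateral displacement d = (dx, dy) tilts it by
// theta = asin(|d|/delta), raising the apex by delta*(1 - cos theta) and
// loading the torsional spring with energy 0.5*kappa*(delta*theta)^2
// (kappa already in eV/A^2).  The total energy -- interpolated grid
// energy at the displaced apex plus spring energy -- is minimized by
// damped gradient descent with backtracking (monotone in energy),
// warm-started along the approach.

struct Relaxer {
  const Field &f;
  double x0, y0, delta, kappa, h, rmax;

  Relaxer(const Field &f_, double x0_, double y0_, double delta_,
          double kappa_, double h_, double theta_cap)
      : f(f_), x0(x0_), y0(y0_), delta(delta_), kappa(kappa_), h(h_),
        rmax(delta_ * std::sin(theta_cap)) {}

  double spring(double r) const {
    double th = std::asin(std::min(r / delta, 1.0));
    double s = delta * th;
    return 0.5 * kappa * s * s;
  }

  double probe_z(double z0, double r) const {
    return z0 + delta - std::sqrt(std::max(delta * delta - r * r, 1e-12));
  }

  double energy(double z0, double dx, double dy) const {
    double r = std::sqrt(dx * dx + dy * dy);
    return f.at(x0 + dx, y0 + dy, probe_z(z0, r)) + spring(r);
  }

  // generalized force (negative gradient) wrt (dx, dy)
  void grad(double z0, double dx, double dy, double &gx, double &gy) const {
    double r = std::sqrt(dx * dx + dy * dy);
    double zp = probe_z(z0, r);
    double px = x0 + dx, py = y0 + dy;
    double Ex = (f.at(px + h, py, zp) - f.at(px - h, py, zp)) / (2 * h);
    double Ey = (f.at(px, py + h, zp) - f.at(px, py - h, zp)) / (2 * h);
    double Ez = (f.at(px, py, zp + h) - f.at(px, py, zp - h)) / (2 * h);
    double root = std::sqrt(std::max(delta * delta - r * r, 1e-12));
    double zx = dx / root, zy = dy / root;  // d(probe z)/d(dx,dy)
    double sx, sy;
    if (r < 1e-12) {
      sx = kappa * dx; sy = kappa * dy;
    } else {
      double th = std::asin(std::min(r / delta, 1.0));
      double s = delta * th;
      double costh = std::cos(th);
      double dsp_dr = kappa * s / std::max(costh, 1e-6);
      sx = dsp_dr * dx / r; sy = dsp_dr * dy / r;
    }
    gx = Ex + Ez * zx + sx;
    gy = Ey + Ez * zy + sy;
  }

  // Damped descent with a Barzilai-Borwein trial step and monotone
  // (Armijo-free, strict-decrease) backtracking: accepted moves never
  // increase the energy, and the quasi-Newton step length handles the
  // strongly anisotropic curvature near the repulsion wall.  Returns
  // the final energy; d updated in place.  flag: 0 ok, 1 no
  // convergence, 2 theta cap hit.
  double relax(double z0, double &dx, double &dy, double force_tol,
               int max_iter, int &flag) {
    double fcur = energy(z0, dx, dy);
    double step_max = 4.0 / std::max(kappa, 1e-6), step0 = 1.0 / std::max(kappa, 1e-6);
    double pdx = 0, pdy = 0, pgx = 0, pgy = 0;
    bool have_prev = false, capped = false, converged = false;
    for (int it = 0; it < max_iter; ++it) {
      double gx, gy;
      grad(z0, dx, dy, gx, gy);
      // at the tilt cap the feasible optimum is a boundary minimum:
      // project out the outward-pushing radial component so both the
      // step and the convergence test act on the feasible directions
      double r = std::sqrt(dx * dx + dy * dy);
      if (r >= rmax - 1e-9) {
        capped = true;
        double ux = dx / r, uy = dy / r;
        double gr = gx * ux + gy * uy;
        if (gr < 0) { gx -= gr * ux; gy -= gr * uy; }
      }
      double gn2 = gx * gx + gy * gy;
      double gn = std::sqrt(gn2);
      if (gn < force_tol) { converged = true; break; }
      double step = step0;
      if (have_prev) {
        double sx = dx - pdx, sy = dy - pdy;
        double yx = gx - pgx, yy = gy - pgy;
        double sy_dot = sx * yx + sy * yy, yy_dot = yx * yx + yy * yy;
        if (yy_dot > 1e-30 && sy_dot > 0)
          step = std::min(std::max(sy_dot / yy_dot, 1e-6), step_max);
      }
      step = std::min(step, 0.3 / gn);  // trust cap: 0.3 A moves
      pdx = dx; pdy = dy; pgx = gx; pgy = gy; have_prev = true;
      bool accepted = false;
      for (int bt = 0; bt < 60; ++bt) {
        double ndx = dx - step * gx, ndy = dy - step * gy;
        double nr = std::sqrt(ndx * ndx + ndy * ndy);
        if (nr > rmax) {
          ndx *= rmax / nr; ndy *= rmax / nr; capped = true;
        }
        double fn = energy(z0, ndx, ndy);
        if (fn < fcur || fn <= fcur - 1e-4 * step * gn2) {
          dx = ndx; dy = ndy; fcur = fn;
          accepted = true;
          break;
        }
        step *= 0.5;
        if (step * gn < 1e-14) break;
      }
      if (!accepted) {
        // no feasible decrease left: the descent has reached a (kink)
        // minimum of the piecewise-trilinear energy, where the
        // interpolated gradient need not vanish -- treat as done
        converged = true;
        break;
      }
    }
    flag = converged ? 0 : 1;
    if (capped) flag = 2;
    return fcur;
  }
};

// Relaxed z-scans for a batch of lateral pixel positions.
// z_levels: untilted probe apex heights, ordered far -> near.
// Returns relaxed total energies (n_z x n_pix), lateral displacement
// magnitudes, and per-(z,pixel) status flags.
// [[Rcpp::export]]
List relax_zscan_cpp(NumericVector values, NumericVector origin,
                     NumericVector spacing, NumericMatrix xy,
                     NumericVector z_levels, double delta, double kappa,
                     double force_tol, int max_iter, double theta_cap,
                     double h) {
  Field f = make_field(values, origin, spacing);
  int npix = xy.nrow(), nz = z_levels.size();
  NumericMatrix E(nz, npix), disp(nz, npix), dxm(nz, npix), dym(nz, npix);
  IntegerMatrix flags(nz, npix);
  for (int p = 0; p < npix; ++p) {
    Relaxer rx(f, xy(p, 0), xy(p, 1), delta, kappa, h, theta_cap);
    double dx = 0.0, dy = 0.0;  // theta = 0 at the farthest height
    for (int iz = 0; iz < nz; ++iz) {
      int flag = 0;
      // z_levels holds untilted apex heights: probe_z(z, 0) == z
      E(iz, p) = rx.relax(z_levels[iz], dx, dy, force_tol, max_iter, flag);
      disp(iz, p) = std::sqrt(dx * dx + dy * dy);
      dxm(iz, p) = dx; dym(iz, p) = dy;
      flags(iz, p) = flag;
    }
  }
  return List::create(_["energy"] = E, _["disp"] = disp,
                      _["dx"] = dxm, _["dy"] = dym, _["flags"] = flags);
}
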