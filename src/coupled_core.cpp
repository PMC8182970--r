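// Coupled fluid-structure time loop: implicit Newmark (average acceleration)
// on the free displacement coefficients, driven per step by either the
// Bernoulli glottal pressure with separation ratio or the quasi-steady 1D
// viscous collapsible-tube flow, with contact-plane projection.
//
// Units throughout: mm, ms, mg, kPa, mN (see package documentation).

#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// banded Cholesky (lower band storage: B(d, j) = A(j + d, j), d = 0..kb)

struct BandChol {
  int n = 0, kb = 0;
  arma::mat L;   // (kb + 1) x n

  void factor(const arma::sp_mat& A) {
    n = A.n_rows;
    kb = 0;
    for (arma::sp_mat::const_iterator it = A.begin(); it != A.end(); ++it) {
      int d = (int)it.row() - (int)it.col();
      if (d > kb) kb = d;
    }
    L.zeros(kb + 1, n);
    for (arma::sp_mat::const_iterator it = A.begin(); it != A.end(); ++it) {
      int d = (int)it.row() - (int)it.col();
      if (d >= 0) L(d, it.col()) = *it;
    }
    for (int j = 0; j < n; ++j) {
      int k0 = std::max(0, j - kb);
      for (int k = k0; k < j; ++k) {
        double ljk = L(j - k, k);
        if (ljk == 0.0) continue;
        int imax = std::min(k + kb, n - 1);
        for (int i = j; i <= imax; ++i) L(i - j, j) -= L(i - k, k) * ljk;
      }
      if (L(0, j) <= 0.0) stop("integration error: singular effective operator");
      L(0, j) = std::sqrt(L(0, j));
      double inv = 1.0 / L(0, j);
      for (int d = 1; d <= kb; ++d) L(d, j) *= inv;
    }
  }

  arma::vec solve(const arma::vec& b) const {
    arma::vec y(n);
    for (int j = 0; j < n; ++j) {
      double s = b(j);
      int k0 = std::max(0, j - kb);
      for (int k = k0; k < j; ++k) s -= L(j - k, k) * y(k);
      y(j) = s / L(0, j);
    }
    for (int j = n - 1; j >= 0; --j) {
      double s = y(j);
      int imax = std::min(j + kb, n - 1);
      for (int i = j + 1; i <= imax; ++i) s -= L(i - j, j) * y(i);
      y(j) = s / L(0, j);
    }
    return y;
  }
};

// ---------------------------------------------------------------------------
// flow models on the station grid

struct FlowParams {
  int model = 1;              // 0 none, 1 bernoulli, 2 viscous
  double p_sub = 0, p_sup = 0, r_sep = 1.2;
  double rho_f = 1.14e-3;     // mg/mm^3
  double mu_f = 1.9e-5;       // kPa*ms
  double chi_min = 0.2;
  double a0 = 0.75, a1 = 0.25;  // vena-contracta coefficients
  double shoot_tol = 1e-8;
};

// minimum-area station, ties toward the most superior station
static int min_station(const arma::vec& A) {
  int k = 0;
  for (int i = 1; i < (int)A.n_elem; ++i) if (A(i) <= A(k)) k = i;
  return k;
}

static void closed_pressure(const arma::vec& A, double p_sub, double p_sup,
                            arma::vec& p) {
  int n = A.n_elem, first = -1, last = -1;
  for (int i = 0; i < n; ++i) if (A(i) <= 0) { if (first < 0) first = i; last = i; }
  for (int i = 0; i < n; ++i)
    p(i) = (i < first) ? p_sub : (i > last ? p_sup : 0.0);
}

static bool bernoulli_stations(const arma::vec& A, const FlowParams& fp,
                               arma::vec& p) {
  int n = A.n_elem;
  int kmin = min_station(A);
  if (A(kmin) <= 0) { closed_pressure(A, fp.p_sub, fp.p_sup, p); return true; }
  double A_sep = fp.r_sep * A(kmin);
  int k_sep = n;
  for (int i = kmin + 1; i < n; ++i) if (A(i) >= A_sep) { k_sep = i; break; }
  for (int i = 0; i < n; ++i) {
    if (i >= k_sep) p(i) = fp.p_sup;
    else {
      double r = A_sep / A(i);
      p(i) = fp.p_sub - (fp.p_sub - fp.p_sup) * r * r;
    }
  }
  return false;
}

// quasi-steady viscous solve; returns closed flag, fills p, sets q
static bool viscous_stations(const arma::vec& z, const arma::vec& A0,
                             const arma::vec& S, const FlowParams& fp,
                             arma::vec& p, double& q_out) {
  int n = z.n_elem;
  int kmin = min_station(A0);
  q_out = 0.0;
  if (A0(kmin) <= 0) { closed_pressure(A0, fp.p_sub, fp.p_sup, p); return true; }

  double zin = z(0), zout = z(n - 1);
  arma::vec A(n), fric(n), chi(n);
  for (int i = 0; i < n; ++i) {
    double zz = std::min(std::max(z(i), zin), zout);
    double al = fp.a0 + fp.a1 * (zz - zout) * (zz - zout) /
                ((zin - zout) * (zin - zout));
    A(i) = al * A0(i);
    fric(i) = 2.0 * fp.mu_f * (S(i) / A(i)) * (S(i) / A(i)) / A(i);
    chi(i) = (i <= kmin) ? 1.0 : fp.chi_min;
  }

  double dP = fp.p_sub - fp.p_sup;
  auto outlet = [&](double q) {
    double pz = fp.p_sub;
    for (int i = 1; i < n; ++i) {
      double w1 = q / A(i - 1), w2 = q / A(i);
      double dz = z(i) - z(i - 1);
      pz += -chi(i) * fp.rho_f * (w2 * w2 - w1 * w1) * 0.5
            - q * 0.5 * (fric(i) + fric(i - 1)) * dz;
    }
    return pz;
  };

  double q = 0.0;
  if (dP > fp.shoot_tol) {
    double a_kin = (1.0 - fp.chi_min) / (A(kmin) * A(kmin)) +
                   fp.chi_min / (A(n - 1) * A(n - 1)) - 1.0 / (A(0) * A(0));
    if (a_kin < 1e-12) a_kin = 1e-12;
    double hi = std::sqrt(2.0 * dP / (fp.rho_f * a_kin));
    double fhi = outlet(hi) - fp.p_sup;
    int grow = 0;
    while (fhi > 0 && grow < 60) { hi *= 2.0; fhi = outlet(hi) - fp.p_sup; ++grow; }
    if (fhi > 0) return false;  // caller checks q_out = NaN
    // Illinois regula falsi on [lo, hi]
    double lo = 0.0, flo = dP;
    for (int it = 0; it < 200; ++it) {
      double mid = (flo * hi - fhi * lo) / (flo - fhi);
      if (!std::isfinite(mid) || mid <= lo || mid >= hi) mid = 0.5 * (lo + hi);
      double fm = outlet(mid) - fp.p_sup;
      if (std::abs(fm) < fp.shoot_tol || hi - lo < 1e-15 * hi) { lo = hi = mid; flo = fhi = fm; break; }
      if (fm > 0) { if (flo > 0 && fm > 0) fhi *= 0.5; lo = mid; flo = fm; }
      else        { hi = mid; fhi = fm; }
    }
    q = 0.5 * (lo + hi);
  }
  q_out = q;
  double pz = fp.p_sub;
  p(0) = pz;
  for (int i = 1; i < n; ++i) {
    double w1 = q / A(i - 1), w2 = q / A(i);
    double dz = z(i) - z(i - 1);
    pz += -chi(i) * fp.rho_f * (w2 * w2 - w1 * w1) * 0.5
          - q * 0.5 * (fric(i) + fric(i - 1)) * dz;
    p(i) = pz;
  }
  return false;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(const arma::sp_mat& Kf, const arma::sp_mat& Df,
                  const arma::sp_mat& Mf,
                  const IntegerVector& free_dofs,       // 1-based full-dof ids
                  const NumericMatrix& ref_nodes,       // n x 2
                  const IntegerVector& gamma_f,         // 1-based, ordered
                  double contact_plane, double depth,
                  double z_in, double z_out, int n_stations,
                  const List& flow,
                  double dt, int n_steps, int record_stride,
                  const NumericVector& u0, const NumericVector& v0,
                  const NumericVector& f_ext,
                  double blowup_limit = 50.0) {
  const int nfull = u0.size();
  const int nn = ref_nodes.nrow();
  const int nf = free_dofs.size();

  FlowParams fp;
  fp.model = as<int>(flow["model"]);
  fp.p_sub = as<double>(flow["p_sub"]);
  fp.p_sup = as<double>(flow["p_sup"]);
  if (flow.containsElementNamed("r_sep")) fp.r_sep = as<double>(flow["r_sep"]);
  if (flow.containsElementNamed("rho_f")) fp.rho_f = as<double>(flow["rho_f"]) * 1e-3;
  if (flow.containsElementNamed("mu_f")) fp.mu_f = as<double>(flow["mu_f"]);
  if (flow.containsElementNamed("chi_min")) fp.chi_min = as<double>(flow["chi_min"]);
  if (flow.containsElementNamed("alpha_coef")) {
    NumericVector ac = flow["alpha_coef"];
    fp.a0 = ac[0]; fp.a1 = ac[1];
  }

  // maps: full dof -> free position (-1 if constrained)
  std::vector<int> fpos(nfull, -1);
  for (int i = 0; i < nf; ++i) fpos[free_dofs[i] - 1] = i;

  const double beta = 0.25, gamma = 0.5;
  const double b1 = 1.0 / (beta * dt * dt), b2 = 1.0 / (beta * dt),
               b3 = (1.0 - 2.0 * beta) / (2.0 * beta);
  const double c1 = gamma / (beta * dt), c2 = gamma / beta - 1.0,
               c3 = dt * (gamma / (2.0 * beta) - 1.0);

  BandChol keff, mchol;
  {
    arma::sp_mat Keff = Kf + c1 * Df + b1 * Mf;
    keff.factor(Keff);
    mchol.factor(Mf);
  }

  arma::vec u(nf), v(nf), fe(nf);
  for (int i = 0; i < nf; ++i) {
    u(i) = u0[free_dofs[i] - 1];
    v(i) = v0[free_dofs[i] - 1];
    fe(i) = f_ext[free_dofs[i] - 1];
  }

  // surface bookkeeping
  const int ng = gamma_f.size();
  std::vector<int> gxf(ng), gzf(ng);   // free positions of surface dofs (-1 fixed)
  arma::vec grefx(ng), grefz(ng);
  for (int i = 0; i < ng; ++i) {
    int nd = gamma_f[i] - 1;
    gxf[i] = fpos[2 * nd];
    gzf[i] = fpos[2 * nd + 1];
    grefx(i) = ref_nodes(nd, 0);
    grefz(i) = ref_nodes(nd, 1);
  }
  // contact candidates: any node with a free x dof
  std::vector<int> cand_node, cand_x;
  for (int nd = 0; nd < nn; ++nd)
    if (fpos[2 * nd] >= 0) { cand_node.push_back(nd); cand_x.push_back(fpos[2 * nd]); }

  arma::vec zst(n_stations), gaps(n_stations), areas(n_stations),
            Sst(n_stations, arma::fill::value(2.0 * depth)), pst(n_stations);
  for (int i = 0; i < n_stations; ++i)
    zst(i) = z_in + (z_out - z_in) * i / (n_stations - 1.0);

  arma::vec gx(ng), gz(ng), gp(ng);

  int status = 0; std::string message = "";
  double q_last = 0.0;

  // surface geometry + station gaps from current u
  auto update_surface = [&]() -> bool {
    for (int i = 0; i < ng; ++i) {
      gx(i) = grefx(i) + (gxf[i] >= 0 ? u(gxf[i]) : 0.0);
      gz(i) = grefz(i) + (gzf[i] >= 0 ? u(gzf[i]) : 0.0);
    }
    for (int i = 1; i < ng; ++i)
      if (gz(i) <= gz(i - 1) &&
          gz(i - 1) >= z_in - 1.0 && gz(i) <= z_out + 1.0) return false;
    int j = 0;
    for (int i = 0; i < n_stations; ++i) {
      double z = zst(i);
      while (j < ng - 2 && gz(j + 1) < z) ++j;
      double xs;
      if (z <= gz(0)) xs = gx(0);
      else if (z >= gz(ng - 1)) xs = gx(ng - 1);
      else {
        int k = j;
        while (k < ng - 1 && gz(k + 1) < z) ++k;
        double s = (z - gz(k)) / (gz(k + 1) - gz(k));
        xs = gx(k) + s * (gx(k + 1) - gx(k));
      }
      double g = contact_plane - xs;
      gaps(i) = g > 0 ? g : 0.0;
      areas(i) = gaps(i) * depth;
    }
    return true;
  };

  // exact minimum gap of the piecewise-linear surface within the channel
  // window: attained at a surface node or at an interpolated window end
  auto min_gap = [&]() -> double {
    double g = std::min(gaps(0), gaps(n_stations - 1));
    for (int i = 0; i < ng; ++i)
      if (gz(i) >= z_in && gz(i) <= z_out) {
        double gi = contact_plane - gx(i);
        if (gi < g) g = gi;
      }
    return g > 0 ? g : 0.0;
  };

  // station pressures -> nodal pressures -> consistent surface forces
  arma::vec F(nf);
  auto compute_forces = [&]() {
    F = fe;
    if (fp.model == 0) return;
    const double dzs = (z_out - z_in) / (n_stations - 1.0);
    for (int i = 0; i < ng; ++i) {
      double z = gz(i);
      if (z <= z_in) gp(i) = fp.p_sub;
      else if (z >= z_out) gp(i) = fp.p_sup;
      else {
        double s = (z - z_in) / dzs;
        int k = (int)std::floor(s);
        if (k >= n_stations - 1) k = n_stations - 2;
        double f = s - k;
        gp(i) = pst(k) * (1.0 - f) + pst(k + 1) * f;
      }
    }
    // closed glottis: the subglottal column below the first contact sees
    // p_sub; gp interpolation above already handles it via pst assignment
    for (int e = 0; e < ng - 1; ++e) {
      double ex = gx(e + 1) - gx(e), ezl = gz(e + 1) - gz(e);
      double len = std::sqrt(ex * ex + ezl * ezl);
      if (len <= 0) continue;
      // outward normal of the solid (domain lies on the -x side of the chain)
      double nx = ezl / len, nz = -ex / len;
      double pa = gp(e), pb = gp(e + 1);
      double wa = len * depth * (pa / 3.0 + pb / 6.0);
      double wb = len * depth * (pa / 6.0 + pb / 3.0);
      if (gxf[e] >= 0)     F(gxf[e])     -= wa * nx;
      if (gzf[e] >= 0)     F(gzf[e])     -= wa * nz;
      if (gxf[e + 1] >= 0) F(gxf[e + 1]) -= wb * nx;
      if (gzf[e + 1] >= 0) F(gzf[e + 1]) -= wb * nz;
    }
  };

  auto station_pressures = [&]() -> bool {
    if (fp.model == 1) { bernoulli_stations(areas, fp, pst); return true; }
    if (fp.model == 2) {
      double q;
      bool closed = viscous_stations(zst, areas, Sst, fp, pst, q);
      (void)closed;
      if (!std::isfinite(q)) return false;
      q_last = q;
      return true;
    }
    return true;
  };

  if (!update_surface()) {
    return List::create(_["status"] = 2, _["message"] = "channel fold-over at t=0");
  }
  if (!station_pressures()) {
    return List::create(_["status"] = 3, _["message"] = "flow solve failed at t=0");
  }
  compute_forces();

  // consistent initial acceleration: M a0 = F - D v - K u
  arma::vec a = mchol.solve(F - Df * v - Kf * u);

  const int nrec = n_steps / record_stride + 1;
  NumericVector times(nrec), width(nrec);
  times[0] = 0.0;
  width[0] = min_gap();

  // energy audit
  double E0 = 0.5 * arma::dot(u, Kf * u) + 0.5 * arma::dot(v, Mf * v);
  double W_fluid = 0.0, Diss = 0.0, C_loss = 0.0;

  int rec = 1;
  arma::vec rhs(nf), unew(nf), anew(nf), vnew(nf);
  // Discrete energy identity of the average-acceleration step with
  // start-of-step equilibrium residual r:  dE = F.du - dt vm.D.vm - 0.5 du.r.
  // r = dF between steps (trapezoid work correction, booked into W_fluid) or
  // the post-projection inconsistency (booked into the contact loss).
  arma::vec r_prev(nf, arma::fill::zeros);
  bool touched_prev = false;
  for (int step = 1; step <= n_steps; ++step) {
    rhs = F + Mf * (b1 * u + b2 * v + b3 * a) + Df * (c1 * u + c2 * v + c3 * a);
    unew = keff.solve(rhs);
    anew = b1 * (unew - u) - b2 * v - b3 * a;
    vnew = v + dt * ((1.0 - gamma) * a + gamma * anew);

    double quad = 0.5 * arma::dot(unew - u, r_prev);
    W_fluid += arma::dot(F, unew - u);
    if (touched_prev) C_loss += quad; else W_fluid -= quad;
    {
      arma::vec vm = 0.5 * (v + vnew);
      Diss += dt * arma::dot(vm, Df * vm);
    }

    // contact projection (energy removed by the projection is logged)
    bool touched = false;
    double e_before = 0.0;
    for (size_t ci = 0; ci < cand_node.size(); ++ci) {
      int nd = cand_node[ci], ix = cand_x[ci];
      double defx = ref_nodes(nd, 0) + unew(ix);
      if (defx > contact_plane) {
        if (!touched) {
          e_before = 0.5 * arma::dot(unew, Kf * unew) +
                     0.5 * arma::dot(vnew, Mf * vnew);
          touched = true;
        }
        unew(ix) = contact_plane - ref_nodes(nd, 0);
        vnew(ix) = 0.0;
        anew(ix) = 0.0;
      }
    }
    if (touched) {
      double e_after = 0.5 * arma::dot(unew, Kf * unew) +
                       0.5 * arma::dot(vnew, Mf * vnew);
      C_loss += e_before - e_after;
    }
    u = unew; v = vnew; a = anew;

    if (!u.is_finite() || arma::abs(u).max() > blowup_limit) {
      status = 1;
      message = "simulation blow-up at step " + std::to_string(step);
      break;
    }
    if (!update_surface()) {
      status = 2;
      message = "channel fold-over at step " + std::to_string(step);
      break;
    }
    if (!station_pressures()) {
      status = 3;
      message = "flow solve failed at step " + std::to_string(step);
      break;
    }
    arma::vec F_old = F;
    compute_forces();
    if (touched) r_prev = F - (Mf * a + Df * v + Kf * u);
    else r_prev = F - F_old;   // pure load change: equilibrium held wrt F_old
    touched_prev = touched;

    if (step % record_stride == 0 && rec < nrec) {
      times[rec] = step * dt;
      width[rec] = min_gap();
      ++rec;
    }
  }

  double E1 = 0.5 * arma::dot(u, Kf * u) + 0.5 * arma::dot(v, Mf * v);

  NumericVector uf(nfull), vf(nfull), af(nfull);
  for (int i = 0; i < nf; ++i) {
    uf[free_dofs[i] - 1] = u(i);
    vf[free_dofs[i] - 1] = v(i);
    af[free_dofs[i] - 1] = a(i);
  }

  return List::create(
    _["status"] = status, _["message"] = message,
    _["times"] = times, _["width"] = width, _["n_recorded"] = rec,
    _["u"] = uf, _["v"] = vf, _["a"] = af,
    _["q_last"] = q_last,
    _["energy"] = List::create(_["e_start"] = E0, _["e_end"] = E1,
                               _["work_fluid"] = W_fluid,
                               _["dissipation"] = Diss,
                               _["contact_loss"] = C_loss));
}

// station-grid viscous solver exposed for cross-checking the R implementation
// [[Rcpp::export]]
List cpp_viscous_profile(const NumericVector& z, const NumericVector& area,
                         const NumericVector& perimeter,
                         double p_sub, double p_sup, const List& flow) {
  FlowParams fp;
  fp.model = 2;
  fp.p_sub = p_sub; fp.p_sup = p_sup;
  fp.rho_f = as<double>(flow["rho_f"]) * 1e-3;
  fp.mu_f = as<double>(flow["mu_f"]);
  fp.chi_min = as<double>(flow["chi_min"]);
  NumericVector ac = flow["alpha_coef"];
  fp.a0 = ac[0]; fp.a1 = ac[1];
  arma::vec zv = as<arma::vec>(z), av = as<arma::vec>(area),
            sv = as<arma::vec>(perimeter), p(z.size());
  double q;
  bool closed = viscous_stations(zv, av, sv, fp, p, q);
  return List::create(_["p"] = p, _["q"] = q, _["closed"] = closed);
}
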