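#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Agent kinds (must match R-side encoding)
#define KIND_DROPLET  0
#define KIND_NUCLEOLUS 1
#define KIND_OBSTACLE 2

// --- linked-cell grid over the nucleus --------------------------------------
// Cell size h is chosen by the caller; indices clamped to the box [-L, L]^3.
struct CellGrid {
  double L, h;
  int nc;                      // cells per dimension
  std::vector<int> head;       // nc^3 heads, -1 = empty
  std::vector<int> nxt;        // per-agent chain

  void init(double L_, double h_, int n) {
    L = L_; h = h_;
    nc = std::max(1, (int)std::floor(2.0 * L / h));
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(n, -1);
  }
  inline int coord(double v) const {
    int c = (int)std::floor((v + L) / (2.0 * L) * nc);
    if (c < 0) c = 0;
    if (c >= nc) c = nc - 1;
    return c;
  }
  inline int idx(int cx, int cy, int cz) const {
    return (cx * nc + cy) * nc + cz;
  }
  inline void insert(int i, double x, double y, double z) {
    int c = idx(coord(x), coord(y), coord(z));
    nxt[i] = head[c];
    head[c] = i;
  }
};

// Contact pairs (center distance <= r_i + r_j) via a linked-cell grid.
// Exposed so collision detection can be cross-checked against the all-pairs
// oracle in tests.  Returns a 2-column matrix of 1-based index pairs, i < j.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, NumericVector rad) {
  int n = pos.nrow();
  std::vector<int> ia, ja;
  if (n >= 2) {
    double rmax = 0.0, L = 1e-9;
    for (int i = 0; i < n; i++) {
      rmax = std::max(rmax, rad[i]);
      L = std::max(L, std::max(std::fabs(pos(i,0)),
            std::max(std::fabs(pos(i,1)), std::fabs(pos(i,2)))));
    }
    double h = std::max(2.0 * rmax, 1e-6);
    CellGrid g;
    g.init(L + rmax + 1e-9, h, n);
    for (int i = 0; i < n; i++) g.insert(i, pos(i,0), pos(i,1), pos(i,2));
    for (int i = 0; i < n; i++) {
      int cx = g.coord(pos(i,0)), cy = g.coord(pos(i,1)), cz = g.coord(pos(i,2));
      for (int ax = std::max(0,cx-1); ax <= std::min(g.nc-1,cx+1); ax++)
      for (int ay = std::max(0,cy-1); ay <= std::min(g.nc-1,cy+1); ay++)
      for (int az = std::max(0,cz-1); az <= std::min(g.nc-1,cz+1); az++) {
        for (int j = g.head[g.idx(ax,ay,az)]; j != -1; j = g.nxt[j]) {
          if (j <= i) continue;
          double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1),
                 dz = pos(i,2)-pos(j,2);
          double s = rad[i] + rad[j];
          if (dx*dx + dy*dy + dz*dz <= s*s) { ia.push_back(i+1); ja.push_back(j+1); }
        }
      }
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); k++) { out(k,0) = ia[k]; out(k,1) = ja[k]; }
  return out;
}

// --- main integrator ---------------------------------------------------------
// Overdamped dynamics: drift F*dt/eta with eta_i = (r_i/r_ref)*f_i, plus an
// isotropic Gaussian increment with per-axis variance 2*D_i*dt where
// D_i = D_base * (r_ref/r_i) / f_i.  Linear overlap penalties; each per-pair
// (and membrane) drift contribution is capped at the current overlap so an
// agent is never pushed past the point of contact in one step.
//
// Droplet pairs exert no force: they coalesce (deepest overlap first) at the
// end of each step, conserving volume.  Anchored obstacles follow the
// nucleolus at a fixed offset plus a capped Ornstein-Uhlenbeck tether
// fluctuation; they exert forces but do not respond to them.
//
// Uses R's RNG (seed via set.seed before calling).
// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix pos0, NumericVector rad0, IntegerVector kind0,
                 NumericVector fric0, LogicalVector anch0, NumericMatrix aoff0,
                 NumericMatrix teth0, IntegerVector id0,
                 double R, double t0, double dt, double t_end,
                 double D_base, double ref_radius,
                 double k_confine, double k_soft, double k_hard,
                 double tether_theta, double tether_sigma, double tether_cap,
                 double sample_dt, int stop_at_count, int next_id,
                 bool forces_on, bool coalesce_on, bool record_tracks,
                 double drift_cap, bool droplet_repel) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), r(n), f(n);
  std::vector<double> ax(n), ay(n), az(n), tx(n), ty(n), tz(n);
  std::vector<int> kind(n), id(n);
  std::vector<char> anch(n), alive(n, 1);
  int nucleo = -1;
  for (int i = 0; i < n; i++) {
    x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2);
    r[i] = rad0[i]; f[i] = fric0[i]; kind[i] = kind0[i]; id[i] = id0[i];
    anch[i] = anch0[i] ? 1 : 0;
    ax[i] = aoff0(i,0); ay[i] = aoff0(i,1); az[i] = aoff0(i,2);
    tx[i] = teth0(i,0); ty[i] = teth0(i,1); tz[i] = teth0(i,2);
    if (kind[i] == KIND_NUCLEOLUS) nucleo = i;
  }
  if (dt <= 0) stop("dt must be positive");
  long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 0) stop("t_end must be >= t0");
  long sample_every = std::max(1L, (long)std::llround(sample_dt / dt));

  std::vector<double> dx(n), dy(n), dz(n);
  std::vector<int> droplets;  // indices of alive droplets (refreshed per step)
  droplets.reserve(n);

  // samples
  std::vector<double> s_t, s_mr;
  std::vector<int> s_n;
  // event log
  std::vector<double> ev_t, ev_r;
  std::vector<int> ev_a, ev_b, ev_m;
  // optional droplet tracks (only meaningful while no coalescence occurs):
  // positions of the initial droplet slots at each sample time
  std::vector<int> track_slots;
  std::vector<double> trk;  // row-major [sample][slot][xyz]
  if (record_tracks)
    for (int i = 0; i < n; i++)
      if (kind[i] == KIND_DROPLET) track_slots.push_back(i);

  double rmax_obs = 0.0;  // obstacle radii are fixed for the whole run
  for (int i = 0; i < n; i++)
    if (kind[i] == KIND_OBSTACLE) rmax_obs = std::max(rmax_obs, r[i]);

  // cell-sorted obstacle arrays: cell size 2*rmax so obstacle-obstacle
  // contacts are always within the 27-cell neighbourhood
  double h = std::max(rmax_obs > 0 ? 2.0 * rmax_obs : 1.0, 0.75);
  double L = R + rmax_obs + 1.0;
  int nc = std::max(1, (int)std::floor(2.0 * L / h));
  int ncells = nc * nc * nc;
  std::vector<int> cellOf, cellStart(ncells + 1), order;
  std::vector<double> ox, oy, oz, orad;
  std::vector<int> oslot;
  std::vector<char> oanch;
  auto coord = [&](double v) {
    int c = (int)std::floor((v + L) / (2.0 * L) * nc);
    return c < 0 ? 0 : (c >= nc ? nc - 1 : c);
  };
  auto cidx = [&](int cx, int cy, int cz) { return (cx * nc + cy) * nc + cz; };

  auto count_droplets = [&](void) {
    int c = 0;
    for (int i = 0; i < n; i++) if (alive[i] && kind[i] == KIND_DROPLET) c++;
    return c;
  };
  auto mean_drop_radius = [&](void) {
    double s = 0; int c = 0;
    for (int i = 0; i < n; i++)
      if (alive[i] && kind[i] == KIND_DROPLET) { s += r[i]; c++; }
    return c ? s / c : NA_REAL;
  };
  auto take_sample = [&](double t) {
    s_t.push_back(t); s_n.push_back(count_droplets());
    s_mr.push_back(mean_drop_radius());
    if (record_tracks)
      for (size_t k = 0; k < track_slots.size(); k++) {
        int i = track_slots[k];
        trk.push_back(x[i]); trk.push_back(y[i]); trk.push_back(z[i]);
      }
  };
  take_sample(t0);

  double tcur = t0;
  bool stopped = false;
  for (long s = 0; s < nsteps && !stopped; s++) {
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);
    droplets.clear();
    for (int i = 0; i < n; i++)
      if (alive[i] && kind[i] == KIND_DROPLET) droplets.push_back(i);

    if (forces_on) {
      // counting-sort alive obstacles into cells (contiguous per-cell ranges)
      int m = 0;
      for (int i = 0; i < n; i++)
        if (alive[i] && kind[i] == KIND_OBSTACLE) m++;
      cellOf.resize(m); order.resize(m);
      ox.resize(m); oy.resize(m); oz.resize(m); orad.resize(m);
      oslot.resize(m); oanch.resize(m);
      {
        std::vector<int> tmp_idx(m);
        int k = 0;
        std::fill(cellStart.begin(), cellStart.end(), 0);
        for (int i = 0; i < n; i++) {
          if (!alive[i] || kind[i] != KIND_OBSTACLE) continue;
          int c = cidx(coord(x[i]), coord(y[i]), coord(z[i]));
          cellOf[k] = c; tmp_idx[k] = i; k++;
          cellStart[c + 1]++;
        }
        for (int c = 0; c < ncells; c++) cellStart[c + 1] += cellStart[c];
        std::vector<int> fill = cellStart;
        for (int k2 = 0; k2 < m; k2++) {
          int p = fill[cellOf[k2]]++;
          int i = tmp_idx[k2];
          ox[p] = x[i]; oy[p] = y[i]; oz[p] = z[i]; orad[p] = r[i];
          oslot[p] = i; oanch[p] = anch[i];
        }
      }

      // pair displacement (capped at overlap); applied along the center line
      auto add_pair = [&](int i, int j) {
        double ddx = x[i]-x[j], ddy = y[i]-y[j], ddz = z[i]-z[j];
        double sum = r[i] + r[j];
        double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
        if (d2 >= sum*sum) return;
        double dist = std::sqrt(d2);
        double nx_, ny_, nz_;
        if (dist < 1e-12) {
          // coincident centers: deterministic axis from the lower agent id
          int lo = std::min(id[i], id[j]);
          nx_ = ny_ = nz_ = 0.0;
          if (lo % 3 == 0) nx_ = 1.0; else if (lo % 3 == 1) ny_ = 1.0; else nz_ = 1.0;
          if (id[i] > id[j]) { nx_ = -nx_; ny_ = -ny_; nz_ = -nz_; }
        } else {
          nx_ = ddx/dist; ny_ = ddy/dist; nz_ = ddz/dist;
        }
        double overlap = sum - dist;
        double k = (kind[i] == KIND_DROPLET || kind[j] == KIND_DROPLET)
                     ? k_soft : k_hard;
        if (!anch[i]) {
          double eta = (r[i]/ref_radius) * f[i];
          double u = std::min(k * overlap * dt / eta, overlap);
          dx[i] += u*nx_; dy[i] += u*ny_; dz[i] += u*nz_;
        }
        if (!anch[j]) {
          double eta = (r[j]/ref_radius) * f[j];
          double u = std::min(k * overlap * dt / eta, overlap);
          dx[j] -= u*nx_; dy[j] -= u*ny_; dz[j] -= u*nz_;
        }
      };

      // obstacle-obstacle: 14-cell half stencil over the sorted cell ranges
      // (skip pairs where both are anchored)
      static const int STEN[14][3] = {
        {0,0,0}, {1,0,0}, {0,1,0}, {0,0,1}, {1,1,0}, {1,-1,0}, {1,0,1},
        {1,0,-1}, {0,1,1}, {0,1,-1}, {1,1,1}, {1,1,-1}, {1,-1,1}, {1,-1,-1}};
      for (int cx = 0; cx < nc; cx++)
      for (int cy = 0; cy < nc; cy++)
      for (int cz = 0; cz < nc; cz++) {
        int c1 = cidx(cx, cy, cz);
        int a0 = cellStart[c1], a1 = cellStart[c1 + 1];
        if (a0 == a1) continue;
        for (int sten = 0; sten < 14; sten++) {
          int bx = cx + STEN[sten][0], by = cy + STEN[sten][1],
              bz = cz + STEN[sten][2];
          if (bx < 0 || by < 0 || bz < 0 || bx >= nc || by >= nc || bz >= nc)
            continue;
          int c2 = cidx(bx, by, bz);
          int b0 = cellStart[c2], b1 = cellStart[c2 + 1];
          bool same = (sten == 0);
          for (int a = a0; a < a1; a++) {
            double xa = ox[a], ya = oy[a], za = oz[a], ra = orad[a];
            char an_a = oanch[a];
            for (int b = same ? a + 1 : b0; b < b1; b++) {
              if (an_a && oanch[b]) continue;
              double ddx = xa - ox[b], ddy = ya - oy[b], ddz = za - oz[b];
              double s2 = ra + orad[b];
              if (ddx*ddx + ddy*ddy + ddz*ddz < s2*s2)
                add_pair(oslot[a], oslot[b]);
            }
          }
        }
      }
      // droplet-obstacle via the sorted cells
      for (size_t di = 0; di < droplets.size(); di++) {
        int i = droplets[di];
        int cx = coord(x[i]), cy = coord(y[i]), cz = coord(z[i]);
        int w = std::max(1, (int)std::ceil((r[i] + rmax_obs) / h));
        for (int axc = std::max(0,cx-w); axc <= std::min(nc-1,cx+w); axc++)
        for (int ayc = std::max(0,cy-w); ayc <= std::min(nc-1,cy+w); ayc++)
        for (int azc = std::max(0,cz-w); azc <= std::min(nc-1,cz+w); azc++) {
          int c2 = cidx(axc, ayc, azc);
          for (int b = cellStart[c2]; b < cellStart[c2 + 1]; b++) {
            double ddx = x[i] - ox[b], ddy = y[i] - oy[b], ddz = z[i] - oz[b];
            double s2 = r[i] + orad[b];
            if (ddx*ddx + ddy*ddy + ddz*ddz < s2*s2) add_pair(i, oslot[b]);
          }
        }
      }
      // droplet-droplet soft repulsion (initialisation relaxation mode only;
      // during dynamics droplet contacts coalesce instead)
      if (droplet_repel) {
        for (size_t a = 0; a < droplets.size(); a++)
          for (size_t b = a + 1; b < droplets.size(); b++)
            add_pair(droplets[a], droplets[b]);
      }
      // nucleolus against everything
      if (nucleo >= 0 && alive[nucleo]) {
        for (int j = 0; j < n; j++)
          if (alive[j] && j != nucleo) add_pair(nucleo, j);
      }
      // membrane confinement (free agents; anchored ones follow the nucleolus)
      for (int i = 0; i < n; i++) {
        if (!alive[i] || anch[i]) continue;
        double dn = std::sqrt(x[i]*x[i] + y[i]*y[i] + z[i]*z[i]);
        double over = dn + r[i] - R;
        if (over > 0 && dn > 1e-12) {
          double eta = (r[i]/ref_radius) * f[i];
          double u = std::min(k_confine * over * dt / eta, over);
          dx[i] -= u * x[i]/dn; dy[i] -= u * y[i]/dn; dz[i] -= u * z[i]/dn;
        }
      }
    }

    // Brownian increment + position update for free agents.  The total
    // deterministic drift per step is capped (overlap resolution speed
    // limit); the cap only binds under extreme transient crowding.
    double R2 = R * R;
    for (int i = 0; i < n; i++) {
      if (!alive[i] || anch[i]) continue;
      double dm2 = dx[i]*dx[i] + dy[i]*dy[i] + dz[i]*dz[i];
      if (dm2 > drift_cap * drift_cap) {
        double sc = drift_cap / std::sqrt(dm2);
        dx[i] *= sc; dy[i] *= sc; dz[i] *= sc;
      }
      double D = D_base * (ref_radius / r[i]) / f[i];
      if (D > 0) {
        double sg = std::sqrt(2.0 * D * dt);
        dx[i] += sg * norm_rand();
        dy[i] += sg * norm_rand();
        dz[i] += sg * norm_rand();
      }
      double m2 = dx[i]*dx[i] + dy[i]*dy[i] + dz[i]*dz[i];
      if (m2 > R2)
        stop("step displacement exceeds the nucleus radius; reduce dt");
      x[i] += dx[i]; y[i] += dy[i]; z[i] += dz[i];
    }
    // anchored obstacles ride on the nucleolus with a capped OU tether
    if (nucleo >= 0) {
      double sg = tether_sigma * std::sqrt(dt);
      for (int i = 0; i < n; i++) {
        if (!alive[i] || !anch[i]) continue;
        tx[i] += -tether_theta * tx[i] * dt + sg * norm_rand();
        ty[i] += -tether_theta * ty[i] * dt + sg * norm_rand();
        tz[i] += -tether_theta * tz[i] * dt + sg * norm_rand();
        double m = std::sqrt(tx[i]*tx[i] + ty[i]*ty[i] + tz[i]*tz[i]);
        if (m > tether_cap && m > 0) {
          double sc = tether_cap / m;
          tx[i] *= sc; ty[i] *= sc; tz[i] *= sc;
        }
        x[i] = x[nucleo] + ax[i] + tx[i];
        y[i] = y[nucleo] + ay[i] + ty[i];
        z[i] = z[nucleo] + az[i] + tz[i];
      }
    }
    tcur = t0 + (s + 1) * dt;

    // iterated coalescence: merge the deepest-overlap droplet pair first
    if (coalesce_on) {
      bool merged_any = true;
      while (merged_any) {
        merged_any = false;
        droplets.clear();
        for (int i = 0; i < n; i++)
          if (alive[i] && kind[i] == KIND_DROPLET) droplets.push_back(i);
        int bi = -1, bj = -1;
        double best = -1.0;
        for (size_t a = 0; a < droplets.size(); a++)
          for (size_t b = a + 1; b < droplets.size(); b++) {
            int i = droplets[a], j = droplets[b];
            double ddx = x[i]-x[j], ddy = y[i]-y[j], ddz = z[i]-z[j];
            double sum = r[i] + r[j];
            double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (d2 <= sum*sum) {
              double ov = sum - std::sqrt(d2);
              if (ov > best) { best = ov; bi = i; bj = j; }
            }
          }
        if (bi >= 0) {
          double va = r[bi]*r[bi]*r[bi], vb = r[bj]*r[bj]*r[bj];
          double v = va + vb;
          double nxp = (va*x[bi] + vb*x[bj]) / v;
          double nyp = (va*y[bi] + vb*y[bj]) / v;
          double nzp = (va*z[bi] + vb*z[bj]) / v;
          ev_t.push_back(tcur);
          ev_a.push_back(id[bi]); ev_b.push_back(id[bj]);
          ev_m.push_back(next_id); ev_r.push_back(std::cbrt(v));
          x[bi] = nxp; y[bi] = nyp; z[bi] = nzp;
          r[bi] = std::cbrt(v);
          id[bi] = next_id++;
          alive[bj] = 0;
          merged_any = true;
        }
      }
    }

    if ((s + 1) % sample_every == 0 || s == nsteps - 1) take_sample(tcur);
    if (stop_at_count > 0 && count_droplets() <= stop_at_count) {
      if ((s + 1) % sample_every != 0 && s != nsteps - 1) take_sample(tcur);
      stopped = true;
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  // compact alive agents
  int m = 0;
  for (int i = 0; i < n; i++) if (alive[i]) m++;
  NumericMatrix pos(m, 3), aoff(m, 3), teth(m, 3);
  NumericVector rad(m), fric(m);
  IntegerVector kd(m), ids(m);
  LogicalVector an(m);
  for (int i = 0, k = 0; i < n; i++) {
    if (!alive[i]) continue;
    pos(k,0) = x[i]; pos(k,1) = y[i]; pos(k,2) = z[i];
    aoff(k,0) = ax[i]; aoff(k,1) = ay[i]; aoff(k,2) = az[i];
    teth(k,0) = tx[i]; teth(k,1) = ty[i]; teth(k,2) = tz[i];
    rad[k] = r[i]; fric[k] = f[i]; kd[k] = kind[i]; ids[k] = id[i];
    an[k] = anch[i] == 1;
    k++;
  }
  List samples = List::create(
    _["t"] = NumericVector(s_t.begin(), s_t.end()),
    _["n_droplets"] = IntegerVector(s_n.begin(), s_n.end()),
    _["mean_radius"] = NumericVector(s_mr.begin(), s_mr.end()));
  List events = List::create(
    _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["id_a"] = IntegerVector(ev_a.begin(), ev_a.end()),
    _["id_b"] = IntegerVector(ev_b.begin(), ev_b.end()),
    _["merged_id"] = IntegerVector(ev_m.begin(), ev_m.end()),
    _["merged_radius"] = NumericVector(ev_r.begin(), ev_r.end()));
  List out = List::create(
    _["pos"] = pos, _["radius"] = rad, _["kind"] = kd, _["friction"] = fric,
    _["anchored"] = an, _["anchor_offset"] = aoff, _["tether"] = teth,
    _["id"] = ids, _["t"] = tcur, _["samples"] = samples,
    _["events"] = events, _["next_id"] = next_id, _["stopped"] = stopped);
  if (record_tracks) {
    int ns = (int)s_t.size(), nk = (int)track_slots.size();
    NumericVector tr(trk.begin(), trk.end());
    tr.attr("dim") = IntegerVector::create(3, nk, ns);
    out["tracks"] = tr;
  }
  return out;
}
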