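#include <Rcpp.h>
using namespace Rcpp;

// 3D lattice helpers ---------------------------------------------------------
// Sites are 1-based linear indices into an nx*ny*nz array (column-major,
// x fastest), matching R's array indexing.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z); // 0-based
}

// Explicit 7-point diffusion with zero-flux (Neumann) boundaries, written in
// flux form so total mass is conserved exactly when decay = 0. Decay is
// applied once at the end by operator splitting (exact exponential factor).
// alpha = D * dt_sub / h^2 must satisfy alpha <= 1/6 (checked by the caller,
// which substeps as needed).
static double *diffuse_buffers(double *cur, double *nxt, int nx, int ny,
                               int nz, double alpha, int nsub,
                               double decay_factor) {
  const int nxy = nx * ny, ntot = nxy * nz;
  for (int s = 0; s < nsub; ++s) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const int base = nx * y + nxy * z;
        const bool ylo = y > 0, yhi = y < ny - 1;
        const bool zlo = z > 0, zhi = z < nz - 1;
        if (ylo && yhi && zlo && zhi) {
          // interior row: only the x boundaries need branches
          double c = cur[base];
          nxt[base] = c + alpha * (cur[base + 1] - c +
            cur[base - nx] + cur[base + nx] + cur[base - nxy] +
            cur[base + nxy] - 4.0 * c);
          for (int i = base + 1; i < base + nx - 1; ++i) {
            c = cur[i];
            nxt[i] = c + alpha * (cur[i - 1] + cur[i + 1] + cur[i - nx] +
              cur[i + nx] + cur[i - nxy] + cur[i + nxy] - 6.0 * c);
          }
          const int i = base + nx - 1;
          c = cur[i];
          nxt[i] = c + alpha * (cur[i - 1] - c +
            cur[i - nx] + cur[i + nx] + cur[i - nxy] + cur[i + nxy] -
            4.0 * c);
        } else {
          for (int x = 0; x < nx; ++x) {
            const int i = base + x;
            const double c = cur[i];
            double acc = 0.0;
            if (x > 0)   acc += cur[i - 1] - c;
            if (x < nx - 1) acc += cur[i + 1] - c;
            if (ylo) acc += cur[i - nx] - c;
            if (yhi) acc += cur[i + nx] - c;
            if (zlo) acc += cur[i - nxy] - c;
            if (zhi) acc += cur[i + nxy] - c;
            nxt[i] = c + alpha * acc;
          }
        }
      }
    }
    std::swap(cur, nxt);
  }
  if (decay_factor != 1.0)
    for (int i = 0; i < ntot; ++i) cur[i] *= decay_factor;
  return cur;
}

// [[Rcpp::export]]
NumericVector cpp_diffuse_decay(NumericVector field, int nx, int ny, int nz,
                                double alpha, int nsub, double decay_factor) {
  NumericVector a_ = clone(field), b_(field.size());
  double *res = diffuse_buffers(REAL(a_), REAL(b_), nx, ny, nz, alpha, nsub,
                                decay_factor);
  return (res == REAL(a_)) ? a_ : b_;
}

// Fused per-step field update used by the engine: secretion, clipped
// consumption, stable explicit diffusion and exponential decay in one pass,
// with the post-update total returned alongside. Semantically identical to
// secrete_consume() followed by diffuse_decay().
// [[Rcpp::export]]
List cpp_field_step(NumericVector field, IntegerVector sec_sites,
                    NumericVector sec_amt, IntegerVector cons_sites,
                    NumericVector cons_amt, int nx, int ny, int nz,
                    double alpha, int nsub, double decay_factor) {
  NumericVector f = clone(field);
  double *p = REAL(f);
  for (int i = 0; i < sec_sites.size(); ++i)
    p[sec_sites[i] - 1] += sec_amt[i % sec_amt.size()];
  for (int i = 0; i < cons_sites.size(); ++i) {
    double &v = p[cons_sites[i] - 1];
    v -= cons_amt[i % cons_amt.size()];
    if (v < 0) v = 0;
  }
  const int ntot = nx * ny * nz;
  double *res = p;
  NumericVector out = f;
  if (nsub > 0) {
    NumericVector b_(f.size());
    res = diffuse_buffers(p, REAL(b_), nx, ny, nz, alpha, nsub, decay_factor);
    if (res != REAL(f)) out = b_;
  } else if (decay_factor != 1.0) {
    for (int i = 0; i < ntot; ++i) p[i] *= decay_factor;
  }
  double tot = 0;
  for (int i = 0; i < ntot; ++i) tot += res[i];
  return List::create(_["field"] = out, _["total"] = tot);
}

// Enumerate empty candidate sites within Chebyshev distance R of (x0,y0,z0)
// restricted to `allowed_region`, score each by the dispersal weight
//   w = w_dist(1/|d|) * w_occ(1/(1+occupied)) * w_type * (1 + chemo_w * n_target)
// and sample one with probability proportional to w. Returns the chosen
// 0-based site or -1, and its clamped acceptance probability via `accept`.
static int sample_placement(const IntegerVector &occ, const IntegerVector &atype,
                            const IntegerVector &region,
                            int x0, int y0, int z0, int R, int allowed_region,
                            int nx, int ny, int nz,
                            int self_type, const NumericMatrix &wtype,
                            int chemo_type, double chemo_w,
                            const double *grad_field, double grad_gamma,
                            double *accept) {
  const int maxc = (2 * R + 1) * (2 * R + 1) * (2 * R + 1);
  std::vector<int> cand; cand.reserve(maxc);
  std::vector<double> w, wacc; w.reserve(maxc); wacc.reserve(maxc);
  double wsum = 0.0;
  for (int dz = -R; dz <= R; ++dz) {
    int z = z0 + dz; if (z < 0 || z >= nz) continue;
    for (int dy = -R; dy <= R; ++dy) {
      int y = y0 + dy; if (y < 0 || y >= ny) continue;
      for (int dx = -R; dx <= R; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int x = x0 + dx; if (x < 0 || x >= nx) continue;
        int i = lin(x, y, z, nx, ny);
        if (occ[i] != 0 || region[i] != allowed_region) continue;
        int cd = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
        // neighbour census of the candidate site
        int nocc = 0, ntarget = 0;
        double tw = 1.0;
        for (int ez = -1; ez <= 1; ++ez) {
          int zz = z + ez; if (zz < 0 || zz >= nz) continue;
          for (int ey = -1; ey <= 1; ++ey) {
            int yy = y + ey; if (yy < 0 || yy >= ny) continue;
            for (int ex = -1; ex <= 1; ++ex) {
              if (ex == 0 && ey == 0 && ez == 0) continue;
              int xx = x + ex; if (xx < 0 || xx >= nx) continue;
              int id = occ[lin(xx, yy, zz, nx, ny)];
              if (id != 0) {
                ++nocc;
                // children born earlier in this sweep have ids beyond atype;
                // they count as occupied but contribute no type weighting
                if (id <= atype.size()) {
                  int tt = atype[id - 1];
                  tw *= wtype(self_type - 1, tt - 1);
                  if (tt == chemo_type) ++ntarget;
                }
              }
            }
          }
        }
        double wi = (1.0 / cd) * (1.0 / (1.0 + nocc)) * tw;
        if (chemo_type > 0) wi *= (1.0 + chemo_w * ntarget);
        const double wa = wi; // dispersal acceptance excludes gradient gain
        // scale-free gradient climbing: candidates are weighted by the
        // local chemoattractant concentration raised to the gain
        if (grad_field && grad_gamma > 0)
          wi *= std::pow(grad_field[i] + 1e-12, grad_gamma);
        if (wi <= 0) continue;
        cand.push_back(i);
        w.push_back(wi);
        wacc.push_back(wa);
        wsum += wi;
      }
    }
  }
  if (cand.empty() || wsum <= 0) { *accept = 0.0; return -1; }
  double u = unif_rand() * wsum, acc = 0.0;
  size_t k = 0;
  for (; k < cand.size(); ++k) { acc += w[k]; if (u <= acc) break; }
  if (k >= cand.size()) k = cand.size() - 1;
  *accept = std::min(1.0, wacc[k]);
  return cand[k];
}

// One tumor-compartment decision sweep. Agents are visited in the caller's
// (seeded, shuffled) order; occupancy is updated in place as the sweep
// proceeds, so exclusion holds at every point. All randomness goes through
// R's RNG: results are reproducible under set.seed.
//
// Agent vectors are parallel; `site` is 1-based linear index (0 = off-lattice).
// Types: 1 = PC, 2 = TAM, 3 = CTL, 4 = Treg.
// Children are reported as (parent, site) pairs; the caller appends them with
// inherited attributes. Child ids used in `occ` are n + 1, n + 2, ... in
// reported order.
// [[Rcpp::export]]
List cpp_agents_step(IntegerVector occ_in, IntegerVector region,
                     IntegerVector type, IntegerVector site_in,
                     IntegerVector alive_in, IntegerVector effector,
                     IntegerVector suppressed_in,
                     IntegerVector order,
                     NumericVector p_die, NumericVector p_div,
                     NumericVector p_mig, NumericVector p_kill,
                     IntegerVector chemo_type, NumericVector chemo_w,
                     NumericVector grad_a, NumericVector grad_gamma_a,
                     NumericVector grad_b, NumericVector grad_gamma_b,
                     IntegerVector grad_sel,
                     int nx, int ny, int nz,
                     int supp_radius, double treg_p_kill_ctl,
                     NumericMatrix wtype) {
  IntegerVector occ = clone(occ_in);
  IntegerVector site = clone(site_in);
  IntegerVector alive = clone(alive_in);
  IntegerVector suppressed = clone(suppressed_in);
  const int n = type.size();
  std::vector<int> child_parent, child_site;
  int pc_deaths = 0, ctl_kills = 0;

  for (int oi = 0; oi < order.size(); ++oi) {
    const int a = order[oi] - 1;
    if (!alive[a] || site[a] == 0) continue;
    const int s0 = site[a] - 1;
    const int z0 = s0 / (nx * ny), y0 = (s0 / nx) % ny, x0 = s0 % nx;
    const int ty = type[a];

    if (ty == 3 && effector[a] && !suppressed[a] && p_kill[a] > 0) {
      // contact lysis: pick a random adjacent PC, kill with p_kill
      std::vector<int> prey;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x = x0 + dx, y = y0 + dy, z = z0 + dz;
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
          int id = occ[lin(x, y, z, nx, ny)];
          if (id != 0 && id <= n && type[id - 1] == 1) prey.push_back(id - 1);
        }
      if (!prey.empty() && unif_rand() < p_kill[a]) {
        int v = prey[(int)(unif_rand() * prey.size()) % prey.size()];
        alive[v] = 0; occ[site[v] - 1] = 0; site[v] = 0;
        ++pc_deaths; ++ctl_kills;
      }
    }

    if (ty == 4 && supp_radius > 0) {
      // Treg contact suppression: arrest CTLs in range, occasionally kill
      for (int dz = -supp_radius; dz <= supp_radius; ++dz)
        for (int dy = -supp_radius; dy <= supp_radius; ++dy)
          for (int dx = -supp_radius; dx <= supp_radius; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x = x0 + dx, y = y0 + dy, z = z0 + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
            int id = occ[lin(x, y, z, nx, ny)];
            if (id != 0 && id <= n && type[id - 1] == 3 && alive[id - 1]) {
              if (unif_rand() < treg_p_kill_ctl) {
                alive[id - 1] = 0; occ[site[id - 1] - 1] = 0; site[id - 1] = 0;
              } else {
                suppressed[id - 1] = 1;
              }
            }
          }
    }

    if (!alive[a]) continue; // may have been removed earlier this sweep
    if (unif_rand() < p_die[a]) {
      alive[a] = 0; occ[s0] = 0; site[a] = 0;
      if (ty == 1) ++pc_deaths;
      continue;
    }

    bool divided = false;
    if (unif_rand() < p_div[a]) {
      double accept;
      int tgt = sample_placement(occ, type, region, x0, y0, z0, 1,
                                 region[s0], nx, ny, nz, ty, wtype, 0, 0.0,
                                 nullptr, 0.0, &accept);
      if (tgt >= 0) {
        int cid = n + (int)child_parent.size() + 1;
        occ[tgt] = cid;
        child_parent.push_back(a + 1);
        child_site.push_back(tgt + 1);
        divided = true;
      }
    }
    if (!divided && unif_rand() < p_mig[a]) {
      double accept;
      const double *gf = grad_sel[a] == 1 ? REAL(grad_a)
                         : (grad_sel[a] == 2 ? REAL(grad_b) : nullptr);
      const double gg = gf ? (grad_sel[a] == 1 ? grad_gamma_a[a]
                                               : grad_gamma_b[a]) : 0.0;
      int tgt = sample_placement(occ, type, region, x0, y0, z0, 2,
                                 region[s0], nx, ny, nz, ty, wtype,
                                 chemo_type[a], chemo_w[a], gf, gg, &accept);
      if (tgt >= 0 && unif_rand() < accept) {
        occ[s0] = 0; occ[tgt] = a + 1; site[a] = tgt + 1;
      }
    }
  }

  return List::create(_["occ"] = occ, _["site"] = site, _["alive"] = alive,
                      _["suppressed"] = suppressed,
                      _["child_parent"] = wrap(child_parent),
                      _["child_site"] = wrap(child_site),
                      _["pc_deaths"] = pc_deaths, _["ctl_kills"] = ctl_kills);
}

// Mark a cube of half-width `radius` around each given site (1-based) TRUE.
// Used for the perivascular proliferation-bonus mask.
// [[Rcpp::export]]
LogicalVector cpp_dilate_mask(LogicalVector mask, IntegerVector sites,
                              int radius, int nx, int ny, int nz) {
  LogicalVector out = clone(mask);
  for (int k = 0; k < sites.size(); ++k) {
    int s = sites[k] - 1;
    int z0 = s / (nx * ny), y0 = (s / nx) % ny, x0 = s % nx;
    for (int dz = -radius; dz <= radius; ++dz) {
      int z = z0 + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -radius; dy <= radius; ++dy) {
        int y = y0 + dy; if (y < 0 || y >= ny) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          int x = x0 + dx; if (x < 0 || x >= nx) continue;
          out[lin(x, y, z, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// Count, for each query site, lattice neighbours within Chebyshev radius R
// holding an agent of the requested type. Used for linkage detection and
// local-density probes.
// [[Rcpp::export]]
IntegerVector cpp_count_type_near(IntegerVector occ, IntegerVector type,
                                  IntegerVector sites, int R, int want_type,
                                  int nx, int ny, int nz) {
  IntegerVector out(sites.size());
  for (int k = 0; k < sites.size(); ++k) {
    int s = sites[k] - 1;
    int z0 = s / (nx * ny), y0 = (s / nx) % ny, x0 = s % nx;
    int cnt = 0;
    for (int dz = -R; dz <= R; ++dz) {
      int z = z0 + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int y = y0 + dy; if (y < 0 || y >= ny) continue;
        for (int dx = -R; dx <= R; ++dx) {
          int x = x0 + dx; if (x < 0 || x >= nx) continue;
          int id = occ[lin(x, y, z, nx, ny)];
          if (id != 0 && type[id - 1] == want_type) ++cnt;
        }
      }
    }
    out[k] = cnt;
  }
  return out;
}
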