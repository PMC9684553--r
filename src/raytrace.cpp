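#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// The sample is represented by contiguous vertical columns resting at
// integer voxel offsets: per pixel (i = row = y, j = col = x) the occupied
// interval along z is [zbot, ztop] in um (empty when ztop <= zbot). The
// beam travels along -z; detectors sit above the support plane. All ray
// tracing reduces to exact 2D grid traversal (Amanatides-Woo) with an
// analytic z-interval overlap per crossed column, which is equivalent to
// exact 3D voxel walking because attenuation is homogeneous along z within
// a column.

struct Seg { int cell; double len; };

// Collect occupied chord lengths (um) of the segment p0 -> p1 through the
// column grid. Cells are indexed i + j*ny. skip_i/skip_j >= 0 excludes one
// column (used by coverage maps). zcap: no column top exceeds this height,
// enabling early exit once the ray has risen above it.
static void ray_segments(double x0, double y0, double z0,
                         double x1, double y1, double z1,
                         const double* zbot, const double* ztop,
                         int ny, int nx, double vox,
                         int skip_i, int skip_j, double zcap,
                         std::vector<Seg>& out) {
  out.clear();
  const double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
  const double L3 = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L3 <= 0.0) return;

  auto add_cell = [&](int ix, int iy, double u0, double u1) {
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return;
    if (iy == skip_i && ix == skip_j) return;
    const int cell = iy + ix * ny;
    const double zb = zbot[cell], zt = ztop[cell];
    if (zt <= zb) return;
    double contrib = 0.0;
    if (dz != 0.0) {
      // u-interval where z(u) in [zb, zt]
      double ua = (zb - z0) / dz, ub = (zt - z0) / dz;
      if (ua > ub) std::swap(ua, ub);
      const double lo = std::max(u0, ua), hi = std::min(u1, ub);
      if (hi > lo) contrib = (hi - lo) * L3;
    } else if (z0 >= zb && z0 <= zt) {
      contrib = (u1 - u0) * L3;
    }
    if (contrib > 0.0) out.push_back({cell, contrib});
  };

  if (dx == 0.0 && dy == 0.0) {
    int ix = (int)std::floor(x0 / vox), iy = (int)std::floor(y0 / vox);
    add_cell(ix, iy, 0.0, 1.0);
    return;
  }

  int ix = (int)std::floor(x0 / vox), iy = (int)std::floor(y0 / vox);
  const int stepx = (dx > 0) - (dx < 0), stepy = (dy > 0) - (dy < 0);
  const double tDx = (dx != 0.0) ? std::fabs(vox / dx) : R_PosInf;
  const double tDy = (dy != 0.0) ? std::fabs(vox / dy) : R_PosInf;
  double tMx, tMy;
  if (dx > 0) tMx = ((ix + 1) * vox - x0) / dx;
  else if (dx < 0) tMx = (ix * vox - x0) / dx;
  else tMx = R_PosInf;
  if (dy > 0) tMy = ((iy + 1) * vox - y0) / dy;
  else if (dy < 0) tMy = (iy * vox - y0) / dy;
  else tMy = R_PosInf;

  double u = 0.0;
  while (u < 1.0) {
    const double unext = std::min(1.0, std::min(tMx, tMy));
    if (unext > u) add_cell(ix, iy, u, unext);
    u = unext;
    if (u >= 1.0) break;
    // early exit: ray permanently above all columns
    if (dz > 0 && z0 + u * dz > zcap) break;
    // early exit: left the grid moving away
    if ((ix < 0 && stepx <= 0) || (ix >= nx && stepx >= 0)) break;
    if ((iy < 0 && stepy <= 0) || (iy >= ny && stepy >= 0)) break;
    if (tMx <= tMy) { ix += stepx; tMx += tDx; }
    else            { iy += stepy; tMy += tDy; }
  }
}

static double grid_zcap(const double* ztop, int n) {
  double m = 0.0;
  for (int k = 0; k < n; ++k) if (ztop[k] > m) m = ztop[k];
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_path(NumericVector p0, NumericVector p1,
                       NumericMatrix zbot, NumericMatrix ztop,
                       NumericMatrix att, double vox,
                       int skip_i, int skip_j) {
  const int ny = zbot.nrow(), nx = zbot.ncol();
  std::vector<Seg> segs;
  segs.reserve(256);
  ray_segments(p0[0], p0[1], p0[2], p1[0], p1[1], p1[2],
               zbot.begin(), ztop.begin(), ny, nx, vox,
               skip_i, skip_j, grid_zcap(ztop.begin(), ny * nx), segs);
  double depth = 0.0, len = 0.0;
  for (const Seg& s : segs) { depth += att[s.cell] * s.len; len += s.len; }
  return NumericVector::create(depth, len);
}

// Exact 3D voxel traversal through an arbitrary per-voxel attenuation
// volume (per um, dims ny x nx x nz); independent route used to cross-check
// the column tracer.
// [[Rcpp::export]]
double cpp_path_3d(NumericVector p0, NumericVector p1,
                   NumericVector att3d, IntegerVector dims, double vox) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  const double L3 = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L3 <= 0.0) return 0.0;
  // breakpoint-collection traversal: all grid-plane crossings in u
  std::vector<double> us;
  us.push_back(0.0); us.push_back(1.0);
  auto plane_us = [&](double o, double d, int n) {
    if (d == 0.0) return;
    for (int k = 0; k <= n; ++k) {
      const double u = (k * vox - o) / d;
      if (u > 0.0 && u < 1.0) us.push_back(u);
    }
  };
  plane_us(p0[0], dx, nx); plane_us(p0[1], dy, ny); plane_us(p0[2], dz, nz);
  std::sort(us.begin(), us.end());
  double depth = 0.0;
  for (size_t k = 0; k + 1 < us.size(); ++k) {
    const double um = 0.5 * (us[k] + us[k + 1]);
    const int ix = (int)std::floor((p0[0] + um * dx) / vox);
    const int iy = (int)std::floor((p0[1] + um * dy) / vox);
    const int iz = (int)std::floor((p0[2] + um * dz) / vox);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) continue;
    depth += att3d[iy + ix * ny + iz * ny * nx] * (us[k + 1] - us[k]) * L3;
  }
  return depth;
}

// Occupied path length (um) between each pixel's column top and the
// detector face center, excluding the pixel's own column.
// [[Rcpp::export]]
NumericMatrix cpp_coverage(NumericMatrix thick_um, NumericVector face_center,
                           double vox) {
  const int ny = thick_um.nrow(), nx = thick_um.ncol();
  NumericMatrix zbot(ny, nx), cov(ny, nx);
  const double zcap = grid_zcap(thick_um.begin(), ny * nx);
  std::vector<Seg> segs;
  segs.reserve(256);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      if (thick_um(i, j) <= 0.0) continue;
      const double x = (j + 0.5) * vox, y = (i + 0.5) * vox;
      ray_segments(x, y, thick_um(i, j), face_center[0], face_center[1],
                   face_center[2], zbot.begin(), thick_um.begin(),
                   ny, nx, vox, i, j, zcap, segs);
      double len = 0.0;
      for (const Seg& s : segs) len += s.len;
      cov(i, j) = len;
    }
  }
  return cov;
}

// Self-absorption K for every occupied voxel and one detector: mean over
// face ray targets of exp(-optical depth) at each requested line energy.
// ob/tv: per-pixel column offset and thickness in voxels. Returns one 3D
// array (ny, nx, nz) per attenuation map, value 1 on empty voxels.
// [[Rcpp::export]]
List cpp_k_matrices(IntegerMatrix ob, IntegerMatrix tv, List att_list,
                    NumericMatrix facepts, double vox, int nz) {
  const int ny = ob.nrow(), nx = ob.ncol(), nl = att_list.size();
  const int npt = facepts.nrow();
  NumericMatrix zbot(ny, nx), ztop(ny, nx);
  for (int k = 0; k < ny * nx; ++k) {
    zbot[k] = ob[k] * vox;
    ztop[k] = (ob[k] + tv[k]) * vox;
  }
  const double zcap = grid_zcap(ztop.begin(), ny * nx);
  std::vector<const double*> atts(nl);
  std::vector<NumericVector> Ks;
  for (int l = 0; l < nl; ++l) {
    atts[l] = NumericMatrix(att_list[l]).begin();
    NumericVector K(ny * nx * nz, 1.0);
    K.attr("dim") = IntegerVector::create(ny, nx, nz);
    Ks.push_back(K);
  }
  std::vector<Seg> segs;
  segs.reserve(256);
  std::vector<double> acc(nl);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      const int t = tv(i, j);
      if (t <= 0) continue;
      const double x = (j + 0.5) * vox, y = (i + 0.5) * vox;
      for (int kk = 0; kk < t; ++kk) {
        const int kz = ob(i, j) + kk;           // 0-based global z index
        if (kz < 0 || kz >= nz) continue;
        const double z = (kz + 0.5) * vox;
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int p = 0; p < npt; ++p) {
          ray_segments(x, y, z, facepts(p, 0), facepts(p, 1), facepts(p, 2),
                       zbot.begin(), ztop.begin(), ny, nx, vox,
                       -1, -1, zcap, segs);
          for (int l = 0; l < nl; ++l) {
            double d = 0.0;
            for (const Seg& s : segs) d += atts[l][s.cell] * s.len;
            acc[l] += std::exp(-d);
          }
        }
        for (int l = 0; l < nl; ++l)
          Ks[l][i + j * ny + kz * ny * nx] = acc[l] / npt;
      }
    }
  }
  List out(nl);
  for (int l = 0; l < nl; ++l) out[l] = Ks[l];
  return out;
}

// Count and equidistantly sample the gap-free candidate topographies of a
// chain of member pixels. tvox: thickness (voxels) per member; omax: max
// offset per member; fixedoff: >= 0 freezes a member at that offset;
// adj[m] = 1 when member m is spatially adjacent to member m-1, in which
// case the pair must keep z-overlap >= 1 voxel:
//   o_m <= o_{m-1} + t_{m-1} - 1  and  o_{m-1} <= o_m + t_m - 1.
// Candidates are ordered lexicographically; when the total exceeds delta,
// every ceil(total/delta)-th candidate is taken. Counts are tracked in
// doubles: beyond 2^53 the sampling is approximately (still
// deterministically) equidistant.
// [[Rcpp::export]]
List cpp_enumerate_candidates(IntegerVector tvox, IntegerVector omax,
                              IntegerVector fixedoff, IntegerVector adj,
                              double delta) {
  const int M = tvox.size();
  const double CAP = 1e290;
  std::vector<std::vector<double>> C(M);   // suffix counts
  auto allowed = [&](int m, int o) {
    if (fixedoff[m] >= 0) return o == fixedoff[m];
    return o >= 0 && o <= omax[m];
  };
  const int top = [&]{ int t = 0; for (int m = 0; m < M; ++m) t = std::max(t, omax[m]); return t; }();
  for (int m = M - 1; m >= 0; --m) {
    C[m].assign(top + 1, 0.0);
    if (m == M - 1) {
      for (int o = 0; o <= top; ++o) C[m][o] = allowed(m, o) ? 1.0 : 0.0;
    } else {
      // prefix sums of C[m+1]
      std::vector<double> ps(top + 2, 0.0);
      for (int o = 0; o <= top; ++o) ps[o + 1] = std::min(CAP, ps[o] + C[m + 1][o]);
      for (int o = 0; o <= top; ++o) {
        if (!allowed(m, o)) continue;
        const int lo = adj[m + 1] ? std::max(0, o - tvox[m + 1] + 1) : 0;
        const int hi = adj[m + 1] ? std::min(top, o + tvox[m] - 1) : top;
        if (hi >= lo) C[m][o] = std::min(CAP, ps[hi + 1] - ps[lo]);
      }
    }
  }
  double total = 0.0;
  for (int o = 0; o <= top; ++o) total = std::min(CAP, total + C[0][o]);
  if (total <= 0.0)
    return List::create(_["total"] = 0.0,
                        _["candidates"] = IntegerMatrix(0, M));
  const double step = (total <= delta) ? 1.0 : std::ceil(total / delta);
  const int ncand = (int)std::ceil(total / step);
  IntegerMatrix cands(ncand, M);
  for (int c = 0; c < ncand; ++c) {
    double r = c * step;
    int oprev = -1;
    for (int m = 0; m < M; ++m) {
      int lo = 0, hi = top;
      if (m > 0 && adj[m]) {
        lo = std::max(0, oprev - tvox[m] + 1);
        hi = std::min(top, oprev + tvox[m - 1] - 1);
      }
      int chosen = -1;
      for (int o = lo; o <= hi; ++o) {
        if (!allowed(m, o)) continue;
        if (r < C[m][o]) { chosen = o; break; }
        r -= C[m][o];
        chosen = o;  // fall back to last feasible under fp saturation
      }
      cands(c, m) = chosen;
      oprev = chosen;
    }
  }
  return List::create(_["total"] = total, _["candidates"] = cands);
}

// L1 score of each candidate topography: member columns are rigidly
// translated to the candidate offsets, the per-line 2D XRF response of the
// scored pixels is simulated (sum over column voxels of EM * mean path
// transmission), and the absolute deviation from the target maps is summed.
//
// The 2D crossing geometry of a ray depends only on the pixel and the face
// target, not on the source voxel's height, so the crossing lists (cells
// with their u-parameter intervals along the segment) are built once per
// region and reused across all candidates and column voxels; cells that
// can never be occupied (zero thickness) are dropped from the lists.
// [[Rcpp::export]]
NumericVector cpp_score_candidates(IntegerMatrix cands,
                                   IntegerVector mem_i, IntegerVector mem_j,
                                   IntegerMatrix ob_ctx, IntegerMatrix tv,
                                   List att_list, List em_prof,
                                   IntegerVector scored, List targets,
                                   NumericMatrix facepts, double vox) {
  const int ny = ob_ctx.nrow(), nx = ob_ctx.ncol();
  const int M = mem_i.size(), ncand = cands.nrow();
  const int nl = att_list.size(), npt = facepts.nrow(), ns = scored.size();
  if (nl > 8) stop("at most 8 scored lines are supported");
  IntegerMatrix ob = clone(ob_ctx);
  std::vector<double> zbot(ny * nx), ztop(ny * nx);
  for (int k = 0; k < ny * nx; ++k) {
    zbot[k] = ob[k] * vox;
    ztop[k] = (ob[k] + tv[k]) * vox;
  }
  double zcap_nonmem = 0.0;
  {
    std::vector<bool> is_mem(ny * nx, false);
    for (int m = 0; m < M; ++m) is_mem[mem_i[m] + mem_j[m] * ny] = true;
    for (int k = 0; k < ny * nx; ++k)
      if (!is_mem[k] && ztop[k] > zcap_nonmem) zcap_nonmem = ztop[k];
  }
  std::vector<const double*> atts(nl);
  std::vector<const double*> tgts(nl);
  for (int l = 0; l < nl; ++l) {
    atts[l] = NumericMatrix(att_list[l]).begin();
    tgts[l] = NumericMatrix(targets[l]).begin();
  }
  std::vector<NumericMatrix> ems;
  for (int s = 0; s < ns; ++s) ems.push_back(NumericMatrix(em_prof[s]));

  // cached crossings per (scored pixel, face point), occupied-capable only
  struct Cross { int cell; double u0, u1; };
  std::vector<std::vector<Cross>> cache(ns * npt);
  std::vector<Seg> segs;
  segs.reserve(512);
  {
    // an all-occupied dummy column field exposes every crossing interval
    std::vector<double> zb0(ny * nx, -1e9), zt0(ny * nx, 1e9);
    for (int s = 0; s < ns; ++s) {
      const int m = scored[s];
      const double x = (mem_j[m] + 0.5) * vox, y = (mem_i[m] + 0.5) * vox;
      for (int p = 0; p < npt; ++p) {
        // reuse the tracer with unit attenuation to collect u-intervals:
        // z range is unbounded so every cell along the 2D path appears
        ray_segments(x, y, 0.0, facepts(p, 0), facepts(p, 1), facepts(p, 2),
                     zb0.data(), zt0.data(), ny, nx, vox, -1, -1,
                     R_PosInf, segs);
        const double dxs = facepts(p, 0) - x, dys = facepts(p, 1) - y,
                     dzs = facepts(p, 2) - 0.0;
        const double L3 = std::sqrt(dxs * dxs + dys * dys + dzs * dzs);
        // recover u-intervals from chord lengths cumulatively
        std::vector<Cross>& cl = cache[s * npt + p];
        double ucur = 0.0;
        for (const Seg& sg : segs) {
          const double du = sg.len / L3;
          if (tv[sg.cell] > 0)
            cl.push_back({sg.cell, ucur, ucur + du});
          ucur += du;
        }
      }
    }
  }

  // which members are free (their columns move between candidates)?
  std::vector<int> free_of_cell(ny * nx, -1);
  {
    std::vector<bool> varies(M, false);
    for (int m = 0; m < M; ++m)
      for (int c = 1; c < ncand && !varies[m]; ++c)
        if (cands(c, m) != cands(0, m)) varies[m] = true;
    for (int m = 0; m < M; ++m)
      if (varies[m]) free_of_cell[mem_i[m] + mem_j[m] * ny] = m;
  }

  // The frozen part of each ray's optical depth depends only on the source
  // voxel's height, i.e. on the scored column's own offset -- a small
  // integer. Memoize it per (scored pixel, face point, voxel, own offset,
  // line); per candidate only the crossings over free member columns are
  // re-evaluated.
  int top = 0;
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < ncand; ++c) top = std::max(top, cands(c, m));
  int maxt = 1;
  for (int s = 0; s < ns; ++s)
    maxt = std::max(maxt, tv[mem_i[scored[s]] + mem_j[scored[s]] * ny]);
  const size_t no = top + 1;
  std::vector<double> dfro((size_t)ns * npt * maxt * no * nl,
                           R_NegInf);      // sentinel: not yet filled

  auto chord_of = [&](const Cross& cr, double z0, double dz, double L3,
                      double zb, double zt) -> double {
    if (dz != 0.0) {
      const double za = z0 + cr.u0 * dz, zbnd = z0 + cr.u1 * dz;
      const double zl = std::min(za, zbnd), zh = std::max(za, zbnd);
      const double lo = std::max(zl, zb), hi = std::min(zh, zt);
      return (hi > lo) ? (hi - lo) / std::fabs(dz) * L3 : 0.0;
    }
    return (z0 >= zb && z0 <= zt) ? (cr.u1 - cr.u0) * L3 : 0.0;
  };

  // compact per-(pixel, target) sublists of the crossings that move between
  // candidates (free member columns other than the pixel's own)
  std::vector<std::vector<Cross>> freecache(ns * npt);
  for (int s = 0; s < ns; ++s) {
    const int own = mem_i[scored[s]] + mem_j[scored[s]] * ny;
    for (int p = 0; p < npt; ++p)
      for (const Cross& cr : cache[s * npt + p])
        if (free_of_cell[cr.cell] >= 0 && cr.cell != own)
          freecache[s * npt + p].push_back(cr);
  }

  NumericVector scores(ncand);
  std::vector<double> sim(nl);
  const double zcap_all = std::max(zcap_nonmem, (top + maxt) * vox);
  for (int c = 0; c < ncand; ++c) {
    for (int m = 0; m < M; ++m) {
      const int cell = mem_i[m] + mem_j[m] * ny;
      ob[cell] = cands(c, m);
      zbot[cell] = ob[cell] * vox;
      ztop[cell] = (ob[cell] + tv[cell]) * vox;
    }
    double sc = 0.0;
    for (int s = 0; s < ns; ++s) {
      const int m = scored[s];
      const int i = mem_i[m], j = mem_j[m], cell = i + j * ny;
      const int t = tv[cell];
      const int oown = ob[cell];
      const double x = (j + 0.5) * vox, y = (i + 0.5) * vox;
      std::fill(sim.begin(), sim.end(), 0.0);
      for (int kk = 0; kk < t; ++kk) {           // kk = depth from column top
        const double z0 = ztop[cell] - (kk + 0.5) * vox;
        for (int p = 0; p < npt; ++p) {
          const double dz = facepts(p, 2) - z0;
          const double dxs = facepts(p, 0) - x, dys = facepts(p, 1) - y;
          const double L3 = std::sqrt(dxs * dxs + dys * dys + dz * dz);
          double* slot = &dfro[((((size_t)s * npt + p) * maxt + kk) * no +
                                oown) * nl];
          if (slot[0] == R_NegInf) {
            for (int l = 0; l < nl; ++l) slot[l] = 0.0;
            for (const Cross& cr : cache[s * npt + p]) {
              if (dz > 0 && z0 + cr.u0 * dz > zcap_all) break;
              const int fm = free_of_cell[cr.cell];
              if (fm >= 0 && cr.cell != cell) continue;  // free: per-candidate
              // own column at its current offset; frozen cells never move
              const double ch = chord_of(cr, z0, dz, L3,
                                         zbot[cr.cell], ztop[cr.cell]);
              if (ch > 0)
                for (int l = 0; l < nl; ++l)
                  slot[l] += atts[l][cr.cell] * ch;
            }
          }
          double dep[8];
          for (int l = 0; l < nl; ++l) dep[l] = slot[l];
          for (const Cross& cr : freecache[s * npt + p]) {
            if (dz > 0 && z0 + cr.u0 * dz > zcap_all) break;
            const double ch = chord_of(cr, z0, dz, L3,
                                       zbot[cr.cell], ztop[cr.cell]);
            if (ch > 0)
              for (int l = 0; l < nl; ++l)
                dep[l] += atts[l][cr.cell] * ch;
          }
          for (int l = 0; l < nl; ++l)
            sim[l] += ems[s](kk, l) * std::exp(-dep[l]) / npt;
        }
      }
      for (int l = 0; l < nl; ++l) sc += std::fabs(sim[l] - tgts[l][cell]);
    }
    scores[c] = sc;
  }
  return scores;
}
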