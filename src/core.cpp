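// Voxel-level primitives for 3D phase unwrapping.
//
// Volumes are passed as flat vectors in R's column-major layout with
// dims = (nx, ny, nz); the x index varies fastest.  All indices exchanged
// with R are 1-based; internal indices are 0-based.

#include <RcppArmadillo.h>
#include <queue>
#include <tuple>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// principal value in (-pi, pi]
static inline double wrap_pv(double x) {
  double w = x - TWOPI * std::ceil((x - M_PI) / TWOPI);
  return w;
}

struct Offs { int dx, dy, dz; };

static std::vector<Offs> neighbor_offsets(int connectivity) {
  std::vector<Offs> out;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (l1 == 0) continue;
        if (connectivity == 6 && l1 > 1) continue;
        if (connectivity == 18 && l1 > 2) continue;
        out.push_back({dx, dy, dz});
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<Offs> offs = neighbor_offsets(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (const Offs &o : offs) {
        int xx = x + o.dx, yy = y + o.dy, zz = z + o.dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Noisy-connector test on one subinterval mask.  A voxel is excluded iff
// (i) it is face-exposed (some 6-neighbor outside the region, volume border
// counts as outside) and (ii) on at least two of the three axes it has an
// out-of-region neighbor within `reach` voxels.  `conjunctive = true`
// switches (ii) to the stricter reading: all `reach` neighbors on one side
// of the axis lie outside.
// [[Rcpp::export]]
LogicalVector cpp_exclude_noisy(LogicalVector region, IntegerVector dims,
                                int reach, bool conjunctive) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector excluded(n, FALSE);
  const int strd[3] = {1, nx, nx * ny};
  const int dim3[3] = {nx, ny, nz};
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!region[v]) continue;
    int c[3];
    c[0] = (int)(v % nx); c[1] = (int)((v / nx) % ny); c[2] = (int)(v / (nx * ny));
    bool edge = false;
    for (int a = 0; a < 3 && !edge; ++a) {
      for (int s = -1; s <= 1; s += 2) {
        int p = c[a] + s;
        if (p < 0 || p >= dim3[a] || !region[v + (R_xlen_t)s * strd[a]]) {
          edge = true; break;
        }
      }
    }
    if (!edge) continue;
    int naxes = 0;
    for (int a = 0; a < 3; ++a) {
      bool axis_hit;
      if (!conjunctive) {
        axis_hit = false;
        for (int d = 1; d <= reach && !axis_hit; ++d) {
          for (int s = -1; s <= 1; s += 2) {
            int p = c[a] + s * d;
            if (p < 0 || p >= dim3[a] ||
                !region[v + (R_xlen_t)(s * d) * strd[a]]) {
              axis_hit = true; break;
            }
          }
        }
      } else {
        bool lo = true, hi = true;
        for (int d = 1; d <= reach; ++d) {
          int p = c[a] - d;
          if (!(p < 0 || !region[v - (R_xlen_t)d * strd[a]])) lo = false;
          p = c[a] + d;
          if (!(p >= dim3[a] || !region[v + (R_xlen_t)d * strd[a]])) hi = false;
        }
        axis_hit = lo || hi;
      }
      if (axis_hit) ++naxes;
    }
    if (naxes >= 2) excluded[v] = TRUE;
  }
  return excluded;
}

// Root-mean-square principal phase difference to in-mask 26-neighbors.
// Voxels with no in-mask neighbor receive pi, the largest attainable score.
// [[Rcpp::export]]
NumericVector cpp_quality_map(NumericVector phase, LogicalVector mask,
                              IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector q(n, NA_REAL);
  std::vector<Offs> offs = neighbor_offsets(26);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / (nx * ny));
    double ss = 0.0; int cnt = 0;
    for (const Offs &o : offs) {
      int xx = x + o.dx, yy = y + o.dy, zz = z + o.dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[w]) continue;
      double d = wrap_pv(phase[w] - phase[v]);
      ss += d * d; ++cnt;
    }
    q[v] = (cnt > 0) ? std::sqrt(ss / cnt) : M_PI;
  }
  return q;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb) ----

static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from each voxel to the nearest
// source voxel.  Returns +Inf everywhere if there are no sources.  Internally
// a large finite sentinel keeps the lower-envelope arithmetic NaN-free.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sources, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e15;
  NumericVector out(n);
  double *g = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = sources[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      double *row = g + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = row[x];
      dt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int x = 0; x < nx; ++x) row[x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nx * y];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; ++zz) f[zz] = g[base + sz * zz];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz) g[base + sz * zz] = d[zz];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (g[i] >= BIG / 2) g[i] = R_PosInf;
  return out;
}

// The k candidates with the smallest key, ties broken by candidate order.
// `cand` holds 1-based linear indices into `key`; the selection is returned
// sorted by (key, index), again 1-based.
// [[Rcpp::export]]
IntegerVector cpp_select_smallest(NumericVector key, IntegerVector cand, int k) {
  R_xlen_t n = cand.size();
  if (k >= n) {
    std::vector<std::pair<double, int>> all(n);
    for (R_xlen_t i = 0; i < n; ++i)
      all[i] = {key[cand[i] - 1], cand[i]};
    std::sort(all.begin(), all.end());
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = all[i].second;
    return out;
  }
  std::vector<std::pair<double, int>> all(n);
  for (R_xlen_t i = 0; i < n; ++i)
    all[i] = {key[cand[i] - 1], cand[i]};
  std::nth_element(all.begin(), all.begin() + k, all.end());
  std::sort(all.begin(), all.begin() + k);
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = all[i].second;
  return out;
}

// ---- quality-guided residual growing ----

struct BasisSpec {
  int L, M, N, T;
  std::vector<int> l, m, n;  // exponents per term, lexicographic in (l,m,n)
};

static BasisSpec make_basis(int L, int M, int N) {
  BasisSpec b; b.L = L; b.M = M; b.N = N;
  for (int l = 0; l <= L; ++l)
    for (int m = 0; m <= M; ++m)
      for (int n = 0; n <= N; ++n) {
        b.l.push_back(l); b.m.push_back(m); b.n.push_back(n);
      }
  b.T = (int)b.l.size();
  return b;
}

// One pass of quality-guided growing over `pass_mask` voxels.  Candidates
// are pass voxels 26-adjacent to a done voxel, processed in order of
// (quality ascending, insertion order).  Each voxel's integer offset comes
// from a distance-weighted (tricube kernel) local polynomial fit to the
// (up to `cap` nearest) done voxels inside the centered window, so the
// prediction is dominated by the voxels adjacent to the growth front.
// Polynomial order is chosen per voxel by nested-model tests (see below).
// Coordinates are centered on the growing voxel and scaled by the window
// half-width, so the prediction at the voxel is the fitted constant term.
// `done`, `unwrapped` and `kvec` are copied, updated and returned.
// [[Rcpp::export]]
List cpp_grow_pass(NumericVector phase, NumericVector quality,
                   LogicalVector pass_mask, LogicalVector done,
                   NumericVector unwrapped, IntegerVector kvec,
                   IntegerVector dims, int window, int cap,
                   IntegerVector orders, int fb_linear, int fb_mean,
                   bool trace) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int h = (window - 1) / 2;
  const double scale = (double)std::max(1, h);
  done = clone(done);
  unwrapped = clone(unwrapped);
  kvec = clone(kvec);

  BasisSpec full = make_basis(orders[0], orders[1], orders[2]);
  // indices of the linear-subset terms within the full basis
  std::vector<int> linsub;
  for (int t = 0; t < full.T; ++t)
    if (full.l[t] <= 1 && full.m[t] <= 1 && full.n[t] <= 1) linsub.push_back(t);
  const int T = full.T, TL = (int)linsub.size();

  // window offsets (excluding center) sorted by distance, then (dz,dy,dx)
  struct WOff { int dx, dy, dz, d2; };
  std::vector<WOff> woffs;
  for (int dz = -h; dz <= h; ++dz)
    for (int dy = -h; dy <= h; ++dy)
      for (int dx = -h; dx <= h; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        woffs.push_back({dx, dy, dz, dx * dx + dy * dy + dz * dz});
      }
  std::stable_sort(woffs.begin(), woffs.end(),
                   [](const WOff &a, const WOff &b) {
                     if (a.d2 != b.d2) return a.d2 < b.d2;
                     if (a.dz != b.dz) return a.dz < b.dz;
                     if (a.dy != b.dy) return a.dy < b.dy;
                     return a.dx < b.dx;
                   });
  const int W = (int)woffs.size();

  // precomputed tricube weight, basis row and weighted upper-triangle outer
  // products per offset, for the full basis and the trilinear sub-basis
  // (most fits never get promoted past the trilinear model, so the full
  // normal equations are only accumulated on demand)
  const int UT = T * (T + 1) / 2, UT8 = TL * (TL + 1) / 2;
  const double D = std::sqrt(3.0) * h * 1.0001;  // just beyond the corners
  std::vector<double> wgt(W), rows((size_t)W * T), outer((size_t)W * UT),
      outer8((size_t)W * UT8);
  for (int w = 0; w < W; ++w) {
    double u3 = std::pow(std::sqrt((double)woffs[w].d2) / D, 3.0);
    wgt[w] = std::pow(1.0 - u3, 3.0);
    double xs = woffs[w].dx / scale, ys = woffs[w].dy / scale,
           zs = woffs[w].dz / scale;
    double px[8], py[8], pz[8];
    px[0] = py[0] = pz[0] = 1.0;
    for (int p = 1; p <= std::max(full.L, std::max(full.M, full.N)); ++p) {
      px[p] = px[p - 1] * xs; py[p] = py[p - 1] * ys; pz[p] = pz[p - 1] * zs;
    }
    double *r = &rows[(size_t)w * T];
    for (int t = 0; t < T; ++t)
      r[t] = px[full.l[t]] * py[full.m[t]] * pz[full.n[t]];
    double *o = &outer[(size_t)w * UT];
    int u = 0;
    for (int i = 0; i < T; ++i)
      for (int j = i; j < T; ++j) o[u++] = wgt[w] * r[i] * r[j];
    double *o8 = &outer8[(size_t)w * UT8];
    u = 0;
    for (int i = 0; i < TL; ++i)
      for (int j = i; j < TL; ++j)
        o8[u++] = wgt[w] * r[linsub[i]] * r[linsub[j]];
  }

  std::vector<Offs> adj = neighbor_offsets(26);
  auto in_bounds = [&](int x, int y, int z) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };

  // Front-aware priority: a candidate is ranked by the worse of its static
  // quality score and the smallest wrapped phase difference along any link
  // to an already-unwrapped 26-neighbor -- the phase derivative along the
  // actual growth path.  Steep gaps are therefore crossed where the field
  // is locally gentle, and regions behind a steep interface wait until a
  // consistent path (e.g. along a low-gradient direction) has reached them.
  // The priority of a voxel can only improve as the front advances; the
  // heap is updated lazily (duplicates allowed, the best entry pops first,
  // later stale entries are skipped because the voxel is done).
  typedef std::tuple<double, long long, int> QEl;
  std::priority_queue<QEl, std::vector<QEl>, std::greater<QEl>> pq;
  std::vector<double> best_prio(n, R_PosInf);
  long long seq = 0;

  auto try_enqueue = [&](R_xlen_t v, R_xlen_t from) {
    if (!pass_mask[v] || done[v]) return;
    double link = std::fabs(wrap_pv(phase[v] - phase[from]));
    double prio = std::max(quality[v], link);
    if (prio < best_prio[v]) {
      best_prio[v] = prio;
      pq.push(QEl(prio, seq++, (int)v));
    }
  };

  for (R_xlen_t v = 0; v < n; ++v) {
    if (!pass_mask[v] || done[v]) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / (nx * ny));
    for (const Offs &o : adj) {
      int xx = x + o.dx, yy = y + o.dy, zz = z + o.dz;
      if (!in_bounds(xx, yy, zz)) continue;
      R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (done[u]) try_enqueue(v, u);
    }
  }

  std::vector<double> A((size_t)UT), bvec(T), yval(cap > 0 ? cap : 1);
  std::vector<int> sel(cap > 0 ? cap : 1);
  std::vector<int> order_trace;
  R_xlen_t processed = 0;

  while (!pq.empty()) {
    QEl top = pq.top(); pq.pop();
    int v = std::get<2>(top);
    if (done[v]) continue;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);

    // nearest done voxels in the window, with weighted moments
    int npts = 0;
    double W1 = 0.0, W2 = 0.0, ysum = 0.0, yy = 0.0;
    for (int w = 0; w < W && npts < cap; ++w) {
      int xx = x + woffs[w].dx, yy_ = y + woffs[w].dy, zz = z + woffs[w].dz;
      if (!in_bounds(xx, yy_, zz)) continue;
      R_xlen_t u = xx + (R_xlen_t)nx * (yy_ + (R_xlen_t)ny * zz);
      if (!done[u]) continue;
      sel[npts] = w;
      yval[npts] = unwrapped[u];
      double wt = wgt[w];
      W1 += wt; W2 += wt * wt;
      ysum += wt * unwrapped[u];
      yy += wt * unwrapped[u] * unwrapped[u];
      ++npts;
    }
    if (npts == 0) continue;  // defensive; cannot occur
    // kernel-effective sample size
    double neff = (W2 > 0) ? W1 * W1 / W2 : 0.0;

    // solve weighted normal equations given an upper-triangle accumulator;
    // returns the prediction at the (centered) voxel (= constant
    // coefficient), the weighted y'X coef inner product and the query
    // leverage
    auto solve_ne = [&](const double *Aut, const double *bacc, int Ts,
                        double w1s, double w2s,
                        double &pred_out, double &fitss_out,
                        double &h0_out) -> bool {
      arma::mat Am(Ts, Ts);
      arma::vec bm(Ts);
      int u = 0;
      for (int i = 0; i < Ts; ++i) {
        bm(i) = bacc[i];
        for (int j = i; j < Ts; ++j) { Am(i, j) = Am(j, i) = Aut[u++]; }
      }
      Am.diag() += 1e-10 * arma::trace(Am) / Ts;
      arma::mat L;
      if (!arma::chol(L, Am, "lower")) return false;
      arma::vec coef = arma::solve(arma::trimatu(L.t()),
                                   arma::solve(arma::trimatl(L), bm));
      if (!coef.is_finite()) return false;
      arma::vec e1(Ts, arma::fill::zeros); e1(0) = 1.0;
      arma::vec w = arma::solve(arma::trimatl(L), e1);
      // weighted prediction-variance factor: Var(pred) ~ sigma^2 * h0 with
      // h0 = (W2/W1) * x0' A^-1 x0 (exact for locally constant weights);
      // reduces to the usual leverage when all weights are equal
      h0_out = (w2s / w1s) * arma::dot(w, w);
      pred_out = coef(0);  // basis at the growing voxel is e1
      fitss_out = arma::dot(bm, coef);
      return true;
    };

    // Nested-model selection.  The weighted mean is the baseline; the
    // trilinear and then the full-order fit must explain significantly
    // more variance (F > 4 on kernel-effective degrees of freedom) to
    // enter -- so noise-only windows are not chased by spurious trends --
    // and must lower the estimated predictive mean squared error at the
    // growing voxel, sigma_hat^2 * (1 + h0): the model residual variance
    // absorbs its lack of fit and the query leverage h0 scales its noise
    // amplification.
    const double FCRIT = 4.0;
    double mean = ysum / W1;
    double pred = mean;
    double rss0 = yy - W1 * mean * mean;
    if (rss0 < 0) rss0 = 0;
    double mse = rss0 / std::max(1.0, neff - 1) * (1.0 + 1.0 / neff);

    // Selection cascade, cheapest-first: the windowed mean is the
    // baseline; the trilinear and full-order fits are evaluated on the
    // nearest 8*T points (the quadratic terms are a local correction, and
    // bounding the subset keeps the T*(T+1)/2 accumulation independent of
    // window occupancy); the full-window trilinear -- whose only advantage
    // is averaging more noise -- is accumulated only when the subset
    // verdict is not already decisive (predictive MSE above 0.15 rad^2,
    // i.e. a 1-sigma prediction error above ~0.4 rad against the pi
    // rounding margin).
    int nq = std::min(npts, 8 * T);
    double W1q = 0, W2q = 0, ysq = 0, yyq = 0;
    for (int p = 0; p < nq; ++p) {
      double wt = wgt[sel[p]];
      W1q += wt; W2q += wt * wt;
      ysq += wt * yval[p];
      yyq += wt * yval[p] * yval[p];
    }
    double neffq = (W2q > 0) ? W1q * W1q / W2q : 0.0;
    double meanq = ysq / std::max(W1q, 1e-300);
    double rss0q = yyq - W1q * meanq * meanq;
    if (rss0q < 0) rss0q = 0;

    if (neffq >= fb_mean && TL >= 2) {
      std::fill(A.begin(), A.begin() + UT8, 0.0);
      std::fill(bvec.begin(), bvec.begin() + TL, 0.0);
      for (int p = 0; p < nq; ++p) {
        const double *o8 = &outer8[(size_t)sel[p] * UT8];
        const double *r = &rows[(size_t)sel[p] * T];
        double wy = wgt[sel[p]] * yval[p];
        for (int u = 0; u < UT8; ++u) A[u] += o8[u];
        for (int t = 0; t < TL; ++t) bvec[t] += r[linsub[t]] * wy;
      }
      double pred1q, fss1q, h1q;
      if (solve_ne(A.data(), bvec.data(), TL, W1q, W2q,
                   pred1q, fss1q, h1q)) {
        double rss1q = yyq - fss1q;
        if (rss1q < 0) rss1q = 0;
        double f1q = ((rss0q - rss1q) / (TL - 1)) /
                     (rss1q / std::max(1.0, neffq - TL));
        double mse1q = rss1q / std::max(1.0, neffq - TL) * (1.0 + h1q);
        if (std::isfinite(pred1q) && f1q > FCRIT && mse1q <= mse) {
          pred = pred1q;
          mse = mse1q;
          if (mse > 0.15 && neffq >= fb_linear && T > TL) {
            std::fill(A.begin(), A.begin() + UT, 0.0);
            std::fill(bvec.begin(), bvec.begin() + T, 0.0);
            for (int p = 0; p < nq; ++p) {
              const double *o = &outer[(size_t)sel[p] * UT];
              const double *r = &rows[(size_t)sel[p] * T];
              double wy = wgt[sel[p]] * yval[p];
              for (int u = 0; u < UT; ++u) A[u] += o[u];
              for (int t = 0; t < T; ++t) bvec[t] += r[t] * wy;
            }
            double pred2, fss2, h2;
            if (solve_ne(A.data(), bvec.data(), T, W1q, W2q,
                         pred2, fss2, h2)) {
              double rss2 = yyq - fss2;
              if (rss2 < 0) rss2 = 0;
              double f2 = ((rss1q - rss2) / (T - TL)) /
                          (rss2 / std::max(1.0, neffq - T));
              double mse2 = rss2 / std::max(1.0, neffq - T) * (1.0 + h2);
              if (std::isfinite(pred2) && f2 > FCRIT && mse2 <= mse) {
                pred = pred2;
                mse = mse2;
              }
            }
          }
        }
      }
    }

    if (mse > 0.15 && npts > nq && neff >= fb_mean && TL >= 2) {
      // wide averaging pass over every done voxel in the window
      std::fill(A.begin(), A.begin() + UT8, 0.0);
      std::fill(bvec.begin(), bvec.begin() + TL, 0.0);
      for (int p = 0; p < npts; ++p) {
        const double *o8 = &outer8[(size_t)sel[p] * UT8];
        const double *r = &rows[(size_t)sel[p] * T];
        double wy = wgt[sel[p]] * yval[p];
        for (int u = 0; u < UT8; ++u) A[u] += o8[u];
        for (int t = 0; t < TL; ++t) bvec[t] += r[linsub[t]] * wy;
      }
      double pred1, fss1, h1;
      if (solve_ne(A.data(), bvec.data(), TL, W1, W2, pred1, fss1, h1)) {
        double rss1 = yy - fss1;
        if (rss1 < 0) rss1 = 0;
        double f1 = ((rss0 - rss1) / (TL - 1)) /
                    (rss1 / std::max(1.0, neff - TL));
        double mse1 = rss1 / std::max(1.0, neff - TL) * (1.0 + h1);
        if (std::isfinite(pred1) && f1 > FCRIT && mse1 <= mse) {
          pred = pred1;
          mse = mse1;
        }
      }
    }

    // Competing predictor: the mean phase continuation across the done
    // 26-neighbors, y_u + wrap(phase_v - phase_u) -- exact whenever the
    // true (noisy) phase steps by less than pi across the links.  The
    // scatter of the continuations measures local phase coherence, putting
    // this predictor into the same predictive-MSE competition: on coherent
    // rapidly varying phase it wins over the window fit (whose residual
    // variance records its model misfit), on incoherent noise it loses to
    // wide averaging.
    {
      double csum = 0.0, css = 0.0, link1 = 0.0;
      int m = 0;
      for (const Offs &o : adj) {
        int xx = x + o.dx, yy_ = y + o.dy, zz = z + o.dz;
        if (!in_bounds(xx, yy_, zz)) continue;
        R_xlen_t u = xx + (R_xlen_t)nx * (yy_ + (R_xlen_t)ny * zz);
        if (!done[u]) continue;
        double step = wrap_pv(phase[v] - phase[u]);
        double c = unwrapped[u] + step;
        csum += c; css += c * c; ++m;
        link1 = step;
      }
      if (m >= 1) {
        double cmean = csum / m;
        double mse_adj;
        if (m >= 2) {
          double cvar = (css - m * cmean * cmean) / (m - 1);
          if (cvar < 0) cvar = 0;
          mse_adj = cvar * (1.0 + 1.0 / m);
        } else {
          // A single link offers no coherence check.  A continuation is
          // exact unless the link aliases (true step beyond pi observed as
          // a small wrapped step), so price it by the aliasing risk under a
          // heavy-tailed step distribution.  The relevant scale is the
          // step NOISE, not the deterministic gradient: noise is isotropic
          // while structure is directional, so the smallest per-axis RMS
          // step at the voxel estimates it robustly.  Doubled as a safety
          // factor against error propagation along chains of single links.
          double axrms[3], best = R_PosInf;
          const int strd3[3] = {1, nx, nx * ny};
          const int c3[3] = {x, y, z}, d3[3] = {nx, ny, nz};
          for (int a = 0; a < 3; ++a) {
            double ss = 0.0; int cnt = 0;
            for (int s2 = -1; s2 <= 1; s2 += 2) {
              int p3 = c3[a] + s2;
              if (p3 < 0 || p3 >= d3[a]) continue;
              R_xlen_t u3 = (R_xlen_t)v + (R_xlen_t)s2 * strd3[a];
              if (!pass_mask[u3] && !done[u3]) continue;
              double d = wrap_pv(phase[u3] - phase[v]);
              ss += d * d; ++cnt;
            }
            axrms[a] = (cnt > 0) ? std::sqrt(ss / cnt) : R_PosInf;
            if (axrms[a] < best) best = axrms[a];
          }
          double scale = std::isfinite(best) ? std::max(best, 0.05)
                                             : std::max(quality[v], 0.05);
          mse_adj = 2.0 * TWOPI * TWOPI *
                    std::exp(-(TWOPI - std::fabs(link1)) / scale);
        }
        if (mse_adj < mse) pred = cmean;
      }
    }

    // Under the spatial-smoothness assumption a voxel adjacent to the done
    // front cannot exceed its window's unwrapped values by more than one
    // wrap; clamping keeps a pathological fit from seeding a runaway.
    double ymin = yval[0], ymax = yval[0];
    for (int p = 1; p < npts; ++p) {
      if (yval[p] < ymin) ymin = yval[p];
      if (yval[p] > ymax) ymax = yval[p];
    }
    if (pred < ymin - TWOPI) pred = ymin - TWOPI;
    if (pred > ymax + TWOPI) pred = ymax + TWOPI;

    long kk = std::lround((pred - phase[v]) / TWOPI);
    done[v] = TRUE;
    kvec[v] = (int)kk;
    unwrapped[v] = phase[v] + TWOPI * (double)kk;
    ++processed;
    if (trace) order_trace.push_back(v + 1);

    for (const Offs &o : adj) {
      int xx = x + o.dx, yy_ = y + o.dy, zz = z + o.dz;
      if (in_bounds(xx, yy_, zz))
        try_enqueue(xx + (R_xlen_t)nx * (yy_ + (R_xlen_t)ny * zz), v);
    }
  }

  std::vector<int> unreached;
  for (R_xlen_t v = 0; v < n; ++v)
    if (pass_mask[v] && !done[v]) unreached.push_back((int)v + 1);

  List out = List::create(_["done"] = done, _["unwrapped"] = unwrapped,
                          _["k"] = kvec, _["n_processed"] = (double)processed,
                          _["unreached"] = wrap(unreached));
  if (trace) out["order"] = wrap(order_trace);
  return out;
}
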