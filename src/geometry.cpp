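// Geometry kernels: marching-tetrahedra isosurfacing, ray-cast
// point-in-mesh, 26-connected labelling, point-to-mesh distances.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kuhn 6-tet subdivision corner ids (0..7, id = dx + 2 dy + 4 dz)
static const int KUHN[6][4] = {
  {0, 1, 3, 7}, {0, 2, 3, 7}, {0, 1, 5, 7},
  {0, 4, 5, 7}, {0, 2, 6, 7}, {0, 4, 6, 7}};

// iso-surface f = iso of a scalar grid (nx x ny x nz, column-major [x,y,z])
// [[Rcpp::export]]
List cpp_marching_tets(const arma::cube& f, const arma::vec& origin,
                       const arma::vec& spacing, double iso) {
  const int nx = f.n_rows, ny = f.n_cols, nz = f.n_slices;
  std::unordered_map<int64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t(k) * ny + j) * nx + i;
  };
  auto vert_on_edge = [&](int64_t ga, int64_t gb, double va, double vb) -> int {
    if (ga > gb) { std::swap(ga, gb); std::swap(va, vb); }
    int64_t key = ga * int64_t(nx) * ny * nz + gb;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (iso - va) / (vb - va);
    int ia = int(ga % nx), ja = int((ga / nx) % ny), ka = int(ga / (int64_t(nx) * ny));
    int ib = int(gb % nx), jb = int((gb / nx) % ny), kb = int(gb / (int64_t(nx) * ny));
    vx.push_back(origin(0) + spacing(0) * (ia + t * (ib - ia)));
    vy.push_back(origin(1) + spacing(1) * (ja + t * (jb - ja)));
    vz.push_back(origin(2) + spacing(2) * (ka + t * (kb - ka)));
    int id = int(vx.size());  // 1-based
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const arma::vec3& toward_pos) {
    // orient so the normal points toward the positive (f > iso) side
    arma::vec3 A = {vx[a - 1], vy[a - 1], vz[a - 1]};
    arma::vec3 B = {vx[b - 1], vy[b - 1], vz[b - 1]};
    arma::vec3 C = {vx[c - 1], vy[c - 1], vz[c - 1]};
    arma::vec3 n = arma::cross(B - A, C - A);
    if (arma::dot(n, toward_pos) < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };
  int dx[8], dy[8], dz[8];
  for (int c = 0; c < 8; ++c) { dx[c] = c & 1; dy[c] = (c >> 1) & 1; dz[c] = (c >> 2) & 1; }
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cv[8]; int64_t cg[8]; arma::vec3 cp[8];
        for (int c = 0; c < 8; ++c) {
          int ii = i + dx[c], jj = j + dy[c], kk = k + dz[c];
          cv[c] = f(ii, jj, kk);
          cg[c] = gid(ii, jj, kk);
          cp[c] = {origin(0) + spacing(0) * ii, origin(1) + spacing(1) * jj,
                   origin(2) + spacing(2) * kk};
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = KUHN[t];
          bool pos[4]; int npos = 0;
          for (int c = 0; c < 4; ++c) {
            pos[c] = cv[T[c]] > iso;
            if (pos[c]) ++npos;
          }
          if (npos == 0 || npos == 4) continue;
          arma::vec3 pc = {0, 0, 0}; arma::vec3 nc = {0, 0, 0};
          int np = 0, nn = 0;
          for (int c = 0; c < 4; ++c) {
            if (pos[c]) { pc += cp[T[c]]; ++np; } else { nc += cp[T[c]]; ++nn; }
          }
          arma::vec3 toward = pc / np - nc / nn;
          if (npos == 1 || npos == 3) {
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if (pos[c] == (npos == 1)) lone = c;
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != lone) others[no++] = c;
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = vert_on_edge(cg[T[lone]], cg[T[others[c]]],
                                  cv[T[lone]], cv[T[others[c]]]);
            emit(e[0], e[1], e[2], toward);
          } else {  // 2-2 case: quad
            int p[2], q[2], np2 = 0, nq2 = 0;
            for (int c = 0; c < 4; ++c)
              if (pos[c]) p[np2++] = c; else q[nq2++] = c;
            int e00 = vert_on_edge(cg[T[p[0]]], cg[T[q[0]]], cv[T[p[0]]], cv[T[q[0]]]);
            int e01 = vert_on_edge(cg[T[p[0]]], cg[T[q[1]]], cv[T[p[0]]], cv[T[q[1]]]);
            int e10 = vert_on_edge(cg[T[p[1]]], cg[T[q[0]]], cv[T[p[1]]], cv[T[q[0]]]);
            int e11 = vert_on_edge(cg[T[p[1]]], cg[T[q[1]]], cv[T[p[1]]], cv[T[q[1]]]);
            emit(e00, e01, e11, toward);
            emit(e00, e11, e10, toward);
          }
        }
      }
  int nv = int(vx.size()), nt = int(tri.size() / 3);
  arma::mat V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  arma::imat Tm(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int c = 0; c < 3; ++c) Tm(i, c) = tri[3 * i + c];
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// ray-cast containment (even-odd, ray along ~+z), 2D xy-binned
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(const arma::mat& pts, const arma::mat& V,
                                 const arma::imat& Tr) {
  const int np = pts.n_rows, nt = Tr.n_rows;
  LogicalVector inside(np);
  // xy bins
  double xmin = V.col(0).min(), xmax = V.col(0).max();
  double ymin = V.col(1).min(), ymax = V.col(1).max();
  int nb = std::max(1, int(std::sqrt(double(nt) / 4.0)));
  double bx = (xmax - xmin) / nb + 1e-300, by = (ymax - ymin) / nb + 1e-300;
  std::vector<std::vector<int>> bins(size_t(nb) * nb);
  auto bin_of = [&](double x, double y) -> std::pair<int, int> {
    int ix = std::min(nb - 1, std::max(0, int((x - xmin) / bx)));
    int iy = std::min(nb - 1, std::max(0, int((y - ymin) / by)));
    return {ix, iy};
  };
  for (int t = 0; t < nt; ++t) {
    double txmin = 1e300, txmax = -1e300, tymin = 1e300, tymax = -1e300;
    for (int c = 0; c < 3; ++c) {
      txmin = std::min(txmin, V(Tr(t, c) - 1, 0));
      txmax = std::max(txmax, V(Tr(t, c) - 1, 0));
      tymin = std::min(tymin, V(Tr(t, c) - 1, 1));
      tymax = std::max(tymax, V(Tr(t, c) - 1, 1));
    }
    auto lo = bin_of(txmin, tymin), hi = bin_of(txmax, tymax);
    for (int ix = lo.first; ix <= hi.first; ++ix)
      for (int iy = lo.second; iy <= hi.second; ++iy)
        bins[size_t(iy) * nb + ix].push_back(t);
  }
  const arma::vec3 dir = {7.3e-5, 3.1e-5, 1.0};  // degeneracy-avoiding tilt
  for (int p = 0; p < np; ++p) {
    arma::vec3 o = pts.row(p).t();
    auto b = bin_of(o(0), o(1));
    int cross = 0;
    for (int t : bins[size_t(b.second) * nb + b.first]) {
      arma::vec3 A = V.row(Tr(t, 0) - 1).t(), B = V.row(Tr(t, 1) - 1).t(),
                 C = V.row(Tr(t, 2) - 1).t();
      arma::vec3 e1 = B - A, e2 = C - A;
      arma::vec3 h = arma::cross(dir, e2);
      double det = arma::dot(e1, h);
      if (std::abs(det) < 1e-14) continue;
      arma::vec3 s = o - A;
      double u = arma::dot(s, h) / det;
      if (u < 0 || u > 1) continue;
      arma::vec3 q = arma::cross(s, e1);
      double v = arma::dot(dir, q) / det;
      if (v < 0 || u + v > 1) continue;
      double tt = arma::dot(e2, q) / det;
      if (tt > 1e-12) ++cross;
    }
    inside[p] = (cross % 2) == 1;
  }
  return inside;
}

// 26-connected component labelling of a logical 3D array
// [[Rcpp::export]]
IntegerVector cpp_label_components_3d(const LogicalVector& mask,
                                      const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector labels(mask.size(), 0);
  auto idx = [&](int i, int j, int k) { return (int64_t(k) * ny + j) * nx + i; };
  int cur = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int64_t id0 = idx(i, j, k);
        if (!mask[id0] || labels[id0]) continue;
        ++cur;
        labels[id0] = cur;
        q.push({i, j, k});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                int ii = c[0] + di, jj = c[1] + dj, kk = c[2] + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                  continue;
                int64_t id = idx(ii, jj, kk);
                if (mask[id] && !labels[id]) {
                  labels[id] = cur;
                  q.push({ii, jj, kk});
                }
              }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}

static arma::vec3 closest_pt_tri(const arma::vec3& p, const arma::vec3& A,
                                 const arma::vec3& B, const arma::vec3& C) {
  arma::vec3 ab = B - A, ac = C - A, ap = p - A;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return A;
  arma::vec3 bp = p - B;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return B;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return A + (d1 / (d1 - d3)) * ab;
  arma::vec3 cp = p - C;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return C;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return A + (d2 / (d2 - d6)) * ac;
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return B + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (C - B);
  double denom = 1.0 / (va + vb + vc);
  return A + ab * (vb * denom) + ac * (vc * denom);
}

// unsigned distance from each point to a triangle mesh
// [[Rcpp::export]]
arma::vec cpp_point_mesh_distance(const arma::mat& pts, const arma::mat& V,
                                  const arma::imat& Tr) {
  const int np = pts.n_rows, nt = Tr.n_rows;
  arma::vec out(np);
  arma::mat lo(nt, 3), hi(nt, 3);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) {
      double a = V(Tr(t, 0) - 1, c), b = V(Tr(t, 1) - 1, c),
             d = V(Tr(t, 2) - 1, c);
      lo(t, c) = std::min({a, b, d});
      hi(t, c) = std::max({a, b, d});
    }
  for (int p = 0; p < np; ++p) {
    arma::vec3 pt = pts.row(p).t();
    double best = arma::datum::inf;
    for (int t = 0; t < nt; ++t) {
      double lb = 0;
      for (int c = 0; c < 3; ++c) {
        if (pt(c) < lo(t, c)) lb += (lo(t, c) - pt(c)) * (lo(t, c) - pt(c));
        else if (pt(c) > hi(t, c)) lb += (pt(c) - hi(t, c)) * (pt(c) - hi(t, c));
      }
      if (lb >= best * best) continue;
      arma::vec3 cp = closest_pt_tri(pt, V.row(Tr(t, 0) - 1).t(),
                                     V.row(Tr(t, 1) - 1).t(),
                                     V.row(Tr(t, 2) - 1).t());
      double d = arma::norm(pt - cp);
      if (d < best) best = d;
    }
    out(p) = best;
  }
  return out;
}

// signed distance to an oriented point cloud (Hoppe-style): for each query,
// find the k nearest cloud points via a spatial grid and return the
// Gaussian-weighted mean of their tangent-plane signed distances
// [[Rcpp::export]]
arma::vec cpp_oriented_cloud_sdf(const arma::mat& q, const arma::mat& pts,
                                 const arma::mat& normals, int k,
                                 double cell) {
  const int nq = q.n_rows, np = pts.n_rows;
  arma::vec out(nq);
  std::unordered_map<int64_t, std::vector<int>> grid;
  auto key = [](int ix, int iy, int iz) {
    // collision-free packing for |index| < 2^20
    return ((int64_t(ix) + (1LL << 20)) << 42) |
           ((int64_t(iy) + (1LL << 20)) << 21) |
           (int64_t(iz) + (1LL << 20));
  };
  auto cix = [&](double v) { return int(std::floor(v / cell)); };
  for (int p = 0; p < np; ++p)
    grid[key(cix(pts(p, 0)), cix(pts(p, 1)), cix(pts(p, 2)))].push_back(p);
  for (int i = 0; i < nq; ++i) {
    arma::vec3 x = q.row(i).t();
    int cx = cix(x(0)), cy = cix(x(1)), cz = cix(x(2));
    std::vector<std::pair<double, int>> found;
    int stop_ring = -1;
    for (int ring = 0; ring < 512; ++ring) {
      for (int ix = cx - ring; ix <= cx + ring; ++ix)
        for (int iy = cy - ring; iy <= cy + ring; ++iy)
          for (int iz = cz - ring; iz <= cz + ring; ++iz) {
            if (std::max({std::abs(ix - cx), std::abs(iy - cy),
                          std::abs(iz - cz)}) != ring) continue;
            auto it = grid.find(key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int p : it->second) {
              double d2 = arma::accu(arma::square(pts.row(p).t() - x));
              found.push_back({d2, p});
            }
          }
      // once enough hits, search one extra ring for boundary safety
      if (stop_ring < 0 && int(found.size()) >= k) stop_ring = ring + 1;
      if (stop_ring >= 0 && ring >= stop_ring) break;
    }
    if (found.empty()) { out(i) = arma::datum::inf; continue; }
    std::partial_sort(found.begin(),
                      found.begin() + std::min<size_t>(k, found.size()),
                      found.end());
    int kk = std::min<size_t>(k, found.size());
    double h2 = std::max(found[kk - 1].first, 1e-12);
    double wsum = 0, fsum = 0;
    for (int j = 0; j < kk; ++j) {
      int p = found[j].second;
      double w = std::exp(-found[j].first / h2);
      arma::vec3 d = x - pts.row(p).t();
      fsum += w * arma::dot(d, normals.row(p).t());
      wsum += w;
    }
    out(i) = fsum / wsum;
  }
  return out;
}

// first-hit distance of rays against a triangle mesh (Inf if no hit);
// also returns the hit triangle index (0 if none)
// [[Rcpp::export]]
List cpp_ray_mesh_intersect(const arma::mat& origins, const arma::mat& dirs,
                            const arma::mat& V, const arma::imat& Tr) {
  const int nr = origins.n_rows, nt = Tr.n_rows;
  arma::vec dist(nr, arma::fill::value(arma::datum::inf));
  arma::ivec hit(nr, arma::fill::zeros);
  for (int r = 0; r < nr; ++r) {
    arma::vec3 o = origins.row(r).t(), d = dirs.row(r).t();
    for (int t = 0; t < nt; ++t) {
      arma::vec3 A = V.row(Tr(t, 0) - 1).t(), B = V.row(Tr(t, 1) - 1).t(),
                 C = V.row(Tr(t, 2) - 1).t();
      arma::vec3 e1 = B - A, e2 = C - A;
      arma::vec3 h = arma::cross(d, e2);
      double det = arma::dot(e1, h);
      if (std::abs(det) < 1e-14) continue;
      arma::vec3 s = o - A;
      double u = arma::dot(s, h) / det;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      arma::vec3 qv = arma::cross(s, e1);
      double v = arma::dot(d, qv) / det;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double tt = arma::dot(e2, qv) / det;
      if (tt > 1e-9 && tt < dist(r)) { dist(r) = tt; hit(r) = t + 1; }
    }
  }
  return List::create(_["distance"] = dist, _["triangle"] = hit);
}

// Euclidean distance from each query to the nearest cloud point
// [[Rcpp::export]]
arma::vec cpp_nn_distance(const arma::mat& q, const arma::mat& pts,
                          double cell) {
  const int nq = q.n_rows, np = pts.n_rows;
  arma::vec out(nq);
  std::unordered_map<int64_t, std::vector<int>> grid;
  auto key = [](int ix, int iy, int iz) {
    // collision-free packing for |index| < 2^20
    return ((int64_t(ix) + (1LL << 20)) << 42) |
           ((int64_t(iy) + (1LL << 20)) << 21) |
           (int64_t(iz) + (1LL << 20));
  };
  auto cix = [&](double v) { return int(std::floor(v / cell)); };
  for (int p = 0; p < np; ++p)
    grid[key(cix(pts(p, 0)), cix(pts(p, 1)), cix(pts(p, 2)))].push_back(p);
  for (int i = 0; i < nq; ++i) {
    arma::vec3 x = q.row(i).t();
    int cx = cix(x(0)), cy = cix(x(1)), cz = cix(x(2));
    double best = arma::datum::inf;
    bool found_any = false;
    for (int ring = 0; ring < 256; ++ring) {
      for (int ix = cx - ring; ix <= cx + ring; ++ix)
        for (int iy = cy - ring; iy <= cy + ring; ++iy)
          for (int iz = cz - ring; iz <= cz + ring; ++iz) {
            if (std::max({std::abs(ix - cx), std::abs(iy - cy),
                          std::abs(iz - cz)}) != ring) continue;
            auto it = grid.find(key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int p : it->second) {
              double d = arma::norm(pts.row(p).t() - x);
              if (d < best) { best = d; found_any = true; }
            }
          }
      // a later ring cannot beat `best` once ring > best/cell + 1
      if (found_any && cell * (ring - 1) > best) break;
    }
    out(i) = best;
  }
  return out;
}
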