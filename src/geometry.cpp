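#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Separable truncated-Gaussian smoothing of a 3D scalar field (column-major),
// sigma in voxel units, zero (background) boundary condition. Callers pad the
// foreground away from the border first.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) { k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + rad]; }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  std::vector<double> a(arr.begin(), arr.end()), b(a.size(), 0.0);
  auto idx = [&](int i, int j, int l) { return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * l); };

  // x pass
  for (int l = 0; l < nz; ++l) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    double acc = 0.0;
    for (int o = -rad; o <= rad; ++o) { int ii = i + o; if (ii >= 0 && ii < nx) acc += k[o + rad] * a[idx(ii, j, l)]; }
    b[idx(i, j, l)] = acc;
  }
  std::swap(a, b);
  // y pass
  for (int l = 0; l < nz; ++l) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    double acc = 0.0;
    for (int o = -rad; o <= rad; ++o) { int jj = j + o; if (jj >= 0 && jj < ny) acc += k[o + rad] * a[idx(i, jj, l)]; }
    b[idx(i, j, l)] = acc;
  }
  std::swap(a, b);
  // z pass
  for (int l = 0; l < nz; ++l) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    double acc = 0.0;
    for (int o = -rad; o <= rad; ++o) { int ll = l + o; if (ll >= 0 && ll < nz) acc += k[o + rad] * a[idx(i, j, ll)]; }
    b[idx(i, j, l)] = acc;
  }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Marching tetrahedra at iso-level `iso`. Each grid cube is split into six
// tetrahedra sharing the main diagonal, so faces interior to the grid are
// decomposed identically in both adjacent cubes and the resulting surface is
// watertight by construction. Iso-crossing vertices live on grid edges and are
// deduplicated by the (sorted) pair of grid-node linear indices, giving an
// indexed mesh in which every edge is shared by exactly two faces. Triangles
// are wound so normals point from foreground (> iso) to background.
static const int CORN[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
};

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dim, double iso,
                             NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto lin = [&](int i, int j, int l) { return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * l); };
  const uint64_t ntot = (uint64_t)nx * ny * nz;

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;          // vertex coords (grid units)
  std::vector<int> f0, f1, f2;             // 0-based face indices

  // vertex on grid edge (a,b): linear interpolation to the iso level
  auto edge_vertex = [&](uint64_t la, uint64_t lb, const double *pa, const double *pb,
                         double va, double vb) -> int {
    uint64_t key = (la < lb) ? la * ntot + lb : lb * ntot + la;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    // canonical endpoint order so shared edges interpolate identically
    const double *p1 = pa, *p2 = pb; double u1 = va, u2 = vb;
    if (la > lb) { p1 = pb; p2 = pa; u1 = vb; u2 = va; }
    double t = (iso - u1) / (u2 - u1);
    int id = (int)vx.size();
    vx.push_back(p1[0] + t * (p2[0] - p1[0]));
    vy.push_back(p1[1] + t * (p2[1] - p1[1]));
    vz.push_back(p1[2] + t * (p2[2] - p1[2]));
    vmap.emplace(key, id);
    return id;
  };

  // emit triangle (v0,v1,v2); ref = a point strictly inside (above iso);
  // flip so the normal points away from ref
  auto emit = [&](int a, int b, int c, const double *ref) {
    double e1x = vx[b] - vx[a], e1y = vy[b] - vy[a], e1z = vz[b] - vz[a];
    double e2x = vx[c] - vx[a], e2y = vy[c] - vy[a], e2z = vz[c] - vz[a];
    double nxn = e1y * e2z - e1z * e2y;
    double nyn = e1z * e2x - e1x * e2z;
    double nzn = e1x * e2y - e1y * e2x;
    double d = nxn * (vx[a] - ref[0]) + nyn * (vy[a] - ref[1]) + nzn * (vz[a] - ref[2]);
    if (d < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  double pts[8][3]; double vals[8]; uint64_t lins[8];
  for (int l = 0; l < nz - 1; ++l)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CORN[c][0], jj = j + CORN[c][1], ll = l + CORN[c][2];
          lins[c] = lin(ii, jj, ll);
          vals[c] = field[lins[c]];
          pts[c][0] = ii; pts[c][1] = jj; pts[c][2] = ll;
          if (vals[c] > iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (vals[id[c]] > iso) ins[ni++] = id[c]; else outs[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;
          auto ev = [&](int a, int b) {
            return edge_vertex(lins[a], lins[b], pts[a], pts[b], vals[a], vals[b]);
          };
          if (ni == 1) {
            int a = ins[0];
            emit(ev(a, outs[0]), ev(a, outs[1]), ev(a, outs[2]), pts[a]);
          } else if (ni == 3) {
            int b = outs[0];
            // normal must point toward the single outside corner: use each
            // inside corner? one inside ref suffices (mean of inside corners)
            double ref[3] = {
              (pts[ins[0]][0] + pts[ins[1]][0] + pts[ins[2]][0]) / 3.0,
              (pts[ins[0]][1] + pts[ins[1]][1] + pts[ins[2]][1]) / 3.0,
              (pts[ins[0]][2] + pts[ins[1]][2] + pts[ins[2]][2]) / 3.0 };
            emit(ev(ins[0], b), ev(ins[1], b), ev(ins[2], b), ref);
          } else { // 2 in, 2 out -> quad
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int p1 = ev(a, c), p2 = ev(a, d), p3 = ev(b, d), p4 = ev(b, c);
            double ref[3] = {
              (pts[a][0] + pts[b][0]) / 2.0,
              (pts[a][1] + pts[b][1]) / 2.0,
              (pts[a][2] + pts[b][2]) / 2.0 };
            emit(p1, p2, p3, ref);
            emit(p1, p3, p4, ref);
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = origin[0] + vx[v] * spacing[0];
    V(v, 1) = origin[1] + vy[v] * spacing[1];
    V(v, 2) = origin[2] + vz[v] * spacing[2];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) { F(f, 0) = f0[f] + 1; F(f, 1) = f1[f] + 1; F(f, 2) = f2[f] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// 26-connected component labelling of a binary 3D array (column-major).
// Labels are assigned in increasing order of the component's smallest linear
// voxel index (scan order), so label 1 is the component whose seed has the
// lowest linear index.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab(ntot);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < ntot; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, l = cur / ((size_t)nx * ny);
      for (int dl = -1; dl <= 1; ++dl) for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dl) continue;
        int ii = i + di, jj = j + dj, ll = l + dl;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || ll < 0 || ll >= nz) continue;
        size_t q = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * ll);
        if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
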