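// Marching tetrahedra over a regular grid of scalar field samples.
// Each grid cell is split into 6 tetrahedra sharing the cell's main diagonal,
// so neighbouring cells agree on shared faces and the extracted isosurface of
// a field that is negative inside and positive outside is watertight and
// consistently oriented (normals point towards positive field values).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct MeshAccum {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

inline uint64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint32_t>(b);
}

// interpolated zero crossing on the grid edge (a, b)
inline int edge_point(MeshAccum& acc, int a, int b, const NumericVector& f,
                      const std::vector<double>& gx,
                      const std::vector<double>& gy,
                      const std::vector<double>& gz) {
  uint64_t key = edge_key(a, b);
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double fa = f[a], fb = f[b];
  double t = fa / (fa - fb);
  if (t < 1e-8) t = 1e-8;           // keep vertices distinct from grid nodes
  if (t > 1.0 - 1e-8) t = 1.0 - 1e-8;
  int idx = static_cast<int>(acc.vx.size());
  acc.vx.push_back(gx[a] + t * (gx[b] - gx[a]));
  acc.vy.push_back(gy[a] + t * (gy[b] - gy[a]));
  acc.vz.push_back(gz[a] + t * (gz[b] - gz[a]));
  acc.edge_vertex.emplace(key, idx);
  return idx;
}

inline void emit(MeshAccum& acc, int p0, int p1, int p2,
                 double ix, double iy, double iz) {
  // orient so the normal points away from the interior reference point
  double ax = acc.vx[p1] - acc.vx[p0], ay = acc.vy[p1] - acc.vy[p0],
         az = acc.vz[p1] - acc.vz[p0];
  double bx = acc.vx[p2] - acc.vx[p0], by = acc.vy[p2] - acc.vy[p0],
         bz = acc.vz[p2] - acc.vz[p0];
  double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
  double dx = acc.vx[p0] - ix, dy = acc.vy[p0] - iy, dz = acc.vz[p0] - iz;
  if (nx * dx + ny * dy + nz * dz < 0.0) std::swap(p1, p2);
  acc.tri.push_back(p0 + 1);
  acc.tri.push_back(p1 + 1);
  acc.tri.push_back(p2 + 1);
}

inline void do_tet(MeshAccum& acc, const int v[4], const NumericVector& f,
                   const std::vector<double>& gx, const std::vector<double>& gy,
                   const std::vector<double>& gz) {
  bool neg[4];
  int nneg = 0;
  for (int i = 0; i < 4; ++i) {
    neg[i] = f[v[i]] < 0.0;
    if (neg[i]) ++nneg;
  }
  if (nneg == 0 || nneg == 4) return;
  if (nneg == 1 || nneg == 3) {
    // single vertex on the minority side: one triangle
    bool minority_neg = (nneg == 1);
    int apex = -1, others[3], no = 0;
    for (int i = 0; i < 4; ++i) {
      if (neg[i] == minority_neg) apex = v[i];
      else others[no++] = v[i];
    }
    // interior reference: a negative grid node of this tet
    int inner = minority_neg ? apex : others[0];
    if (!minority_neg) {
      for (int i = 0; i < 4; ++i) if (neg[i]) { inner = v[i]; break; }
    }
    int p0 = edge_point(acc, apex, others[0], f, gx, gy, gz);
    int p1 = edge_point(acc, apex, others[1], f, gx, gy, gz);
    int p2 = edge_point(acc, apex, others[2], f, gx, gy, gz);
    emit(acc, p0, p1, p2, gx[inner], gy[inner], gz[inner]);
  } else {
    // 2-2 split: quad, two triangles
    int a[2], b[2], na = 0, nb = 0;
    for (int i = 0; i < 4; ++i) {
      if (neg[i]) a[na++] = v[i];
      else b[nb++] = v[i];
    }
    int p00 = edge_point(acc, a[0], b[0], f, gx, gy, gz);
    int p01 = edge_point(acc, a[0], b[1], f, gx, gy, gz);
    int p10 = edge_point(acc, a[1], b[0], f, gx, gy, gz);
    int p11 = edge_point(acc, a[1], b[1], f, gx, gy, gz);
    emit(acc, p00, p01, p11, gx[a[0]], gy[a[0]], gz[a[0]]);
    emit(acc, p00, p11, p10, gx[a[0]], gy[a[0]], gz[a[0]]);
  }
}

}  // namespace

// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(NumericVector f, NumericVector xs, NumericVector ys,
                   NumericVector zs) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  if (static_cast<R_xlen_t>(nx) * ny * nz != f.size())
    stop("field length does not match grid dimensions");
  // grid node coordinates, flattened with x fastest (R array order)
  const R_xlen_t n = f.size();
  std::vector<double> gx(n), gy(n), gz(n);
  R_xlen_t id = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++id) {
        gx[id] = xs[i];
        gy[id] = ys[j];
        gz[id] = zs[k];
      }
  MeshAccum acc;
  // 6-tet decomposition of the cube (c0..c7), all sharing diagonal c0-c7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  const int dx = 1, dy = nx, dz = nx * ny;
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      R_xlen_t base = static_cast<R_xlen_t>(k) * dz + static_cast<R_xlen_t>(j) * dy;
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t c0 = base + i;
        int corner[8] = {
          static_cast<int>(c0),           static_cast<int>(c0 + dx),
          static_cast<int>(c0 + dy),      static_cast<int>(c0 + dx + dy),
          static_cast<int>(c0 + dz),      static_cast<int>(c0 + dx + dz),
          static_cast<int>(c0 + dy + dz), static_cast<int>(c0 + dx + dy + dz)};
        // quick reject: all same sign
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          if (f[corner[c]] < 0.0) any_neg = true; else any_pos = true;
        }
        if (!any_neg || !any_pos) continue;
        for (int t = 0; t < 6; ++t) {
          int v[4] = {corner[tets[t][0]], corner[tets[t][1]],
                      corner[tets[t][2]], corner[tets[t][3]]};
          do_tet(acc, v, f, gx, gy, gz);
        }
      }
    }
  }
  const int nv = static_cast<int>(acc.vx.size());
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = acc.vx[i];
    V(i, 1) = acc.vy[i];
    V(i, 2) = acc.vz[i];
  }
  const int nf = static_cast<int>(acc.tri.size() / 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = acc.tri[3 * i];
    F(i, 1) = acc.tri[3 * i + 1];
    F(i, 2) = acc.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
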