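// Isosurface extraction by a marching-cubes variant: each voxel cell is split
// into six tetrahedra (Kuhn triangulation around the main diagonal), the level
// set is linearly interpolated along tetrahedron edges, and vertices are
// welded through an edge-keyed map so the output is watertight wherever the
// surface does not hit the volume boundary. The decomposition is translation
// consistent, so shared cube faces triangulate identically in both cells and
// no ambiguity cases arise.
//
// Vertices are returned in continuous voxel-index coordinates (0-based);
// physical spacing and origin are applied on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// offsets of the 8 cube corners
const int CORNER[8][3] = {
  {0, 0, 0},  // 0
  {1, 0, 0},  // 1
  {1, 1, 0},  // 2
  {0, 1, 0},  // 3
  {0, 0, 1},  // 4
  {1, 0, 1},  // 5
  {1, 1, 1},  // 6
  {0, 1, 1},  // 7
};

// six tetrahedra sharing the 0-6 main diagonal
const int TETS[6][4] = {
  {0, 1, 2, 6},
  {0, 2, 3, 6},
  {0, 3, 7, 6},
  {0, 7, 4, 6},
  {0, 4, 5, 6},
  {0, 5, 1, 6},
};

struct MarchState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, int nx, int ny, int nz, double level) {
  auto node_id = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  auto val = [&](int64_t id) -> double { return vals[id]; };

  MarchState st;
  st.edge_vertex.reserve(1 << 16);

  // interpolated vertex on the grid edge (na, nb); welded globally
  auto edge_point = [&](int64_t na, int64_t nb, double va, double vb) -> int {
    if (na > nb) { std::swap(na, nb); std::swap(va, vb); }
    uint64_t key = ((uint64_t)na << 32) ^ (uint64_t)nb;
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int ai = (int)(na % nx), aj = (int)((na / nx) % ny), ak = (int)(na / ((int64_t)nx * ny));
    int bi = (int)(nb % nx), bj = (int)((nb / nx) % ny), bk = (int)(nb / ((int64_t)nx * ny));
    int id = (int)st.vx.size();
    st.vx.push_back(ai + t * (bi - ai));
    st.vy.push_back(aj + t * (bj - aj));
    st.vz.push_back(ak + t * (bk - ak));
    st.edge_vertex[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, double inx, double iny, double inz) {
    // orient so the normal points away from the inside (>= level) corners
    double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
    double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double area2 = nxv * nxv + nyv * nyv + nzv * nzv;
    if (area2 < 1e-24) return;  // degenerate sliver (level hits grid nodes)
    double dx = inx - st.vx[a], dy = iny - st.vy[a], dz = inz - st.vz[a];
    if (nxv * dx + nyv * dy + nzv * dz > 0) std::swap(b, c);
    st.f0.push_back(a + 1);
    st.f1.push_back(b + 1);
    st.f2.push_back(c + 1);
  };

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        int64_t nid[8];
        double v[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          nid[c] = node_id(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]);
          v[c] = val(nid[c]);
          (v[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int tc[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], outs[4];
          int nin = 0, nout = 0;
          for (int m = 0; m < 4; ++m) {
            if (v[tc[m]] >= level) ins[nin++] = tc[m];
            else outs[nout++] = tc[m];
          }
          if (nin == 0 || nin == 4) continue;
          // centroid of inside corners, for orientation
          double inx = 0, iny = 0, inz = 0;
          for (int m = 0; m < nin; ++m) {
            inx += i + CORNER[ins[m]][0];
            iny += j + CORNER[ins[m]][1];
            inz += k + CORNER[ins[m]][2];
          }
          inx /= nin; iny /= nin; inz /= nin;
          if (nin == 1) {
            int a = edge_point(nid[ins[0]], nid[outs[0]], v[ins[0]], v[outs[0]]);
            int b = edge_point(nid[ins[0]], nid[outs[1]], v[ins[0]], v[outs[1]]);
            int c = edge_point(nid[ins[0]], nid[outs[2]], v[ins[0]], v[outs[2]]);
            emit(a, b, c, inx, iny, inz);
          } else if (nin == 3) {
            int a = edge_point(nid[ins[0]], nid[outs[0]], v[ins[0]], v[outs[0]]);
            int b = edge_point(nid[ins[1]], nid[outs[0]], v[ins[1]], v[outs[0]]);
            int c = edge_point(nid[ins[2]], nid[outs[0]], v[ins[2]], v[outs[0]]);
            emit(a, b, c, inx, iny, inz);
          } else {  // 2 in, 2 out: quad across four crossed edges
            int a = edge_point(nid[ins[0]], nid[outs[0]], v[ins[0]], v[outs[0]]);
            int b = edge_point(nid[ins[0]], nid[outs[1]], v[ins[0]], v[outs[1]]);
            int c = edge_point(nid[ins[1]], nid[outs[1]], v[ins[1]], v[outs[1]]);
            int d = edge_point(nid[ins[1]], nid[outs[0]], v[ins[1]], v[outs[0]]);
            emit(a, b, c, inx, iny, inz);
            emit(a, c, d, inx, iny, inz);
          }
        }
      }
    }
  }

  int nvert = (int)st.vx.size();
  NumericMatrix V(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    V(i, 0) = st.vx[i];
    V(i, 1) = st.vy[i];
    V(i, 2) = st.vz[i];
  }
  int nface = (int)st.f0.size();
  IntegerMatrix F(nface, 3);
  for (int f = 0; f < nface; ++f) {
    F(f, 0) = st.f0[f];
    F(f, 1) = st.f1[f];
    F(f, 2) = st.f2[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
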