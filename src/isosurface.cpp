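#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>

using namespace Rcpp;

// Isosurface of a binary voxel field at level 0.5 by marching tetrahedra.
// Each grid cell is split into the six Kuhn tetrahedra around the main
// diagonal; the split is translation-invariant, so shared cell faces are
// triangulated identically and the surface is watertight. Surface vertices
// sit on grid edges joining an inside (1) and outside (0) sample, at the
// midpoint (linear interpolation of a binary field at iso 0.5).

static const int KUHN_TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

// cube corner offsets (x, y, z)
static const int CORNER[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static int edge_midpoint(MeshAccum &m, int64_t ga, int64_t gb,
                         const double *pa, const double *pb) {
  uint64_t lo = (uint64_t)std::min(ga, gb);
  uint64_t hi = (uint64_t)std::max(ga, gb);
  uint64_t key = (lo << 32) | hi;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  int id = (int)m.vx.size();
  m.vx.push_back(0.5 * (pa[0] + pb[0]));
  m.vy.push_back(0.5 * (pa[1] + pb[1]));
  m.vz.push_back(0.5 * (pa[2] + pb[2]));
  m.edge_vertex.emplace(key, id);
  return id;
}

// orient triangle (a,b,c) so its normal points from inside toward outside
static void push_triangle(MeshAccum &m, int a, int b, int c,
                          const double *dir_out) {
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double d = nx * dir_out[0] + ny * dir_out[1] + nz * dir_out[2];
  if (d >= 0) { m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c); }
  else        { m.f0.push_back(a); m.f1.push_back(c); m.f2.push_back(b); }
}

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int *msk = LOGICAL(mask);
  MeshAccum m;

  auto lin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  double cpos[8][3];
  int cval[8];
  int64_t cidx[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int any1 = 0, any0 = 0;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CORNER[c][0], jj = j + CORNER[c][1], kk = k + CORNER[c][2];
          cidx[c] = lin(ii, jj, kk);
          cval[c] = msk[cidx[c]] ? 1 : 0;
          cpos[c][0] = ii * sx; cpos[c][1] = jj * sy; cpos[c][2] = kk * sz;
          if (cval[c]) any1 = 1; else any0 = 1;
        }
        if (!any1 || !any0) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = KUHN_TETS[t];
          int in[4], nin = 0, nout = 0, iin[4], iout[4];
          for (int v = 0; v < 4; ++v) {
            in[v] = cval[T[v]];
            if (in[v]) iin[nin++] = T[v]; else iout[nout++] = T[v];
          }
          if (nin == 0 || nin == 4) continue;

          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int v = 0; v < nin; ++v)
            for (int d = 0; d < 3; ++d) cin[d] += cpos[iin[v]][d] / nin;
          for (int v = 0; v < nout; ++v)
            for (int d = 0; d < 3; ++d) cout[d] += cpos[iout[v]][d] / nout;
          double dir_out[3] = {cout[0] - cin[0], cout[1] - cin[1], cout[2] - cin[2]};

          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? iin[0] : iout[0];
            const int *others = (nin == 1) ? iout : iin;
            int p[3];
            for (int v = 0; v < 3; ++v)
              p[v] = edge_midpoint(m, cidx[apex], cidx[others[v]],
                                   cpos[apex], cpos[others[v]]);
            push_triangle(m, p[0], p[1], p[2], dir_out);
          } else { // nin == 2: quad m(a,c) m(a,d) m(b,d) m(b,c)
            int a = iin[0], b = iin[1], c = iout[0], d = iout[1];
            int mac = edge_midpoint(m, cidx[a], cidx[c], cpos[a], cpos[c]);
            int mad = edge_midpoint(m, cidx[a], cidx[d], cpos[a], cpos[d]);
            int mbd = edge_midpoint(m, cidx[b], cidx[d], cpos[b], cpos[d]);
            int mbc = edge_midpoint(m, cidx[b], cidx[c], cpos[b], cpos[c]);
            push_triangle(m, mac, mad, mbd, dir_out);
            push_triangle(m, mac, mbd, mbc, dir_out);
          }
        }
      }

  int V = (int)m.vx.size(), F = (int)m.f0.size();
  NumericMatrix verts(V, 3);
  IntegerMatrix faces(F, 3);
  for (int v = 0; v < V; ++v) {
    verts(v, 0) = m.vx[v]; verts(v, 1) = m.vy[v]; verts(v, 2) = m.vz[v];
  }
  for (int f = 0; f < F; ++f) {
    faces(f, 0) = m.f0[f] + 1; faces(f, 1) = m.f1[f] + 1; faces(f, 2) = m.f2[f] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
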