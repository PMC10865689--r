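#include <Rcpp.h>
#include <vector>
#include <array>
#include <set>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Quadric error-metric edge-collapse decimation (Garland-Heckbert).
// Collapses the cheapest valid edge until the requested vertex count is
// reached; the link condition and a normal-flip test keep the mesh a closed
// 2-manifold, so genus-0 inputs keep Euler characteristic 2.

typedef std::array<double, 10> Quad; // upper triangle of symmetric 4x4

static inline void quad_add(Quad &a, const Quad &b) {
  for (int i = 0; i < 10; ++i) a[i] += b[i];
}

static inline double quad_eval(const Quad &q, double x, double y, double z) {
  return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
       + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
       + q[7]*z*z + 2*q[8]*z + q[9];
}

struct Cand {
  double cost; int i, j, si, sj;
  bool operator<(const Cand &o) const { return cost > o.cost; } // min-heap
};

struct Mesh {
  std::vector<std::array<double,3> > pos;
  std::vector<std::array<int,3> > face;
  std::vector<bool> vdead, fdead;
  std::vector<std::set<int> > vfaces;
  std::vector<Quad> Q;
  std::vector<int> stamp;
};

static void face_normal(const Mesh &m, const std::array<int,3> &f,
                        double out[3]) {
  const double *a = m.pos[f[0]].data(), *b = m.pos[f[1]].data(),
               *c = m.pos[f[2]].data();
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  out[0] = u[1]*w[2] - u[2]*w[1];
  out[1] = u[2]*w[0] - u[0]*w[2];
  out[2] = u[0]*w[1] - u[1]*w[0];
}

static Quad face_quadric(const Mesh &m, const std::array<int,3> &f) {
  double n[3];
  face_normal(m, f, n);
  double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  Quad q; q.fill(0.0);
  if (len < 1e-300) return q;
  double area = 0.5 * len;
  for (int d = 0; d < 3; ++d) n[d] /= len;
  const double *a = m.pos[f[0]].data();
  double dpl = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
  double p[4] = {n[0], n[1], n[2], dpl};
  int idx = 0;
  for (int r = 0; r < 4; ++r)
    for (int c = r; c < 4; ++c) q[idx++] = area * p[r] * p[c];
  return q;
}

// optimal collapse target for quadric q, falling back to endpoints/midpoint
static void optimal_point(const Quad &q, const double *vi, const double *vj,
                          double out[3]) {
  double A[9] = {q[0], q[1], q[2], q[1], q[4], q[5], q[2], q[5], q[7]};
  double b[3] = {-q[3], -q[6], -q[8]};
  double det = A[0]*(A[4]*A[8]-A[5]*A[7]) - A[1]*(A[3]*A[8]-A[5]*A[6])
             + A[2]*(A[3]*A[7]-A[4]*A[6]);
  double scale = std::fabs(q[0]) + std::fabs(q[4]) + std::fabs(q[7]) + 1e-300;
  if (std::fabs(det) > 1e-10 * scale * scale * scale) {
    out[0] = (b[0]*(A[4]*A[8]-A[5]*A[7]) - A[1]*(b[1]*A[8]-A[5]*b[2])
              + A[2]*(b[1]*A[7]-A[4]*b[2])) / det;
    out[1] = (A[0]*(b[1]*A[8]-b[2]*A[5]) - b[0]*(A[3]*A[8]-A[5]*A[6])
              + A[2]*(A[3]*b[2]-b[1]*A[6])) / det;
    out[2] = (A[0]*(A[4]*b[2]-A[7]*b[1]) - A[1]*(A[3]*b[2]-b[1]*A[6])
              + b[0]*(A[3]*A[7]-A[4]*A[6])) / det;
    return;
  }
  double mid[3] = {0.5*(vi[0]+vj[0]), 0.5*(vi[1]+vj[1]), 0.5*(vi[2]+vj[2])};
  const double *cands[3] = {vi, vj, mid};
  double best = R_PosInf;
  for (int c = 0; c < 3; ++c) {
    double e = quad_eval(q, cands[c][0], cands[c][1], cands[c][2]);
    if (e < best) { best = e; out[0] = cands[c][0]; out[1] = cands[c][1]; out[2] = cands[c][2]; }
  }
}

static void vertex_neighbors(const Mesh &m, int v, std::set<int> &nb) {
  nb.clear();
  for (std::set<int>::const_iterator it = m.vfaces[v].begin();
       it != m.vfaces[v].end(); ++it) {
    const std::array<int,3> &f = m.face[*it];
    for (int k = 0; k < 3; ++k) if (f[k] != v) nb.insert(f[k]);
  }
}

// [[Rcpp::export(name = ".cpp_decimate_quadric")]]
List cpp_decimate_quadric(NumericMatrix vertices, IntegerMatrix faces,
                          int target_vertices) {
  Mesh m;
  int V = vertices.nrow(), F = faces.nrow();
  m.pos.resize(V); m.vdead.assign(V, false); m.vfaces.resize(V);
  m.Q.assign(V, Quad()); m.stamp.assign(V, 0);
  for (int v = 0; v < V; ++v) {
    m.pos[v][0] = vertices(v,0); m.pos[v][1] = vertices(v,1); m.pos[v][2] = vertices(v,2);
    m.Q[v].fill(0.0);
  }
  m.face.resize(F); m.fdead.assign(F, false);
  for (int f = 0; f < F; ++f) {
    for (int k = 0; k < 3; ++k) {
      m.face[f][k] = faces(f,k) - 1;
      m.vfaces[m.face[f][k]].insert(f);
    }
    Quad q = face_quadric(m, m.face[f]);
    for (int k = 0; k < 3; ++k) quad_add(m.Q[m.face[f][k]], q);
  }

  std::priority_queue<Cand> pq;
  std::set<std::pair<int,int> > edges;
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < 3; ++k) {
      int a = m.face[f][k], b = m.face[f][(k+1)%3];
      if (a > b) std::swap(a, b);
      edges.insert(std::make_pair(a, b));
    }
  for (std::set<std::pair<int,int> >::iterator it = edges.begin();
       it != edges.end(); ++it) {
    int i = it->first, j = it->second;
    Quad q = m.Q[i]; quad_add(q, m.Q[j]);
    double p[3];
    optimal_point(q, m.pos[i].data(), m.pos[j].data(), p);
    Cand c = {quad_eval(q, p[0], p[1], p[2]), i, j, 0, 0};
    pq.push(c);
  }

  int live = V;
  std::set<int> nbi, nbj;
  while (live > target_vertices && !pq.empty()) {
    Cand c = pq.top(); pq.pop();
    int i = c.i, j = c.j;
    if (m.vdead[i] || m.vdead[j]) continue;
    if (c.si != m.stamp[i] || c.sj != m.stamp[j]) continue;

    // shared faces and link condition
    std::vector<int> shared;
    for (std::set<int>::iterator it = m.vfaces[i].begin();
         it != m.vfaces[i].end(); ++it)
      if (m.vfaces[j].count(*it)) shared.push_back(*it);
    if (shared.size() != 2) continue; // boundary or non-manifold edge
    vertex_neighbors(m, i, nbi);
    vertex_neighbors(m, j, nbj);
    int ncommon = 0;
    for (std::set<int>::iterator it = nbi.begin(); it != nbi.end(); ++it)
      if (nbj.count(*it)) ++ncommon;
    if (ncommon != 2) continue; // collapsing would pinch the surface

    Quad q = m.Q[i]; quad_add(q, m.Q[j]);
    double p[3];
    optimal_point(q, m.pos[i].data(), m.pos[j].data(), p);

    // normal-flip test on surviving faces around i and j
    bool flip = false;
    for (int side = 0; side < 2 && !flip; ++side) {
      int v = side == 0 ? i : j;
      for (std::set<int>::iterator it = m.vfaces[v].begin();
           it != m.vfaces[v].end() && !flip; ++it) {
        if (std::find(shared.begin(), shared.end(), *it) != shared.end()) continue;
        double n0[3], n1[3];
        std::array<int,3> f = m.face[*it];
        face_normal(m, f, n0);
        std::array<double,3> save = m.pos[v];
        m.pos[v][0] = p[0]; m.pos[v][1] = p[1]; m.pos[v][2] = p[2];
        face_normal(m, f, n1);
        m.pos[v] = save;
        double d = n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2];
        double l0 = std::sqrt(n0[0]*n0[0]+n0[1]*n0[1]+n0[2]*n0[2]);
        double l1 = std::sqrt(n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2]);
        if (l1 < 1e-14 || d < 1e-10 * l0 * l1) flip = true;
      }
    }
    if (flip) continue;

    // collapse j into i
    m.pos[i][0] = p[0]; m.pos[i][1] = p[1]; m.pos[i][2] = p[2];
    quad_add(m.Q[i], m.Q[j]);
    for (size_t s = 0; s < shared.size(); ++s) {
      int f = shared[s];
      m.fdead[f] = true;
      for (int k = 0; k < 3; ++k) m.vfaces[m.face[f][k]].erase(f);
    }
    std::vector<int> jf(m.vfaces[j].begin(), m.vfaces[j].end());
    for (size_t s = 0; s < jf.size(); ++s) {
      int f = jf[s];
      for (int k = 0; k < 3; ++k) if (m.face[f][k] == j) m.face[f][k] = i;
      m.vfaces[j].erase(f);
      m.vfaces[i].insert(f);
    }
    m.vdead[j] = true;
    ++m.stamp[i]; ++m.stamp[j];
    --live;

    vertex_neighbors(m, i, nbi);
    for (std::set<int>::iterator it = nbi.begin(); it != nbi.end(); ++it) {
      int k = *it;
      if (m.vdead[k]) continue;
      int a = std::min(i, k), b = std::max(i, k);
      Quad qq = m.Q[a]; quad_add(qq, m.Q[b]);
      double pp[3];
      optimal_point(qq, m.pos[a].data(), m.pos[b].data(), pp);
      Cand nc = {quad_eval(qq, pp[0], pp[1], pp[2]), a, b, m.stamp[a], m.stamp[b]};
      pq.push(nc);
    }
  }

  std::vector<int> remap(V, -1);
  int nv = 0;
  for (int v = 0; v < V; ++v) if (!m.vdead[v]) remap[v] = nv++;
  int nf = 0;
  for (int f = 0; f < F; ++f) if (!m.fdead[f]) ++nf;
  NumericMatrix outv(nv, 3);
  IntegerMatrix outf(nf, 3);
  for (int v = 0; v < V; ++v)
    if (!m.vdead[v])
      for (int d = 0; d < 3; ++d) outv(remap[v], d) = m.pos[v][d];
  int fi = 0;
  for (int f = 0; f < F; ++f)
    if (!m.fdead[f]) {
      for (int k = 0; k < 3; ++k) outf(fi, k) = remap[m.face[f][k]] + 1;
      ++fi;
    }
  return List::create(_["vertices"] = outv, _["faces"] = outf,
                      _["reached"] = live);
}
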