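// Isosurface extraction by marching tetrahedra.
//
// Each grid cell (the cube spanned by 8 neighbouring voxel centres) is split
// into six tetrahedra around the main diagonal; this decomposition induces
// matching triangle diagonals on the shared faces of neighbouring cells, so
// the extracted surface is watertight. Vertices lie on tetrahedron edges where
// the field crosses the level, placed by linear interpolation, and are
// deduplicated through a global edge table. Deterministic for fixed input.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <functional>

using namespace Rcpp;

#define IDX(i, j, k) ((i) + nx * ((j) + (size_t)ny * (k)))

// six tetrahedra around the cube diagonal corner0 - corner7
static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

// [[Rcpp::export]]
List cpp_isosurface(NumericVector f, IntegerVector dim, double dx, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* fp = REAL(f);
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  size_t n = (size_t)nx * ny * nz;
  // values shifted so that exact hits of the level are treated as inside
  std::vector<double> val(n);
  for (size_t t = 0; t < n; ++t) {
    double v = fp[t] - level;
    val[t] = (v == 0.0) ? 1e-300 : v;
  }

  auto vertex_on_edge = [&](size_t g0, size_t g1) -> int {
    uint64_t key = (g0 < g1) ? ((uint64_t)g0 << 32 | g1) : ((uint64_t)g1 << 32 | g0);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double f0 = val[g0], f1 = val[g1];
    double t = f0 / (f0 - f1);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double x0 = ((double)(g0 % nx) + 0.5) * dx;
    double y0 = ((double)((g0 / nx) % ny) + 0.5) * dx;
    double z0 = ((double)(g0 / ((size_t)nx * ny)) + 0.5) * dx;
    double x1 = ((double)(g1 % nx) + 0.5) * dx;
    double y1 = ((double)((g1 / nx) % ny) + 0.5) * dx;
    double z1 = ((double)(g1 / ((size_t)nx * ny)) + 0.5) * dx;
    int id = (int)vx.size();
    vx.push_back(x0 + t * (x1 - x0));
    vy.push_back(y0 + t * (y1 - y0));
    vz.push_back(z0 + t * (z1 - z0));
    edge_vertex.emplace(key, id);
    return id;
  };

  size_t corner[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        corner[0] = IDX(i, j, k);
        corner[1] = IDX(i + 1, j, k);
        corner[2] = IDX(i, j + 1, k);
        corner[3] = IDX(i + 1, j + 1, k);
        corner[4] = IDX(i, j, k + 1);
        corner[5] = IDX(i + 1, j, k + 1);
        corner[6] = IDX(i, j + 1, k + 1);
        corner[7] = IDX(i + 1, j + 1, k + 1);
        for (int t = 0; t < 6; ++t) {
          size_t g[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            g[c] = corner[TETS[t][c]];
            in[c] = val[g[c]] > 0;
            nin += in[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // one corner apart: a single triangle
            bool lone_in = (nin == 1);
            int apex = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == lone_in) apex = c;
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) others[m++] = c;
            int a = vertex_on_edge(g[apex], g[others[0]]);
            int b = vertex_on_edge(g[apex], g[others[1]]);
            int cdx = vertex_on_edge(g[apex], g[others[2]]);
            tri.push_back(a); tri.push_back(b); tri.push_back(cdx);
          } else {
            // 2-2 split: quad cut, two triangles
            int ins[2], outs[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c)
              (in[c] ? ins[mi++] : outs[mo++]) = c;
            int a = vertex_on_edge(g[ins[0]], g[outs[0]]);
            int b = vertex_on_edge(g[ins[0]], g[outs[1]]);
            int c2 = vertex_on_edge(g[ins[1]], g[outs[1]]);
            int d2 = vertex_on_edge(g[ins[1]], g[outs[0]]);
            tri.push_back(a); tri.push_back(b); tri.push_back(c2);
            tri.push_back(a); tri.push_back(c2); tri.push_back(d2);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int q = 0; q < nv; ++q) {
    verts(q, 0) = vx[q];
    verts(q, 1) = vy[q];
    verts(q, 2) = vz[q];
  }
  IntegerMatrix faces(nf, 3);
  for (int q = 0; q < nf; ++q) {
    faces(q, 0) = tri[3 * q] + 1;
    faces(q, 1) = tri[3 * q + 1] + 1;
    faces(q, 2) = tri[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Connected components of a vertex subset over the mesh edges (union-find).
// keep: logical per vertex; returns 0 for dropped vertices, else a component
// label (1-based, root index).
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix faces, LogicalVector keep) {
  int n = keep.size();
  std::vector<int> parent(n);
  for (int q = 0; q < n; ++q) parent[q] = q;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  int nf = faces.nrow();
  for (int q = 0; q < nf; ++q) {
    int vv[3] = {faces(q, 0) - 1, faces(q, 1) - 1, faces(q, 2) - 1};
    for (int e = 0; e < 3; ++e) {
      int a = vv[e], b = vv[(e + 1) % 3];
      if (!keep[a] || !keep[b]) continue;
      int ra = find(a), rb = find(b);
      if (ra != rb) parent[ra] = rb;
    }
  }
  IntegerVector out(n);
  for (int q = 0; q < n; ++q) out[q] = keep[q] ? find(q) + 1 : 0;
  return out;
}
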