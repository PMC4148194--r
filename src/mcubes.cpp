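// Marching cubes on boolean occupancy with linear edge interpolation.
//
// The 256-entry case table is generated at first use rather than copied from
// a reference listing.  Construction: on every cube face (viewed from outside
// the cube, corners in counter-clockwise order) each maximal run of inside
// corners contributes one directed segment from its entering crossing edge to
// its leaving crossing edge.  Because the rule is face-local and both cubes
// sharing a face see the same segment pairing, adjacent cubes always agree on
// ambiguous (saddle) faces and the assembled surface is watertight.  Segments
// chain into closed loops over the cube's crossing edges; each loop is fanned
// into triangles whose right-hand-rule normals point from the inside region
// to the outside.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// corner c has lattice offset ((c&1), (c>>1)&1, (c>>2)&1)
static const int EDGE_CORNERS[12][2] = {
  {0,1},{2,3},{4,5},{6,7},      // x edges 0-3
  {0,2},{1,3},{4,6},{5,7},      // y edges 4-7
  {0,4},{1,5},{2,6},{3,7}};     // z edges 8-11

// face corner cycles, counter-clockwise as seen from outside the cube
static const int FACE_CYCLE[6][4] = {
  {0,4,6,2},  // x = 0
  {1,3,7,5},  // x = 1
  {0,1,5,4},  // y = 0
  {2,6,7,3},  // y = 1
  {0,2,3,1},  // z = 0
  {4,5,7,6}}; // z = 1

static int edge_between(int a, int b) {
  for (int e = 0; e < 12; ++e) {
    if ((EDGE_CORNERS[e][0] == a && EDGE_CORNERS[e][1] == b) ||
        (EDGE_CORNERS[e][0] == b && EDGE_CORNERS[e][1] == a)) return e;
  }
  return -1;
}

// tri_table[mask] = flat list of edge-id triples
static std::vector<std::vector<int>> tri_table;

static void build_tables() {
  if (!tri_table.empty()) return;
  tri_table.resize(256);
  for (int mask = 0; mask < 256; ++mask) {
    bool in[8];
    for (int c = 0; c < 8; ++c) in[c] = (mask >> c) & 1;
    int succ[12];
    for (int e = 0; e < 12; ++e) succ[e] = -1;
    for (int f = 0; f < 6; ++f) {
      const int* cyc = FACE_CYCLE[f];
      // transitions around the 4-cycle
      int enter[4], leave[4], ne = 0, nl = 0;
      int enter_pos[4], leave_pos[4];
      for (int j = 0; j < 4; ++j) {
        int a = cyc[j], b = cyc[(j + 1) % 4];
        int e = edge_between(a, b);
        if (!in[a] && in[b]) { enter[ne] = e; enter_pos[ne++] = j; }
        if (in[a] && !in[b]) { leave[nl] = e; leave_pos[nl++] = j; }
      }
      // pair each entering crossing with the first leaving crossing ahead
      for (int i = 0; i < ne; ++i) {
        int best = -1, bestd = 99;
        for (int l = 0; l < nl; ++l) {
          int d = (leave_pos[l] - enter_pos[i] + 4) % 4;
          if (d == 0) d = 4; // leave cannot share the position of its enter
          if (d < bestd) { bestd = d; best = l; }
        }
        succ[enter[i]] = leave[best];
      }
    }
    // chain segments into loops, fan each loop
    bool used[12] = {false};
    std::vector<int>& tris = tri_table[mask];
    for (int e0 = 0; e0 < 12; ++e0) {
      if (succ[e0] < 0 || used[e0]) continue;
      std::vector<int> loop;
      int e = e0;
      do { loop.push_back(e); used[e] = true; e = succ[e]; } while (e != e0);
      for (size_t i = 1; i + 1 < loop.size(); ++i) {
        tris.push_back(loop[0]);
        tris.push_back(loop[i]);
        tris.push_back(loop[i + 1]);
      }
    }
  }
}

// Extract the boundary mesh of the occupancy region.  g is an interpolation
// field, positive (>= 0) at inside points and negative outside wherever it is
// consistent with the occupancy; crossing positions fall back to the edge
// midpoint on edges where g disagrees with the occupancy.  Points outside the
// lattice are outside the solid; edges leaving the lattice are cut at the
// boundary lattice point so clipped solids are capped by boundary faces.
// [[Rcpp::export]]
List cpp_marching_cubes(LogicalVector occ, NumericVector g,
                        IntegerVector dims, NumericVector origin,
                        double spacing) {
  build_tables();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double BIG = 1e30;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<long long, int> edge_vertex;

  const long long EN1 = n1 + 2, EN2 = n2 + 2; // extended grid for edge keys

  auto in_range = [&](int i, int j, int k) {
    return i >= 0 && i < n1 && j >= 0 && j < n2 && k >= 0 && k < n3;
  };
  auto occ_at = [&](int i, int j, int k) -> bool {
    if (!in_range(i, j, k)) return false;
    return occ[(long long)i + (long long)n1 * (j + (long long)n2 * k)] != 0;
  };
  auto g_at = [&](int i, int j, int k) -> double {
    if (!in_range(i, j, k)) return -BIG;
    return g[(long long)i + (long long)n1 * (j + (long long)n2 * k)];
  };

  for (int k = -1; k < n3; ++k)
  for (int j = -1; j < n2; ++j)
  for (int i = -1; i < n1; ++i) {
    int mask = 0;
    for (int c = 0; c < 8; ++c) {
      if (occ_at(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1)))
        mask |= (1 << c);
    }
    if (mask == 0 || mask == 255) continue;
    const std::vector<int>& tt = tri_table[mask];
    for (size_t t = 0; t < tt.size(); ++t) {
      int e = tt[t];
      int ca = EDGE_CORNERS[e][0], cb = EDGE_CORNERS[e][1];
      int ia = i + (ca & 1), ja = j + ((ca >> 1) & 1), ka = k + ((ca >> 2) & 1);
      int ib = i + (cb & 1), jb = j + ((cb >> 1) & 1), kb = k + ((cb >> 2) & 1);
      int axis = e < 4 ? 0 : (e < 8 ? 1 : 2);
      // canonical key on the smaller endpoint of the lattice edge
      long long li = (ia + 1) + EN1 * ((ja + 1) + EN2 * (long long)(ka + 1));
      long long key = 3 * li + axis;
      int vid;
      std::unordered_map<long long, int>::iterator it = edge_vertex.find(key);
      if (it != edge_vertex.end()) {
        vid = it->second;
      } else {
        bool a_in = occ_at(ia, ja, ka);
        // order endpoints: p1 inside, p2 outside
        int i1 = ia, j1 = ja, k1 = ka, i2 = ib, j2 = jb, k2 = kb;
        if (!a_in) { std::swap(i1, i2); std::swap(j1, j2); std::swap(k1, k2); }
        double g1 = g_at(i1, j1, k1), g2 = g_at(i2, j2, k2);
        double tpar = 0.5;
        if (g1 >= 0.0 && g2 < 0.0) {
          tpar = g1 / (g1 - g2);
          if (tpar < 0.0) tpar = 0.0;
          if (tpar > 1.0) tpar = 1.0;
        }
        vx.push_back(origin[0] + spacing * (i1 + tpar * (i2 - i1)));
        vy.push_back(origin[1] + spacing * (j1 + tpar * (j2 - j1)));
        vz.push_back(origin[2] + spacing * (k1 + tpar * (k2 - k1)));
        vid = (int)vx.size() - 1;
        edge_vertex[key] = vid;
      }
      tri.push_back(vid);
    }
  }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0) = vx[v]; V(v,1) = vy[v]; V(v,2) = vz[v]; }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t,0) = tri[3*t] + 1; T(t,1) = tri[3*t+1] + 1; T(t,2) = tri[3*t+2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// min_i (|p - x_i| - r_i - inflate) at every lattice point
// [[Rcpp::export]]
NumericVector cpp_balls_distance(NumericMatrix xyz, NumericVector radii,
                                 double inflate, NumericVector origin,
                                 double spacing, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int na = xyz.nrow();
  NumericVector out((long long)n1 * n2 * n3);
  long long idx = 0;
  for (int k = 0; k < n3; ++k) {
    double pz = origin[2] + spacing * k;
    for (int j = 0; j < n2; ++j) {
      double py = origin[1] + spacing * j;
      for (int i = 0; i < n1; ++i, ++idx) {
        double px = origin[0] + spacing * i;
        double best = R_PosInf;
        for (int a = 0; a < na; ++a) {
          double dx = px - xyz(a,0), dy = py - xyz(a,1), dz = pz - xyz(a,2);
          double d = std::sqrt(dx*dx + dy*dy + dz*dz) - radii[a] - inflate;
          if (d < best) best = d;
        }
        out[idx] = best;
      }
    }
  }
  return out;
}

// Separable lower-envelope transform (Felzenszwalb & Huttenlocher):
// out(p) = min_q ( |p - q|^2 + f(q) ), squared distances in Angstrom^2.
// INF entries in f are admissible (sites that do not compete).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = -1; // first finite site
  for (int q = 0; q < n; ++q) if (R_finite(f[q])) { q0 = q; break; }
  if (q0 < 0) { for (int q = 0; q < n; ++q) d[q] = R_PosInf; return; }
  int kk = 0;
  v[0] = q0; z[0] = -R_PosInf; z[1] = R_PosInf;
  for (int q = q0 + 1; q < n; ++q) {
    if (!R_finite(f[q])) continue;
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + h2 * q * (double)q) - (f[p] + h2 * p * (double)p)) /
          (2.0 * h2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q; z[kk] = s; z[kk + 1] = R_PosInf;
  }
  int m = 0;
  for (int q = 0; q < n; ++q) {
    while (z[m + 1] < q) ++m;
    double dq = (double)(q - v[m]);
    d[q] = h2 * dq * dq + f[v[m]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_power_transform(NumericVector f, IntegerVector dims,
                                  double spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double h2 = spacing * spacing;
  std::vector<double> buf(f.begin(), f.end());
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> line(nmax), dl(nmax);
  // x pass
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      long long base = (long long)n1 * (j + (long long)n2 * k);
      for (int i = 0; i < n1; ++i) line[i] = buf[base + i];
      dt1d(line, dl, n1, h2);
      for (int i = 0; i < n1; ++i) buf[base + i] = dl[i];
    }
  // y pass
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j)
        line[j] = buf[i + (long long)n1 * (j + (long long)n2 * k)];
      dt1d(line, dl, n2, h2);
      for (int j = 0; j < n2; ++j)
        buf[i + (long long)n1 * (j + (long long)n2 * k)] = dl[j];
    }
  // z pass
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k)
        line[k] = buf[i + (long long)n1 * (j + (long long)n2 * k)];
      dt1d(line, dl, n3, h2);
      for (int k = 0; k < n3; ++k)
        buf[i + (long long)n1 * (j + (long long)n2 * k)] = dl[k];
    }
  return NumericVector(buf.begin(), buf.end());
}

// Occupancy of lattice points against a closed mesh by ray-parity, one axis
// ray per (j,k) column with a small deterministic offset to dodge degenerate
// hits on vertices and edges.
// [[Rcpp::export]]
LogicalVector cpp_point_in_mesh(NumericMatrix V, IntegerMatrix T,
                                NumericVector origin, double spacing,
                                IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nt = T.nrow();
  LogicalVector out((long long)n1 * n2 * n3);
  const double ey = 0.371 * spacing * 1e-3, ez = 0.613 * spacing * 1e-3;

  // bin triangles by the (j,k) columns their yz bounding box covers
  std::vector<std::vector<int>> bins((size_t)n2 * n3);
  for (int t = 0; t < nt; ++t) {
    double ylo = R_PosInf, yhi = R_NegInf, zlo = R_PosInf, zhi = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      double y = V(T(t,c) - 1, 1), z = V(T(t,c) - 1, 2);
      if (y < ylo) ylo = y; if (y > yhi) yhi = y;
      if (z < zlo) zlo = z; if (z > zhi) zhi = z;
    }
    int j0 = (int)std::floor((ylo - ey - origin[1]) / spacing);
    int j1 = (int)std::ceil ((yhi - ey - origin[1]) / spacing);
    int k0 = (int)std::floor((zlo - ez - origin[2]) / spacing);
    int k1 = (int)std::ceil ((zhi - ez - origin[2]) / spacing);
    if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (j1 > n2 - 1) j1 = n2 - 1; if (k1 > n3 - 1) k1 = n3 - 1;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)j + (size_t)n2 * k].push_back(t);
  }

  std::vector<double> xs;
  for (int k = 0; k < n3; ++k)
  for (int j = 0; j < n2; ++j) {
    const std::vector<int>& tl = bins[(size_t)j + (size_t)n2 * k];
    if (tl.empty()) continue;
    double ry = origin[1] + spacing * j + ey;
    double rz = origin[2] + spacing * k + ez;
    xs.clear();
    for (size_t u = 0; u < tl.size(); ++u) {
      int t = tl[u];
      double x0 = V(T(t,0)-1,0), y0 = V(T(t,0)-1,1), z0 = V(T(t,0)-1,2);
      double x1 = V(T(t,1)-1,0), y1 = V(T(t,1)-1,1), z1 = V(T(t,1)-1,2);
      double x2 = V(T(t,2)-1,0), y2 = V(T(t,2)-1,1), z2 = V(T(t,2)-1,2);
      // 2D barycentric point-in-triangle in the yz plane
      double d = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
      if (d == 0.0) continue; // ray parallel to triangle plane edge-on
      double a = ((ry - y0) * (z2 - z0) - (rz - z0) * (y2 - y0)) / d;
      double b = ((y1 - y0) * (rz - z0) - (z1 - z0) * (ry - y0)) / d;
      if (a < 0.0 || b < 0.0 || a + b > 1.0) continue;
      xs.push_back(x0 + a * (x1 - x0) + b * (x2 - x0));
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (int i = 0; i < n1; ++i) {
      double px = origin[0] + spacing * i;
      int cnt = (int)(std::lower_bound(xs.begin(), xs.end(), px) - xs.begin());
      if (cnt & 1)
        out[(long long)i + (long long)n1 * (j + (long long)n2 * k)] = true;
    }
  }
  return out;
}

static double point_triangle_dist2(double px, double py, double pz,
                                   const double* a, const double* b,
                                   const double* c) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {px-a[0], py-a[1], pz-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx=a[0]; qy=a[1]; qz=a[2]; goto done; }
  {
    double bp[3] = {px-b[0], py-b[1], pz-b[2]};
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { qx=b[0]; qy=b[1]; qz=b[2]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      qx=a[0]+v*ab[0]; qy=a[1]+v*ab[1]; qz=a[2]+v*ab[2]; goto done;
    }
    double cp[3] = {px-c[0], py-c[1], pz-c[2]};
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0 && d5 <= d6) { qx=c[0]; qy=c[1]; qz=c[2]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      qx=a[0]+w*ac[0]; qy=a[1]+w*ac[1]; qz=a[2]+w*ac[2]; goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      qx=b[0]+w*(c[0]-b[0]); qy=b[1]+w*(c[1]-b[1]); qz=b[2]+w*(c[2]-b[2]);
      goto done;
    }
    double den = 1.0 / (va + vb + vc);
    double v = vb * den, w = vc * den;
    qx = a[0] + ab[0]*v + ac[0]*w;
    qy = a[1] + ab[1]*v + ac[1]*w;
    qz = a[2] + ab[2]*v + ac[2]*w;
  }
done:
  double dx = px-qx, dy = py-qy, dz = pz-qz;
  return dx*dx + dy*dy + dz*dz;
}

// Signed distance to the mesh at lattice points adjacent to an occupancy
// change (positive inside); +/- 1e9 elsewhere.  Used as the interpolation
// field when a solid is rebuilt from a mesh.
// [[Rcpp::export]]
NumericVector cpp_mesh_signed_near(NumericMatrix V, IntegerMatrix T,
                                   LogicalVector occ, NumericVector origin,
                                   double spacing, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int nt = T.nrow();
  const double BIGD = 1e9;
  NumericVector out((long long)n1 * n2 * n3);
  std::vector<double> tv(nt * 9);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d)
        tv[9*t + 3*c + d] = V(T(t,c) - 1, d);

  auto occ_at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) return false;
    return occ[(long long)i + (long long)n1 * (j + (long long)n2 * k)] != 0;
  };
  long long idx = 0;
  for (int k = 0; k < n3; ++k)
  for (int j = 0; j < n2; ++j)
  for (int i = 0; i < n1; ++i, ++idx) {
    bool o = occ_at(i, j, k);
    bool near = false;
    if (occ_at(i-1,j,k) != o || occ_at(i+1,j,k) != o ||
        occ_at(i,j-1,k) != o || occ_at(i,j+1,k) != o ||
        occ_at(i,j,k-1) != o || occ_at(i,j,k+1) != o) near = true;
    if (!near) { out[idx] = o ? BIGD : -BIGD; continue; }
    double px = origin[0] + spacing * i;
    double py = origin[1] + spacing * j;
    double pz = origin[2] + spacing * k;
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      double d2 = point_triangle_dist2(px, py, pz, &tv[9*t], &tv[9*t+3],
                                       &tv[9*t+6]);
      if (d2 < best) best = d2;
    }
    double d = std::sqrt(best);
    // points exactly on the mesh count as boundary: keep the outside value
    // strictly negative so edge interpolation lands on the surface
    out[idx] = o ? d : -std::max(d, 1e-9);
  }
  return out;
}

// for each atom of A, minimum distance to any atom of B
// [[Rcpp::export]]
NumericVector cpp_min_cross_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = A(i,0)-B(j,0), dy = A(i,1)-B(j,1), dz = A(i,2)-B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
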