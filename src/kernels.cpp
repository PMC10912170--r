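#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <queue>
#include <limits>

using namespace Rcpp;

// Axis order convention: R arrays are dim = c(n1, n2, n3) = (z, y, x),
// column-major, so linear index = i1 + n1*(i2 + n2*i3) (0-based).
// World coordinates are voxel centers at (i + 0.5) * spacing per axis,
// reported as (z, y, x) in micrometres.

static inline int64_t lidx(int i1, int i2, int i3, int n1, int n2) {
  return (int64_t)i1 + (int64_t)n1 * ((int64_t)i2 + (int64_t)n2 * (int64_t)i3);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Freudenthal/Kuhn 6-tet cube subdivision.
// Globally consistent across cubes, hence watertight; vertices are deduped
// by the lattice edge they lie on.
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx;           // vertex coords, (z,y,x) triplets
  std::vector<int> tri;             // triangle vertex indices, 0-based
};

static int edge_point(MTState &st, const NumericVector &field,
                      int64_t a, int64_t b, double level,
                      int n1, int n2, const double *sp) {
  if (a > b) std::swap(a, b);
  uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double fa = field[a], fb = field[b];
  double t = (level - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  // decode lattice coords
  int a1 = (int)(a % n1), a2 = (int)((a / n1) % n2), a3 = (int)(a / ((int64_t)n1 * n2));
  int b1 = (int)(b % n1), b2 = (int)((b / n1) % n2), b3 = (int)(b / ((int64_t)n1 * n2));
  double z = ((a1 + 0.5) + t * (b1 - a1)) * sp[0];
  double y = ((a2 + 0.5) + t * (b2 - a2)) * sp[1];
  double x = ((a3 + 0.5) + t * (b3 - a3)) * sp[2];
  int id = (int)(st.vx.size() / 3);
  st.vx.push_back(z); st.vx.push_back(y); st.vx.push_back(x);
  st.edge_vertex[key] = id;
  return id;
}

static inline void vcoord(const MTState &st, int v, double *out) {
  out[0] = st.vx[3 * v]; out[1] = st.vx[3 * v + 1]; out[2] = st.vx[3 * v + 2];
}

// append triangle (i,j,k), flipped if its normal does not point along dirref
static void push_tri(MTState &st, int i, int j, int k, const double *dirref) {
  double a[3], b[3], c[3];
  vcoord(st, i, a); vcoord(st, j, b); vcoord(st, k, c);
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double n[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
  double d = n[0]*dirref[0] + n[1]*dirref[1] + n[2]*dirref[2];
  if (d >= 0) { st.tri.push_back(i); st.tri.push_back(j); st.tri.push_back(k); }
  else        { st.tri.push_back(i); st.tri.push_back(k); st.tri.push_back(j); }
}

static void latt_coord(int64_t a, int n1, int n2, const double *sp, double *out) {
  int a1 = (int)(a % n1), a2 = (int)((a / n1) % n2), a3 = (int)(a / ((int64_t)n1 * n2));
  out[0] = (a1 + 0.5) * sp[0]; out[1] = (a2 + 0.5) * sp[1]; out[2] = (a3 + 0.5) * sp[2];
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             double level, NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  MTState st;
  // Kuhn triangulation: 6 tets around the main diagonal c000-c111.
  // cube corner k encoded by bits (b1,b2,b3) = offsets along dims 1..3
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  for (int i3 = 0; i3 + 1 < n3; ++i3)
    for (int i2 = 0; i2 + 1 < n2; ++i2)
      for (int i1 = 0; i1 + 1 < n1; ++i1) {
        int64_t corner[8];
        double fval[8];
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          int d1 = k & 1, d2 = (k >> 1) & 1, d3 = (k >> 2) & 1;
          corner[k] = lidx(i1 + d1, i2 + d2, i3 + d3, n1, n2);
          fval[k] = field[corner[k]];
          if (fval[k] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t p[4]; double f[4]; bool in[4]; int nin = 0;
          for (int k = 0; k < 4; ++k) {
            p[k] = corner[tets[t][k]]; f[k] = fval[tets[t][k]];
            in[k] = f[k] >= level; if (in[k]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int k = 0; k < 4; ++k)
              if (in[k] == (nin == 1)) { apex = k; break; }
            int others[3]; int m = 0;
            for (int k = 0; k < 4; ++k) if (k != apex) others[m++] = k;
            int e0 = edge_point(st, field, p[apex], p[others[0]], level, n1, n2, sp);
            int e1 = edge_point(st, field, p[apex], p[others[1]], level, n1, n2, sp);
            int e2 = edge_point(st, field, p[apex], p[others[2]], level, n1, n2, sp);
            double ap[3]; latt_coord(p[apex], n1, n2, sp, ap);
            double a[3], b[3], c[3];
            vcoord(st, e0, a); vcoord(st, e1, b); vcoord(st, e2, c);
            double cen[3] = { (a[0]+b[0]+c[0])/3 - ap[0],
                              (a[1]+b[1]+c[1])/3 - ap[1],
                              (a[2]+b[2]+c[2])/3 - ap[2] };
            if (nin == 3) { cen[0] = -cen[0]; cen[1] = -cen[1]; cen[2] = -cen[2]; }
            // outward: away from the inside apex (nin==1), or toward the
            // outside apex (nin==3) => reference dir points to outside
            push_tri(st, e0, e1, e2, cen);
          } else { // nin == 2: quad split into two triangles
            int ia[2], ob[2]; int mi = 0, mo = 0;
            for (int k = 0; k < 4; ++k) { if (in[k]) ia[mi++] = k; else ob[mo++] = k; }
            int e00 = edge_point(st, field, p[ia[0]], p[ob[0]], level, n1, n2, sp);
            int e01 = edge_point(st, field, p[ia[0]], p[ob[1]], level, n1, n2, sp);
            int e10 = edge_point(st, field, p[ia[1]], p[ob[0]], level, n1, n2, sp);
            int e11 = edge_point(st, field, p[ia[1]], p[ob[1]], level, n1, n2, sp);
            double ci[3], co[3], d0[3], d1[3];
            latt_coord(p[ia[0]], n1, n2, sp, d0); latt_coord(p[ia[1]], n1, n2, sp, d1);
            ci[0] = 0.5*(d0[0]+d1[0]); ci[1] = 0.5*(d0[1]+d1[1]); ci[2] = 0.5*(d0[2]+d1[2]);
            latt_coord(p[ob[0]], n1, n2, sp, d0); latt_coord(p[ob[1]], n1, n2, sp, d1);
            co[0] = 0.5*(d0[0]+d1[0]); co[1] = 0.5*(d0[1]+d1[1]); co[2] = 0.5*(d0[2]+d1[2]);
            double dir[3] = { co[0]-ci[0], co[1]-ci[1], co[2]-ci[2] };
            push_tri(st, e00, e01, e11, dir);
            push_tri(st, e00, e11, e10, dir);
          }
        }
      }
  int nv = (int)(st.vx.size() / 3), nf = (int)(st.tri.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[3*i]; V(i, 1) = st.vx[3*i+1]; V(i, 2) = st.vx[3*i+2];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.tri[3*i] + 1; F(i, 1) = st.tri[3*i+1] + 1; F(i, 2) = st.tri[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, anisotropic spacing. Distance of every voxel to the nearest
// voxel with mask != 0.
// ---------------------------------------------------------------------------

static void dt1d(double *f, double *d, int *v, double *z, int n, double h) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int64_t n = (int64_t)n1 * n2 * n3;
  NumericVector out(n);
  const double BIG = 1e30;
  for (int64_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : BIG;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      int64_t base = lidx(0, i2, i3, n1, n2);
      for (int i1 = 0; i1 < n1; ++i1) f[i1] = out[base + i1];
      dt1d(f.data(), d.data(), v.data(), z.data(), n1, spacing[0]);
      for (int i1 = 0; i1 < n1; ++i1) out[base + i1] = d[i1];
    }
  // axis 2
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i2 = 0; i2 < n2; ++i2) f[i2] = out[lidx(i1, i2, i3, n1, n2)];
      dt1d(f.data(), d.data(), v.data(), z.data(), n2, spacing[1]);
      for (int i2 = 0; i2 < n2; ++i2) out[lidx(i1, i2, i3, n1, n2)] = d[i2];
    }
  // axis 3
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i3 = 0; i3 < n3; ++i3) f[i3] = out[lidx(i1, i2, i3, n1, n2)];
      dt1d(f.data(), d.data(), v.data(), z.data(), n3, spacing[2]);
      for (int i3 = 0; i3 < n3; ++i3) out[lidx(i1, i2, i3, n1, n2)] = d[i3];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Point-to-mesh distance, signed by the generalized winding number
// (negative inside). Also reports the index of the nearest face.
// ---------------------------------------------------------------------------

static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double ac[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double ap[3] = { p[0]-a[0], p[1]-a[1], p[2]-a[2] };
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    double bp[3] = { p[0]-b[0], p[1]-b[1], p[2]-b[2] };
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      q[0]=a[0]+t*ab[0]; q[1]=a[1]+t*ab[1]; q[2]=a[2]+t*ab[2]; goto done;
    }
    double cp[3] = { p[0]-c[0], p[1]-c[1], p[2]-c[2] };
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      q[0]=a[0]+t*ac[0]; q[1]=a[1]+t*ac[1]; q[2]=a[2]+t*ac[2]; goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      q[0]=b[0]+t*(c[0]-b[0]); q[1]=b[1]+t*(c[1]-b[1]); q[2]=b[2]+t*(c[2]-b[2]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double vv = vb * denom, ww = vc * denom;
      q[0]=a[0]+ab[0]*vv+ac[0]*ww; q[1]=a[1]+ab[1]*vv+ac[1]*ww; q[2]=a[2]+ab[2]*vv+ac[2]*ww;
    }
  }
done:
  double dx=p[0]-q[0], dy=p[1]-q[1], dz=p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
List cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  IntegerVector nearest(np);
  NumericVector winding(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    double best = std::numeric_limits<double>::infinity();
    int bestf = NA_INTEGER;
    double wsum = 0.0;
    for (int f = 0; f < nf; ++f) {
      double a[3] = { V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2) };
      double b[3] = { V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2) };
      double c[3] = { V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2) };
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) { best = d2; bestf = f + 1; }
      // solid angle (van Oosterom & Strackee)
      double ra[3] = { a[0]-p[0], a[1]-p[1], a[2]-p[2] };
      double rb[3] = { b[0]-p[0], b[1]-p[1], b[2]-p[2] };
      double rc[3] = { c[0]-p[0], c[1]-p[1], c[2]-p[2] };
      double la = std::sqrt(ra[0]*ra[0]+ra[1]*ra[1]+ra[2]*ra[2]);
      double lb = std::sqrt(rb[0]*rb[0]+rb[1]*rb[1]+rb[2]*rb[2]);
      double lc = std::sqrt(rc[0]*rc[0]+rc[1]*rc[1]+rc[2]*rc[2]);
      double det = ra[0]*(rb[1]*rc[2]-rb[2]*rc[1])
                 - ra[1]*(rb[0]*rc[2]-rb[2]*rc[0])
                 + ra[2]*(rb[0]*rc[1]-rb[1]*rc[0]);
      double den = la*lb*lc + (ra[0]*rb[0]+ra[1]*rb[1]+ra[2]*rb[2])*lc
                 + (rb[0]*rc[0]+rb[1]*rc[1]+rb[2]*rc[2])*la
                 + (rc[0]*ra[0]+rc[1]*ra[1]+rc[2]*ra[2])*lb;
      wsum += 2.0 * std::atan2(det, den);
    }
    double w = wsum / (4.0 * M_PI); // ~1 inside, ~0 outside
    dist[i] = (w > 0.5 ? -1.0 : 1.0) * std::sqrt(best);
    nearest[i] = bestf;
    winding[i] = w;
  }
  return List::create(_["distance"] = dist, _["nearest_face"] = nearest,
                      _["winding"] = winding);
}

// ---------------------------------------------------------------------------
// Connected component labelling, 6-connectivity
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int64_t n = (int64_t)n1 * n2 * n3;
  IntegerVector lab(n);
  int next = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int i1 = (int)(cur % n1), i2 = (int)((cur / n1) % n2), i3 = (int)(cur / ((int64_t)n1 * n2));
      const int off[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
      for (int k = 0; k < 6; ++k) {
        int j1 = i1 + off[k][0], j2 = i2 + off[k][1], j3 = i3 + off[k][2];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        int64_t q = lidx(j1, j2, j3, n1, n2);
        if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with zero padding (used for Gaussian smoothing
// and blob-scale filtering); kernels are applied along dims 1,2,3.
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double> &a, int n1, int n2, int n3,
                      const NumericVector &k, int axis) {
  int kn = k.size(), kh = kn / 2;
  std::vector<double> line;
  if (axis == 0) {
    line.resize(n1);
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2) {
        int64_t base = lidx(0, i2, i3, n1, n2);
        for (int i = 0; i < n1; ++i) line[i] = a[base + i];
        for (int i = 0; i < n1; ++i) {
          double s = 0;
          for (int j = 0; j < kn; ++j) {
            int q = i + j - kh;
            if (q >= 0 && q < n1) s += line[q] * k[j];
          }
          a[base + i] = s;
        }
      }
  } else if (axis == 1) {
    line.resize(n2);
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i1 = 0; i1 < n1; ++i1) {
        for (int i = 0; i < n2; ++i) line[i] = a[lidx(i1, i, i3, n1, n2)];
        for (int i = 0; i < n2; ++i) {
          double s = 0;
          for (int j = 0; j < kn; ++j) {
            int q = i + j - kh;
            if (q >= 0 && q < n2) s += line[q] * k[j];
          }
          a[lidx(i1, i, i3, n1, n2)] = s;
        }
      }
  } else {
    line.resize(n3);
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        for (int i = 0; i < n3; ++i) line[i] = a[lidx(i1, i2, i, n1, n2)];
        for (int i = 0; i < n3; ++i) {
          double s = 0;
          for (int j = 0; j < kn; ++j) {
            int q = i + j - kh;
            if (q >= 0 && q < n3) s += line[q] * k[j];
          }
          a[lidx(i1, i2, i, n1, n2)] = s;
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3d(NumericVector arr, IntegerVector dims,
                             NumericVector k1, NumericVector k2,
                             NumericVector k3) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int64_t n = (int64_t)n1 * n2 * n3;
  std::vector<double> a(n);
  for (int64_t i = 0; i < n; ++i) a[i] = arr[i];
  if (k1.size() > 1 || k1[0] != 1.0) conv_axis(a, n1, n2, n3, k1, 0);
  if (k2.size() > 1 || k2[0] != 1.0) conv_axis(a, n1, n2, n3, k2, 1);
  if (k3.size() > 1 || k3[0] != 1.0) conv_axis(a, n1, n2, n3, k3, 2);
  NumericVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = a[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Accelerated queries used by cohort-scale runs. Same definitions as the
// exact routines above, with spatial culling:
//  - cpp_contact_mask: TRUE iff the point is inside the (star-shaped,
//    closed) mesh or within `delta` of it; uniform grid over faces.
//  - cpp_signed_distance_fast: exact nearest distance via a face-centroid
//    prefilter; sign from the nearest face normal.
// ---------------------------------------------------------------------------

struct FaceGrid {
  double lo[3], h;
  int n[3];
  std::vector<std::vector<int>> cells;
  int cell(int i, int j, int k) const { return i + n[0] * (j + n[1] * k); }
};

static void build_grid(FaceGrid &g, const NumericMatrix &V,
                       const IntegerMatrix &F, double h) {
  double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
  for (int i = 0; i < V.nrow(); ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], V(i,a)); hi[a] = std::max(hi[a], V(i,a));
    }
  for (int a = 0; a < 3; ++a) {
    g.lo[a] = lo[a] - 1e-9;
    g.n[a] = std::max(1, (int)std::ceil((hi[a] - lo[a]) / h) + 1);
  }
  g.h = h;
  g.cells.assign((size_t)g.n[0] * g.n[1] * g.n[2], {});
  for (int f = 0; f < F.nrow(); ++f) {
    double flo[3] = {1e300,1e300,1e300}, fhi[3] = {-1e300,-1e300,-1e300};
    for (int k = 0; k < 3; ++k) {
      int v = F(f,k) - 1;
      for (int a = 0; a < 3; ++a) {
        flo[a] = std::min(flo[a], V(v,a)); fhi[a] = std::max(fhi[a], V(v,a));
      }
    }
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      c0[a] = std::max(0, (int)((flo[a] - g.lo[a]) / h));
      c1[a] = std::min(g.n[a] - 1, (int)((fhi[a] - g.lo[a]) / h));
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          g.cells[g.cell(i, j, k)].push_back(f);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_contact_mask(NumericMatrix P, NumericMatrix V,
                               IntegerMatrix F, double delta) {
  int np = P.nrow(), nv = V.nrow();
  // bounding sphere about the vertex mean
  double c[3] = {0,0,0};
  for (int i = 0; i < nv; ++i) for (int a = 0; a < 3; ++a) c[a] += V(i,a);
  for (int a = 0; a < 3; ++a) c[a] /= nv;
  double rmin = 1e300, rmax = 0;
  for (int i = 0; i < nv; ++i) {
    double d2 = 0;
    for (int a = 0; a < 3; ++a) { double t = V(i,a)-c[a]; d2 += t*t; }
    rmin = std::min(rmin, d2); rmax = std::max(rmax, d2);
  }
  rmin = std::sqrt(rmin); rmax = std::sqrt(rmax);
  double h = std::max(0.5, delta);
  double rq = delta + 1.0;       // candidate radius; grid lookups cover it
  FaceGrid g;
  build_grid(g, V, F, h);
  LogicalVector out(np);
  double d2max = delta * delta;
  std::vector<int> seen(F.nrow(), -1);
  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    double db = std::sqrt((p[0]-c[0])*(p[0]-c[0]) + (p[1]-c[1])*(p[1]-c[1]) +
                          (p[2]-c[2])*(p[2]-c[2]));
    if (db - rmax > delta) { out[i] = false; continue; }
    if (db < rmin) { out[i] = true; continue; }  // inside (star-shaped)
    // exact search over all faces within rq of p (grid cells cover the box
    // [p - rq, p + rq], so every face within rq is examined)
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      c0[a] = std::max(0, (int)((p[a] - rq - g.lo[a]) / g.h));
      c1[a] = std::min(g.n[a] - 1, (int)((p[a] + rq - g.lo[a]) / g.h));
    }
    double best = 1e300; int bf = -1;
    bool hit = false;
    for (int k = c0[2]; k <= c1[2] && !hit; ++k)
      for (int j = c0[1]; j <= c1[1] && !hit; ++j)
        for (int ii = c0[0]; ii <= c1[0] && !hit; ++ii) {
          const std::vector<int> &fl = g.cells[g.cell(ii, j, k)];
          for (int t : fl) {
            if (seen[t] == i) continue;
            seen[t] = i;
            double a_[3] = { V(F(t,0)-1,0), V(F(t,0)-1,1), V(F(t,0)-1,2) };
            double b_[3] = { V(F(t,1)-1,0), V(F(t,1)-1,1), V(F(t,1)-1,2) };
            double cc[3] = { V(F(t,2)-1,0), V(F(t,2)-1,1), V(F(t,2)-1,2) };
            double d2 = point_tri_dist2(p, a_, b_, cc);
            if (d2 < best) { best = d2; bf = t; }
            if (best <= d2max) { hit = true; break; }
          }
        }
    if (hit) { out[i] = true; continue; }
    if (bf < 0 || std::sqrt(best) > rq) {
      // no face within the query radius: decide by a full scan (rare; only
      // for shapes whose interior is far from every face)
      best = 1e300; bf = 0;
      for (int t = 0; t < F.nrow(); ++t) {
        double a_[3] = { V(F(t,0)-1,0), V(F(t,0)-1,1), V(F(t,0)-1,2) };
        double b_[3] = { V(F(t,1)-1,0), V(F(t,1)-1,1), V(F(t,1)-1,2) };
        double cc[3] = { V(F(t,2)-1,0), V(F(t,2)-1,1), V(F(t,2)-1,2) };
        double d2 = point_tri_dist2(p, a_, b_, cc);
        if (d2 < best) { best = d2; bf = t; }
      }
      if (best <= d2max) { out[i] = true; continue; }
    }
    // nearest face is exact here; inside (behind its outward normal) counts
    double a_[3] = { V(F(bf,0)-1,0), V(F(bf,0)-1,1), V(F(bf,0)-1,2) };
    double b_[3] = { V(F(bf,1)-1,0), V(F(bf,1)-1,1), V(F(bf,1)-1,2) };
    double cc[3] = { V(F(bf,2)-1,0), V(F(bf,2)-1,1), V(F(bf,2)-1,2) };
    double u[3] = { b_[0]-a_[0], b_[1]-a_[1], b_[2]-a_[2] };
    double w[3] = { cc[0]-a_[0], cc[1]-a_[1], cc[2]-a_[2] };
    double nrm[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    double dp = (p[0]-a_[0])*nrm[0] + (p[1]-a_[1])*nrm[1] + (p[2]-a_[2])*nrm[2];
    out[i] = dp < 0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_signed_distance_fast(NumericMatrix P, NumericMatrix V,
                              IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> fc(3 * nf), fr(nf);
  for (int f = 0; f < nf; ++f) {
    double a_[3] = { V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2) };
    double b_[3] = { V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2) };
    double cc[3] = { V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2) };
    double r2 = 0;
    for (int a = 0; a < 3; ++a) {
      fc[3*f+a] = (a_[a] + b_[a] + cc[a]) / 3.0;
      double t1 = a_[a]-fc[3*f+a], t2 = b_[a]-fc[3*f+a], t3 = cc[a]-fc[3*f+a];
      r2 += std::max(t1*t1, std::max(t2*t2, t3*t3));
    }
    fr[f] = std::sqrt(r2);
  }
  double rmaxf = 0;
  for (int f = 0; f < nf; ++f) rmaxf = std::max(rmaxf, fr[f]);
  NumericVector dist(np);
  IntegerVector nearest(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    double bestc = 1e300;
    for (int f = 0; f < nf; ++f) {
      double d2 = 0;
      for (int a = 0; a < 3; ++a) { double t = p[a]-fc[3*f+a]; d2 += t*t; }
      if (d2 < bestc) bestc = d2;
    }
    double bound = std::sqrt(bestc) + 2.0 * rmaxf;
    double best = 1e300; int bf = 0;
    for (int f = 0; f < nf; ++f) {
      double d2 = 0;
      for (int a = 0; a < 3; ++a) { double t = p[a]-fc[3*f+a]; d2 += t*t; }
      if (std::sqrt(d2) - fr[f] > bound) continue;
      double a_[3] = { V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2) };
      double b_[3] = { V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2) };
      double cc[3] = { V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2) };
      double d2e = point_tri_dist2(p, a_, b_, cc);
      if (d2e < best) { best = d2e; bf = f; }
    }
    double a_[3] = { V(F(bf,0)-1,0), V(F(bf,0)-1,1), V(F(bf,0)-1,2) };
    double b_[3] = { V(F(bf,1)-1,0), V(F(bf,1)-1,1), V(F(bf,1)-1,2) };
    double cc[3] = { V(F(bf,2)-1,0), V(F(bf,2)-1,1), V(F(bf,2)-1,2) };
    double u[3] = { b_[0]-a_[0], b_[1]-a_[1], b_[2]-a_[2] };
    double w[3] = { cc[0]-a_[0], cc[1]-a_[1], cc[2]-a_[2] };
    double nrm[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    double dp = (p[0]-a_[0])*nrm[0] + (p[1]-a_[1])*nrm[1] + (p[2]-a_[2])*nrm[2];
    dist[i] = (dp < 0 ? -1.0 : 1.0) * std::sqrt(best);
    nearest[i] = bf + 1;
  }
  return List::create(_["distance"] = dist, _["nearest_face"] = nearest);
}
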