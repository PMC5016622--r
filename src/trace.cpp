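// Forward Monte Carlo ray tracer for canopy light interception.
//
// Equal-energy rays are emitted from a horizontal source plane above the
// scene (parallel beam for the direct component, cosine-weighted hemisphere
// for the isotropic diffuse sky). At each surface hit the absorbed fraction
// (1 - rho - tau) of the ray's energy is scored to that surface and the ray
// continues with the remainder, choosing reflection vs transmission with
// probability rho : tau, Lambertian about the local normal. Rays terminate
// on escape or after max_impacts interactions (remainder booked as
// truncated), so absorbed + escaped + truncated = emitted up to
// floating-point accumulation error.
//
// Determinism: every ray owns its own counter-based RNG stream seeded from
// (seed, ray index), so results are reproducible for a fixed seed
// independent of traversal details.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(Vec3 a) { double n = norm(a); return {a.x / n, a.y / n, a.z / n}; }

// ---- per-ray RNG: splitmix64 seeding + xorshift64* stream -----------------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  double uniform() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t r = s * 0x2545F4914F6CDD1DULL;
    return (r >> 11) * (1.0 / 9007199254740992.0);
  }
};

// ---- triangles and BVH ----------------------------------------------------
struct Tri {
  Vec3 a, e1, e2, n; // vertex, edges, unit normal
  int surf;          // 0-based surface index
};

struct BvhNode {
  Vec3 bmin, bmax;
  int left, right;   // child node indices, or -1 for leaf
  int start, count;  // triangle range for leaves
};

struct Bvh {
  std::vector<Tri> tris;
  std::vector<BvhNode> nodes;

  int build(std::vector<int>& idx, int start, int count,
            const std::vector<Vec3>& centroids, std::vector<Tri>& src) {
    BvhNode node;
    Vec3 bmin = {1e30, 1e30, 1e30}, bmax = {-1e30, -1e30, -1e30};
    for (int i = start; i < start + count; ++i) {
      const Tri& t = src[idx[i]];
      Vec3 v0 = t.a, v1 = t.a + t.e1, v2 = t.a + t.e2;
      for (Vec3 v : {v0, v1, v2}) {
        bmin.x = std::min(bmin.x, v.x); bmin.y = std::min(bmin.y, v.y); bmin.z = std::min(bmin.z, v.z);
        bmax.x = std::max(bmax.x, v.x); bmax.y = std::max(bmax.y, v.y); bmax.z = std::max(bmax.z, v.z);
      }
    }
    node.bmin = bmin; node.bmax = bmax;
    int my = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 4) {
      nodes[my].left = nodes[my].right = -1;
      nodes[my].start = (int)tris.size();
      nodes[my].count = count;
      for (int i = start; i < start + count; ++i) tris.push_back(src[idx[i]]);
      return my;
    }
    Vec3 ext = bmax - bmin;
    int axis = (ext.x > ext.y && ext.x > ext.z) ? 0 : (ext.y > ext.z ? 1 : 2);
    int mid = start + count / 2;
    std::nth_element(idx.begin() + start, idx.begin() + mid,
                     idx.begin() + start + count,
                     [&](int a, int b) {
                       const Vec3& ca = centroids[a];
                       const Vec3& cb = centroids[b];
                       double va = axis == 0 ? ca.x : (axis == 1 ? ca.y : ca.z);
                       double vb = axis == 0 ? cb.x : (axis == 1 ? cb.y : cb.z);
                       return va < vb;
                     });
    int l = build(idx, start, mid - start, centroids, src);
    int r = build(idx, mid, start + count - mid, centroids, src);
    nodes[my].left = l; nodes[my].right = r;
    nodes[my].start = nodes[my].count = 0;
    return my;
  }
};

static inline bool box_hit(const BvhNode& n, Vec3 o, Vec3 inv_d, double tmax) {
  double t0 = (n.bmin.x - o.x) * inv_d.x, t1 = (n.bmax.x - o.x) * inv_d.x;
  double tlo = std::min(t0, t1), thi = std::max(t0, t1);
  t0 = (n.bmin.y - o.y) * inv_d.y; t1 = (n.bmax.y - o.y) * inv_d.y;
  tlo = std::max(tlo, std::min(t0, t1)); thi = std::min(thi, std::max(t0, t1));
  t0 = (n.bmin.z - o.z) * inv_d.z; t1 = (n.bmax.z - o.z) * inv_d.z;
  tlo = std::max(tlo, std::min(t0, t1)); thi = std::min(thi, std::max(t0, t1));
  return thi >= std::max(tlo, 0.0) && tlo <= tmax;
}

// Moller-Trumbore; returns t or -1
static inline double tri_hit(const Tri& tr, Vec3 o, Vec3 d, double eps) {
  Vec3 p = cross(d, tr.e2);
  double det = dot(tr.e1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = o - tr.a;
  double u = dot(tv, p) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  Vec3 q = cross(tv, tr.e1);
  double v = dot(d, q) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = dot(tr.e2, q) * inv;
  return t > eps ? t : -1.0;
}

static int nearest_hit(const Bvh& bvh, Vec3 o, Vec3 d, double eps,
                       double& t_out) {
  Vec3 inv_d = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
  double best_t = 1e30;
  int best = -1;
  int stack[64];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    const BvhNode& node = bvh.nodes[stack[--sp]];
    if (!box_hit(node, o, inv_d, best_t)) continue;
    if (node.left < 0) {
      for (int i = node.start; i < node.start + node.count; ++i) {
        double t = tri_hit(bvh.tris[i], o, d, eps);
        if (t > 0 && t < best_t) { best_t = t; best = i; }
      }
    } else {
      stack[sp++] = node.left;
      stack[sp++] = node.right;
    }
  }
  t_out = best_t;
  return best;
}

static inline Vec3 lambertian(Vec3 n, Rng& rng) {
  double u1 = rng.uniform(), u2 = rng.uniform();
  double ct = std::sqrt(u1), st = std::sqrt(1.0 - u1);
  double phi = 2.0 * M_PI * u2;
  Vec3 ref = std::fabs(n.z) < 0.9 ? Vec3{0, 0, 1} : Vec3{1, 0, 0};
  Vec3 t1 = normalize(cross(ref, n));
  Vec3 t2 = cross(n, t1);
  return (st * std::cos(phi)) * t1 + (st * std::sin(phi)) * t2 + ct * n;
}

struct Kahan {
  double s = 0, c = 0;
  void add(double x) {
    double y = x - c, t = s + y;
    c = (t - s) - y;
    s = t;
  }
};

// [[Rcpp::export(name = ".trace_cpp")]]
List trace_cpp(NumericMatrix tri, IntegerVector tri_surf,
               NumericVector surf_rho, NumericVector surf_tau,
               NumericVector beam_dir, double beam_power,
               double diffuse_power,
               double plane_z, double xmin, double xmax,
               double ymin, double ymax,
               double n_rays, int max_impacts, double seed) {
  int ntri = tri.nrow();
  int nsurf = surf_rho.size();

  std::vector<Tri> src;
  src.reserve(ntri);
  std::vector<Vec3> centroids;
  int n_degenerate = 0;
  for (int i = 0; i < ntri; ++i) {
    Vec3 a = {tri(i, 0), tri(i, 1), tri(i, 2)};
    Vec3 b = {tri(i, 3), tri(i, 4), tri(i, 5)};
    Vec3 c = {tri(i, 6), tri(i, 7), tri(i, 8)};
    Tri t;
    t.a = a; t.e1 = b - a; t.e2 = c - a;
    Vec3 nrm = cross(t.e1, t.e2);
    double nn = norm(nrm);
    if (!(nn > 1e-16)) { ++n_degenerate; continue; }
    t.n = {nrm.x / nn, nrm.y / nn, nrm.z / nn};
    t.surf = tri_surf[i] - 1;
    src.push_back(t);
    centroids.push_back((1.0 / 3.0) * (a + b + c));
  }

  std::vector<double> absorbed(nsurf, 0.0), sumsq(nsurf, 0.0);
  Kahan abs_tot, esc_tot, trunc_tot, emit_tot;

  double diag = 1.0;
  Bvh bvh;
  bool empty = src.empty();
  if (!empty) {
    std::vector<int> idx(src.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
    bvh.build(idx, 0, (int)idx.size(), centroids, src);
    Vec3 ext = bvh.nodes[0].bmax - bvh.nodes[0].bmin;
    diag = std::max(norm(ext), 1e-6);
  }
  double eps = 1e-9 * diag;

  double total_power = beam_power + diffuse_power;
  long long n_total = (long long)n_rays;
  long long n_direct = total_power > 0
    ? (long long)std::llround(n_rays * beam_power / total_power) : 0;
  if (beam_power <= 0) n_direct = 0;
  if (diffuse_power <= 0) n_direct = n_total;
  double e_direct = n_direct > 0 ? beam_power / (double)n_direct : 0.0;
  double e_diffuse = (n_total - n_direct) > 0
    ? diffuse_power / (double)(n_total - n_direct) : 0.0;

  Vec3 bd = {beam_dir[0], beam_dir[1], beam_dir[2]};
  if (norm(bd) > 0) bd = normalize(bd);

  std::vector<int> dep_surf(max_impacts);
  std::vector<double> dep_amt(max_impacts);
  uint64_t useed = (uint64_t)seed;

  for (long long r = 0; r < n_total; ++r) {
    Rng rng(useed * 0x9E3779B97F4A7C15ULL + (uint64_t)r);
    bool direct = r < n_direct;
    double energy = direct ? e_direct : e_diffuse;
    if (energy <= 0) continue;
    emit_tot.add(energy);
    Vec3 o = {xmin + (xmax - xmin) * rng.uniform(),
              ymin + (ymax - ymin) * rng.uniform(), plane_z};
    Vec3 d;
    if (direct) {
      d = bd;
    } else {
      d = lambertian({0, 0, -1}, rng);
    }
    if (empty) { esc_tot.add(energy); continue; }

    int n_dep = 0;
    int impacts = 0;
    bool alive = true;
    while (alive) {
      double t;
      int hit = nearest_hit(bvh, o, d, eps, t);
      if (hit < 0) { esc_tot.add(energy); alive = false; break; }
      const Tri& tr = bvh.tris[hit];
      double rho = surf_rho[tr.surf], tau = surf_tau[tr.surf];
      double e_next = energy * (rho + tau);
      double dep = energy - e_next;
      // merge repeated deposits on the same surface within one ray path
      bool merged = false;
      for (int q = 0; q < n_dep; ++q) {
        if (dep_surf[q] == tr.surf) { dep_amt[q] += dep; merged = true; break; }
      }
      if (!merged) { dep_surf[n_dep] = tr.surf; dep_amt[n_dep] = dep; ++n_dep; }
      abs_tot.add(dep);
      energy = e_next;
      ++impacts;
      if (energy <= 0) { alive = false; break; }
      if (impacts >= max_impacts) {
        trunc_tot.add(energy);
        alive = false;
        break;
      }
      Vec3 hitp = o + t * d;
      Vec3 n_face = dot(d, tr.n) < 0 ? tr.n : Vec3{-tr.n.x, -tr.n.y, -tr.n.z};
      double u = rng.uniform();
      Vec3 n_out = (u < rho / (rho + tau)) ? n_face
                                           : Vec3{-n_face.x, -n_face.y, -n_face.z};
      d = lambertian(n_out, rng);
      o = hitp + (2.0 * eps) * n_out;
    }
    for (int q = 0; q < n_dep; ++q) {
      absorbed[dep_surf[q]] += dep_amt[q];
      sumsq[dep_surf[q]] += dep_amt[q] * dep_amt[q];
    }
  }

  return List::create(
    _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
    _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
    _["emitted"] = emit_tot.s,
    _["escaped"] = esc_tot.s,
    _["truncated"] = trunc_tot.s,
    _["absorbed_total"] = abs_tot.s,
    _["n_rays"] = (double)n_total,
    _["n_direct"] = (double)n_direct,
    _["n_degenerate"] = n_degenerate);
}
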