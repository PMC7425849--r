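#include "meshtools.h"
#include <queue>
#include <set>
#include <map>
using namespace Rcpp;
using namespace s3d;

namespace {

// symmetric 4x4 quadric stored as 10 doubles:
// [0]=q11 [1]=q12 [2]=q13 [3]=q14 [4]=q22 [5]=q23 [6]=q24 [7]=q33 [8]=q34 [9]=q44
struct Quadric {
  double q[10];
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0; }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
  }
  void operator+=(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const Vec3& v) const {
    return q[0]*v.x*v.x + 2*q[1]*v.x*v.y + 2*q[2]*v.x*v.z + 2*q[3]*v.x
         + q[4]*v.y*v.y + 2*q[5]*v.y*v.z + 2*q[6]*v.y
         + q[7]*v.z*v.z + 2*q[8]*v.z + q[9];
  }
  // minimizer of the quadric; false if near-singular
  bool optimum(Vec3& out) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13)
               + a13 * (a12 * a23 - a22 * a13);
    double scale = std::max(std::fabs(a11), std::max(std::fabs(a22), std::fabs(a33)));
    if (std::fabs(det) < 1e-10 * scale * scale * scale + 1e-300) return false;
    double inv = 1.0 / det;
    out.x = inv * (b1 * (a22 * a33 - a23 * a23) + b2 * (a13 * a23 - a12 * a33) + b3 * (a12 * a23 - a13 * a22));
    out.y = inv * (b1 * (a23 * a13 - a12 * a33) + b2 * (a11 * a33 - a13 * a13) + b3 * (a12 * a13 - a11 * a23));
    out.z = inv * (b1 * (a12 * a23 - a22 * a13) + b2 * (a12 * a13 - a11 * a23) + b3 * (a11 * a22 - a12 * a12));
    return true;
  }
};

struct Entry {
  double cost;
  int a, b;          // a < b
  int va_ver, vb_ver;
  double px, py, pz; // collapse target
};
struct EntryCmp {
  bool operator()(const Entry& l, const Entry& r) const {
    if (l.cost != r.cost) return l.cost > r.cost; // min-heap
    if (l.a != r.a) return l.a > r.a;
    return l.b > r.b;
  }
};

} // namespace

// Quality-weighted quadric-error-metric edge-collapse decimation.
// quality in [0,1] per vertex; a collapse's QEM cost is multiplied by
// (1 + k * max(quality at endpoints)), so painted regions survive longer.
// Deterministic: ties broken by (cost, lower vertex index, higher index).
// [[Rcpp::export(name = ".cpp_decimate_qem")]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, NumericVector quality,
                      int target_faces, double k) {
  int n = Vin.nrow(), m = Fin.nrow();
  std::vector<Vec3> V(n);
  for (int i = 0; i < n; ++i) V[i] = Vec3(Vin(i, 0), Vin(i, 1), Vin(i, 2));
  std::vector<int> Fv(3 * (size_t)m);
  std::vector<char> alive_f(m, 1), alive_v(n, 1);
  std::vector<std::vector<int> > vfaces(n);
  for (int f = 0; f < m; ++f)
    for (int c = 0; c < 3; ++c) {
      Fv[3 * (size_t)f + c] = Fin(f, c);
      vfaces[Fin(f, c)].push_back(f);
    }
  std::vector<double> qual(n);
  for (int i = 0; i < n; ++i) qual[i] = quality[i];

  // face-plane quadrics, area weighted
  std::vector<Quadric> Q(n);
  for (int f = 0; f < m; ++f) {
    Vec3 p0 = V[Fv[3*(size_t)f]], p1 = V[Fv[3*(size_t)f+1]], p2 = V[Fv[3*(size_t)f+2]];
    Vec3 nrm = cross(p1 - p0, p2 - p0);
    double a2 = norm(nrm);
    if (a2 <= 0) continue;
    Vec3 un = nrm * (1.0 / a2);
    double d = -dot(un, p0);
    double w = 0.5 * a2; // triangle area
    for (int c = 0; c < 3; ++c) Q[Fv[3*(size_t)f+c]].add_plane(un.x, un.y, un.z, d, w);
  }

  // boundary constraint quadrics: plane through boundary edge, orthogonal to face
  {
    std::map<std::pair<int,int>, std::pair<int,int> > ecount; // edge -> (count, face)
    for (int f = 0; f < m; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = Fv[3*(size_t)f+c], b = Fv[3*(size_t)f+(c+1)%3];
        std::pair<int,int> key(std::min(a,b), std::max(a,b));
        std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = ecount.find(key);
        if (it == ecount.end()) ecount[key] = std::make_pair(1, f);
        else it->second.first++;
      }
    for (std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second.first != 1) continue;
      int a = it->first.first, b = it->first.second, f = it->second.second;
      Vec3 e = V[b] - V[a];
      Vec3 p0 = V[Fv[3*(size_t)f]], p1 = V[Fv[3*(size_t)f+1]], p2 = V[Fv[3*(size_t)f+2]];
      Vec3 fn = normalize(cross(p1 - p0, p2 - p0));
      Vec3 cn = normalize(cross(e, fn));
      double d = -dot(cn, V[a]);
      double w = 100.0 * dot(e, e);
      Quadric bq;
      bq.add_plane(cn.x, cn.y, cn.z, d, w);
      Q[a] += bq; Q[b] += bq;
    }
  }

  std::vector<int> version(n, 0);
  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> heap;

  // cost + target position for edge (a,b), a<b
  struct Local {
    static Entry make(int a, int b, const std::vector<Vec3>& V,
                      const std::vector<Quadric>& Q, const std::vector<double>& qual,
                      const std::vector<int>& version, double k) {
      Quadric Qe = Q[a]; Qe += Q[b];
      Vec3 p;
      if (!Qe.optimum(p)) {
        Vec3 mid = (V[a] + V[b]) * 0.5;
        double ca = Qe.eval(V[a]), cb = Qe.eval(V[b]), cm = Qe.eval(mid);
        p = V[a];
        double cbest = ca;
        if (cb < cbest) { cbest = cb; p = V[b]; }
        if (cm < cbest) { p = mid; }
      }
      double cost = std::max(0.0, Qe.eval(p)) * (1.0 + k * std::max(qual[a], qual[b]));
      Entry e;
      e.cost = cost; e.a = a; e.b = b;
      e.va_ver = version[a]; e.vb_ver = version[b];
      e.px = p.x; e.py = p.y; e.pz = p.z;
      return e;
    }
  };

  // initial edges
  {
    std::set<std::pair<int,int> > seen;
    for (int f = 0; f < m; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = Fv[3*(size_t)f+c], b = Fv[3*(size_t)f+(c+1)%3];
        std::pair<int,int> key(std::min(a,b), std::max(a,b));
        if (seen.insert(key).second)
          heap.push(Local::make(key.first, key.second, V, Q, qual, version, k));
      }
  }

  int alive_faces = m;
  bool floor_hit = false;
  std::vector<int> shared, common;

  while (alive_faces > target_faces) {
    if (heap.empty()) { floor_hit = true; break; }
    Entry e = heap.top(); heap.pop();
    int a = e.a, b = e.b;
    if (!alive_v[a] || !alive_v[b]) continue;
    if (version[a] != e.va_ver || version[b] != e.vb_ver) continue;

    // faces containing the edge
    shared.clear();
    for (size_t q = 0; q < vfaces[a].size(); ++q) {
      int f = vfaces[a][q];
      if (!alive_f[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (Fv[3*(size_t)f+c] == b) { shared.push_back(f); break; }
    }
    if (shared.empty()) continue; // stale edge

    // link condition: common vertex neighbors must all be opposite corners of shared faces
    std::set<int> na, nb;
    for (size_t q = 0; q < vfaces[a].size(); ++q) {
      int f = vfaces[a][q];
      if (!alive_f[f]) continue;
      for (int c = 0; c < 3; ++c) { int v = Fv[3*(size_t)f+c]; if (v != a) na.insert(v); }
    }
    for (size_t q = 0; q < vfaces[b].size(); ++q) {
      int f = vfaces[b][q];
      if (!alive_f[f]) continue;
      for (int c = 0; c < 3; ++c) { int v = Fv[3*(size_t)f+c]; if (v != b) nb.insert(v); }
    }
    common.clear();
    for (std::set<int>::iterator it = na.begin(); it != na.end(); ++it)
      if (nb.count(*it)) common.push_back(*it);
    if ((int)common.size() != (int)shared.size()) continue; // would create non-manifold edge

    // never collapse a whole tetrahedron shut
    if (alive_faces - (int)shared.size() < 4) { floor_hit = true; break; }

    // normal flip / degeneracy check on surviving faces
    Vec3 p(e.px, e.py, e.pz);
    bool flip = false;
    for (int side = 0; side < 2 && !flip; ++side) {
      int v = side == 0 ? a : b;
      for (size_t q = 0; q < vfaces[v].size() && !flip; ++q) {
        int f = vfaces[v][q];
        if (!alive_f[f]) continue;
        bool has_other = false;
        for (int c = 0; c < 3; ++c)
          if (Fv[3*(size_t)f+c] == (side == 0 ? b : a)) has_other = true;
        if (has_other) continue; // face dies
        Vec3 o0 = V[Fv[3*(size_t)f]], o1 = V[Fv[3*(size_t)f+1]], o2 = V[Fv[3*(size_t)f+2]];
        Vec3 nold = cross(o1 - o0, o2 - o0);
        Vec3 n0 = Fv[3*(size_t)f] == v ? p : o0;
        Vec3 n1 = Fv[3*(size_t)f+1] == v ? p : o1;
        Vec3 n2 = Fv[3*(size_t)f+2] == v ? p : o2;
        Vec3 nnew = cross(n1 - n0, n2 - n0);
        if (dot(nold, nnew) <= 1e-14 * dot(nold, nold)) flip = true;
      }
    }
    if (flip) continue;

    // collapse b into a at position p
    V[a] = p;
    Q[a] += Q[b];
    qual[a] = std::max(qual[a], qual[b]);
    for (size_t q = 0; q < vfaces[b].size(); ++q) {
      int f = vfaces[b][q];
      if (!alive_f[f]) continue;
      bool has_a = false;
      for (int c = 0; c < 3; ++c) if (Fv[3*(size_t)f+c] == a) has_a = true;
      if (has_a) {
        alive_f[f] = 0;
        --alive_faces;
      } else {
        for (int c = 0; c < 3; ++c) if (Fv[3*(size_t)f+c] == b) Fv[3*(size_t)f+c] = a;
        vfaces[a].push_back(f);
      }
    }
    alive_v[b] = 0;
    ++version[a];
    ++version[b];

    // refresh candidate edges around a
    std::set<int> nbrs;
    for (size_t q = 0; q < vfaces[a].size(); ++q) {
      int f = vfaces[a][q];
      if (!alive_f[f]) continue;
      for (int c = 0; c < 3; ++c) { int v = Fv[3*(size_t)f+c]; if (v != a) nbrs.insert(v); }
    }
    for (std::set<int>::iterator it = nbrs.begin(); it != nbrs.end(); ++it) {
      int x = *it;
      heap.push(Local::make(std::min(a, x), std::max(a, x), V, Q, qual, version, k));
    }
  }

  // compact
  std::vector<int> vmap(n, -1);
  int nv = 0;
  for (int f = 0; f < m; ++f) {
    if (!alive_f[f]) continue;
    for (int c = 0; c < 3; ++c) {
      int v = Fv[3*(size_t)f+c];
      if (vmap[v] < 0) vmap[v] = nv++;
    }
  }
  NumericMatrix VO(nv, 3);
  NumericVector QO(nv);
  for (int v = 0; v < n; ++v)
    if (vmap[v] >= 0) {
      VO(vmap[v], 0) = V[v].x; VO(vmap[v], 1) = V[v].y; VO(vmap[v], 2) = V[v].z;
      QO[vmap[v]] = qual[v];
    }
  IntegerMatrix FO(alive_faces, 3);
  int fi = 0;
  for (int f = 0; f < m; ++f) {
    if (!alive_f[f]) continue;
    for (int c = 0; c < 3; ++c) FO(fi, c) = vmap[Fv[3*(size_t)f+c]];
    ++fi;
  }
  return List::create(_["vertices"] = VO, _["faces"] = FO,
                      _["quality"] = QO, _["floor_hit"] = floor_hit);
}
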