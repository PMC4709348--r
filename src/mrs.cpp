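// Multiresolution region-merging segmentation core.
//
// Regions start as single cells and are merged pairwise. The fusion cost of a
// candidate merge is
//   f = wShape * dShape + (1 - wShape) * dColor
// with
//   hColor(R)  = sum_b w_b * n_R * sd_b(R)
//   hShape(R)  = wCmpct * (l_R / sqrt(n_R)) + (1 - wCmpct) * (l_R / b_R)
//   dX         = hX(merged) - hX(R1) - hX(R2)
// where n = cell count, sd_b = population standard deviation of band b,
// l = perimeter in cell-edge units and b = bounding-box perimeter in the same
// units. Merging proceeds globally cheapest-pair first (ties broken by the
// lowest id pair, ids assigned in row-major scan order), and a merge is
// admissible iff f < scale^2. Cheapest-first ordering makes the result at a
// larger scale an exact continuation of the result at a smaller one, so the
// final segment count is non-increasing in the scale parameter.

#include <Rcpp.h>
#include <queue>
#include <map>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

namespace {

struct Region {
  bool alive = false;
  double n = 0;
  std::vector<double> sum, sumsq;
  double perim = 0;                  // cell-edge units
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  int version = 0;
  std::map<int, double> shared;      // neighbor id -> shared edge count
};

struct Cand {
  double cost;
  int a, b, va, vb;
};

struct CandOrder {
  bool operator()(const Cand& x, const Cand& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;   // min-heap on cost
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

inline double bandSd(const Region& R, int b) {
  double mu = R.sum[b] / R.n;
  double v = R.sumsq[b] / R.n - mu * mu;
  return v > 0 ? std::sqrt(v) : 0.0;
}

inline double hColor(const Region& R, const std::vector<double>& w) {
  double h = 0;
  for (size_t b = 0; b < w.size(); ++b) h += w[b] * R.n * bandSd(R, b);
  return h;
}

inline double hShape(double n, double perim, int rmin, int rmax, int cmin,
                     int cmax, double wCmpct) {
  double bbox = 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
  return wCmpct * (perim / std::sqrt(n)) + (1.0 - wCmpct) * (perim / bbox);
}

double mergeCost(const Region& A, const Region& B, double sharedEdges,
                 const std::vector<double>& w, double wShape, double wCmpct) {
  size_t nb = w.size();
  double n = A.n + B.n;
  double hc = 0;
  for (size_t b = 0; b < nb; ++b) {
    double s = A.sum[b] + B.sum[b], ss = A.sumsq[b] + B.sumsq[b];
    double mu = s / n, v = ss / n - mu * mu;
    hc += w[b] * n * (v > 0 ? std::sqrt(v) : 0.0);
  }
  double dColor = hc - hColor(A, w) - hColor(B, w);
  double perim = A.perim + B.perim - 2.0 * sharedEdges;
  double hm = hShape(n, perim, std::min(A.rmin, B.rmin), std::max(A.rmax, B.rmax),
                     std::min(A.cmin, B.cmin), std::max(A.cmax, B.cmax), wCmpct);
  double dShape = hm -
    hShape(A.n, A.perim, A.rmin, A.rmax, A.cmin, A.cmax, wCmpct) -
    hShape(B.n, B.perim, B.rmin, B.rmax, B.cmin, B.cmax, wCmpct);
  return wShape * dShape + (1.0 - wShape) * dColor;
}

} // namespace

// [[Rcpp::export(name = ".mrsSegment")]]
IntegerMatrix mrsSegment(NumericVector values, LogicalMatrix valid,
                         NumericVector weights, double scale, double wShape,
                         double wCmpct) {
  IntegerVector dims = values.attr("dim");
  if (dims.size() != 3) stop("values must be an nr x nc x nb array");
  const int nr = dims[0], nc = dims[1], nb = dims[2];
  const double scale2 = scale * scale;
  std::vector<double> w(weights.begin(), weights.end());
  if ((int)w.size() != nb) stop("one weight per band required");

  auto cellId = [&](int r, int c) { return r * nc + c; }; // row-major ids
  auto val = [&](int r, int c, int b) {
    return values[r + (double)nr * c + (double)nr * nc * b];
  };

  std::vector<Region> reg(nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!valid(r, c)) continue;
      Region& R = reg[cellId(r, c)];
      R.alive = true; R.n = 1; R.perim = 4;
      R.rmin = R.rmax = r; R.cmin = R.cmax = c;
      R.sum.resize(nb); R.sumsq.resize(nb);
      for (int b = 0; b < nb; ++b) {
        double v = val(r, c, b);
        if (!std::isfinite(v)) stop("non-finite cell value in a valid cell");
        R.sum[b] = v; R.sumsq[b] = v * v;
      }
    }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!valid(r, c)) continue;
      int id = cellId(r, c);
      if (c + 1 < nc && valid(r, c + 1)) {
        reg[id].shared[cellId(r, c + 1)] = 1;
        reg[cellId(r, c + 1)].shared[id] = 1;
      }
      if (r + 1 < nr && valid(r + 1, c)) {
        reg[id].shared[cellId(r + 1, c)] = 1;
        reg[cellId(r + 1, c)].shared[id] = 1;
      }
    }

  std::priority_queue<Cand, std::vector<Cand>, CandOrder> pq;
  auto pushPair = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    double c = mergeCost(reg[a], reg[b], reg[a].shared.at(b), w, wShape, wCmpct);
    pq.push({c, a, b, reg[a].version, reg[b].version});
  };
  for (int id = 0; id < nr * nc; ++id) {
    if (!reg[id].alive) continue;
    for (auto& kv : reg[id].shared)
      if (kv.first > id) pushPair(id, kv.first);
  }

  std::vector<int> parent(nr * nc);
  for (int i = 0; i < nr * nc; ++i) parent[i] = i;

  while (!pq.empty()) {
    Cand t = pq.top(); pq.pop();
    Region& A = reg[t.a];
    Region& B = reg[t.b];
    if (!A.alive || !B.alive || A.version != t.va || B.version != t.vb)
      continue;                      // stale entry
    if (t.cost >= scale2) break;     // cheapest fresh pair inadmissible
    // merge B into A
    double sharedAB = A.shared.at(t.b);
    A.n += B.n;
    for (int b = 0; b < nb; ++b) { A.sum[b] += B.sum[b]; A.sumsq[b] += B.sumsq[b]; }
    A.perim += B.perim - 2.0 * sharedAB;
    A.rmin = std::min(A.rmin, B.rmin); A.rmax = std::max(A.rmax, B.rmax);
    A.cmin = std::min(A.cmin, B.cmin); A.cmax = std::max(A.cmax, B.cmax);
    A.shared.erase(t.b);
    for (auto& kv : B.shared) {
      int x = kv.first;
      if (x == t.a) continue;
      A.shared[x] += kv.second;
      reg[x].shared.erase(t.b);
      reg[x].shared[t.a] = A.shared[x];
    }
    B.alive = false;
    B.shared.clear();
    B.sum.clear(); B.sumsq.clear();
    parent[t.b] = t.a;
    A.version++;
    for (auto& kv : A.shared) pushPair(t.a, kv.first);
  }

  // resolve cell -> surviving region, compact labels in row-major order
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  IntegerMatrix labels(nr, nc);
  std::map<int, int> compact;
  int next = 1;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!valid(r, c)) { labels(r, c) = NA_INTEGER; continue; }
      int root = find(cellId(r, c));
      auto it = compact.find(root);
      if (it == compact.end()) { compact[root] = next; labels(r, c) = next; ++next; }
      else labels(r, c) = it->second;
    }
  return labels;
}
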