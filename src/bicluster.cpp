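// Greedy seed-and-grow search for dense biclusters in the bipartite
// k-mer x read incidence graph. Deterministic: ties resolve to the
// lowest-index (lexicographically smallest) vertex. Candidate selection
// uses lazy max-heaps keyed by (gain, -index); stale entries are discarded
// on inspection, so per-step cost is logarithmic in the touched edges.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e300;

typedef std::pair<double, int> HeapEntry; // (key, -index)
typedef std::priority_queue<HeapEntry> Heap;

struct Cluster {
  std::vector<int> vs, vt;
  double e, density;
};

// peek the best valid entry; stale tops are popped and dropped
static inline int heap_top(Heap &h, const std::vector<double> &gain) {
  while (!h.empty()) {
    const HeapEntry &t = h.top();
    int id = -t.second;
    if (gain[id] == t.first && gain[id] > 0) return id;
    h.pop();
  }
  return -1;
}

// [[Rcpp::export(name = ".bicluster_search_cpp")]]
List bicluster_search_cpp(int nk, int nr, IntegerVector ek, IntegerVector er,
                          double min_density, int min_kmers, int min_reads,
                          int max_clusters) {
  std::vector<std::vector<int>> adj_k(nk), adj_r(nr);
  const int ne = ek.size();
  for (int i = 0; i < ne; i++) {
    adj_k[ek[i]].push_back(er[i]);
    adj_r[er[i]].push_back(ek[i]);
  }
  for (auto &v : adj_k) std::sort(v.begin(), v.end());
  for (auto &v : adj_r) std::sort(v.begin(), v.end());

  std::vector<char> tried(nk, 0), in_vs(nk, 0), in_vt(nr, 0);
  std::vector<double> gain_k(nk, 0.0), gain_r(nr, 0.0);
  std::vector<int> touched_k, touched_r;
  const int seed_min = std::max(1, (int)std::ceil(min_density * min_reads));
  std::vector<Cluster> clusters;

  // lazy max-heap over seed degrees
  std::vector<double> deg(nk);
  Heap seeds;
  for (int m = 0; m < nk; m++) {
    deg[m] = adj_k[m].size();
    if (deg[m] >= seed_min) seeds.push(HeapEntry(deg[m], -m));
  }

  while ((int)clusters.size() < max_clusters) {
    // seed: highest-degree untried k-mer
    int s = -1;
    while (!seeds.empty()) {
      const HeapEntry &t = seeds.top();
      int id = -t.second;
      if (!tried[id] && deg[id] == t.first && deg[id] >= seed_min) {
        s = id;
        break;
      }
      seeds.pop();
    }
    if (s < 0) break;
    tried[s] = 1;
    if (adj_k[s].empty()) continue;

    // ---- grow ----
    touched_k.clear();
    touched_r.clear();
    std::vector<int> vs, vt, grown_vs;
    Heap heap_k, heap_r;
    vs.push_back(s);
    grown_vs.push_back(s);
    gain_k[s] = NEG;
    touched_k.push_back(s);
    double e = 0;
    for (int r : adj_k[s]) {
      vt.push_back(r);
      gain_r[r] = NEG;
      touched_r.push_back(r);
    }
    e = vt.size();
    for (int r : vt) {
      for (int m : adj_r[r]) {
        if (gain_k[m] == 0.0) touched_k.push_back(m);
        if (gain_k[m] >= 0) {
          gain_k[m] += 1.0;
          heap_k.push(HeapEntry(gain_k[m], -m));
        }
      }
    }
    while (true) {
      bool progressed = false;
      // k-mer phase
      int bm = heap_top(heap_k, gain_k);
      if (bm >= 0) {
        double bg = gain_k[bm];
        if ((e + bg) / (((double)vs.size() + 1) * vt.size()) >= min_density) {
          vs.push_back(bm);
          grown_vs.push_back(bm);
          e += bg;
          gain_k[bm] = NEG;
          for (int r : adj_k[bm]) {
            if (gain_r[r] == 0.0) touched_r.push_back(r);
            if (gain_r[r] >= 0) {
              gain_r[r] += 1.0;
              heap_r.push(HeapEntry(gain_r[r], -r));
            }
          }
          progressed = true;
        }
      }
      // read phase
      int br = heap_top(heap_r, gain_r);
      if (br >= 0) {
        double bg = gain_r[br];
        if ((e + bg) / ((double)vs.size() * (vt.size() + 1)) >= min_density) {
          vt.push_back(br);
          e += bg;
          gain_r[br] = NEG;
          for (int m : adj_r[br]) {
            if (gain_k[m] == 0.0) touched_k.push_back(m);
            if (gain_k[m] >= 0) {
              gain_k[m] += 1.0;
              heap_k.push(HeapEntry(gain_k[m], -m));
            }
          }
          progressed = true;
        }
      }
      if (!progressed) break;
    }
    // every k-mer absorbed into the grown candidate counts as used
    for (int m : grown_vs) tried[m] = 1;

    // ---- prune: drop the vertex whose removal most increases density ----
    for (int m : vs) in_vs[m] = 1;
    for (int r : vt) in_vt[r] = 1;
    std::vector<double> loss_k(vs.size()), loss_r(vt.size());
    std::vector<int> pos_vs(nk, -1), pos_vt(nr, -1);
    for (size_t i = 0; i < vs.size(); i++) {
      int c = 0;
      for (int r : adj_k[vs[i]])
        if (in_vt[r]) c++;
      loss_k[i] = c;
      pos_vs[vs[i]] = i;
    }
    for (size_t j = 0; j < vt.size(); j++) {
      int c = 0;
      for (int m : adj_r[vt[j]])
        if (in_vs[m]) c++;
      loss_r[j] = c;
      pos_vt[vt[j]] = j;
    }
    while (true) {
      double d = e / ((double)vs.size() * vt.size());
      // removing the vertex with the smallest loss maximises the new density
      double bk = -1, brv = -1;
      int ik = -1, ir = -1;
      if (vs.size() > 1) {
        for (size_t i = 0; i < vs.size(); i++) {
          double nd = (e - loss_k[i]) / (((double)vs.size() - 1) * vt.size());
          if (nd > bk) {
            bk = nd;
            ik = i;
          }
        }
      }
      if (vt.size() > 1) {
        for (size_t j = 0; j < vt.size(); j++) {
          double nd = (e - loss_r[j]) / ((double)vs.size() * (vt.size() - 1));
          if (nd > brv) {
            brv = nd;
            ir = j;
          }
        }
      }
      if (std::max(bk, brv) <= d) break;
      if (bk >= brv) {
        int m = vs[ik];
        e -= loss_k[ik];
        in_vs[m] = 0;
        pos_vs[m] = -1;
        for (int r : adj_k[m])
          if (in_vt[r]) loss_r[pos_vt[r]] -= 1;
        vs[ik] = vs.back();
        vs.pop_back();
        loss_k[ik] = loss_k.back();
        loss_k.pop_back();
        if (ik < (int)vs.size()) pos_vs[vs[ik]] = ik;
      } else {
        int r = vt[ir];
        e -= loss_r[ir];
        in_vt[r] = 0;
        pos_vt[r] = -1;
        for (int m : adj_r[r])
          if (in_vs[m]) loss_k[pos_vs[m]] -= 1;
        vt[ir] = vt.back();
        vt.pop_back();
        loss_r[ir] = loss_r.back();
        loss_r.pop_back();
        if (ir < (int)vt.size()) pos_vt[vt[ir]] = ir;
      }
    }
    double density = e / ((double)vs.size() * vt.size());
    bool accepted = (int)vs.size() >= min_kmers && (int)vt.size() >= min_reads &&
                    density >= min_density;
    if (accepted) {
      // remove the cluster's edges from the working graph
      for (int m : vs) {
        auto &a = adj_k[m];
        a.erase(std::remove_if(a.begin(), a.end(),
                               [&](int r) { return in_vt[r] != 0; }),
                a.end());
        deg[m] = a.size();
        if (deg[m] >= seed_min && !tried[m])
          seeds.push(HeapEntry(deg[m], -m));
      }
      for (int r : vt) {
        auto &a = adj_r[r];
        a.erase(std::remove_if(a.begin(), a.end(),
                               [&](int m) { return in_vs[m] != 0; }),
                a.end());
      }
      Cluster cl;
      cl.vs = vs;
      cl.vt = vt;
      std::sort(cl.vs.begin(), cl.vs.end());
      std::sort(cl.vt.begin(), cl.vt.end());
      cl.e = e;
      cl.density = density;
      clusters.push_back(cl);
    }
    for (int m : vs) in_vs[m] = 0;
    for (int r : vt) in_vt[r] = 0;
    for (int m : touched_k) gain_k[m] = 0.0;
    for (int r : touched_r) gain_r[r] = 0.0;
  }

  List out(clusters.size());
  for (size_t i = 0; i < clusters.size(); i++) {
    IntegerVector vs1(clusters[i].vs.begin(), clusters[i].vs.end());
    IntegerVector vt1(clusters[i].vt.begin(), clusters[i].vt.end());
    out[i] = List::create(
        Named("vs") = vs1 + 1, Named("vt") = vt1 + 1,
        Named("e") = clusters[i].e, Named("density") = clusters[i].density);
  }
  return out;
}
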